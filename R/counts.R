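#' Shared/private polymorphism count table
#'
#' Container for the 2x2 table at the heart of the shared-vs-private test:
#' the numbers of shared nonsynonymous (`s_n`), shared synonymous (`s_s`),
#' private nonsynonymous (`r_n`) and private synonymous (`r_s`)
#' polymorphisms in a two-population comparison.
#'
#' Counts are non-negative; they are normally integers, but real values are
#' accepted because bootstrap-weighted sums and model expectations (see
#' [expected_counts()]) are real-valued.
#'
#' @param s_n,s_s,r_n,r_s Non-negative counts of shared nonsynonymous,
#'   shared synonymous, private nonsynonymous and private synonymous
#'   polymorphisms.
#' @return An object of class `poly_counts`: a named numeric vector with
#'   elements `s_n`, `s_s`, `r_n`, `r_s`.
#' @examples
#' poly_counts(20, 10, 10, 10)
#' @export
poly_counts <- function(s_n, s_s, r_n, r_s) {
  x <- c(s_n = as.numeric(s_n), s_s = as.numeric(s_s),
         r_n = as.numeric(r_n), r_s = as.numeric(r_s))
  if (anyNA(x) || length(x) != 4L)
    stop("all four counts (s_n, s_s, r_n, r_s) must be supplied and non-missing")
  if (any(x < 0))
    stop("polymorphism counts must be non-negative")
  structure(x, class = "poly_counts")
}

#' @method print poly_counts
#' @export
print.poly_counts <- function(x, ...) {
  m <- as.matrix(x)
  cat("Shared/private polymorphism counts:\n")
  print(m, ...)
  invisible(x)
}

#' @export
as.matrix.poly_counts <- function(x, ...) {
  matrix(unclass(x)[c("s_n", "s_s", "r_n", "r_s")], nrow = 2, byrow = TRUE,
         dimnames = list(c("shared", "private"),
                         c("nonsynonymous", "synonymous")))
}

as_poly_counts <- function(x) {
  if (inherits(x, "poly_counts")) return(x)
  if (is.matrix(x) && all(dim(x) == c(2, 2)))
    return(poly_counts(x[1, 1], x[1, 2], x[2, 1], x[2, 2]))
  if (is.numeric(x) && length(x) == 4) {
    if (!is.null(names(x)) && all(c("s_n", "s_s", "r_n", "r_s") %in% names(x)))
      return(poly_counts(x["s_n"], x["s_s"], x["r_n"], x["r_s"]))
    return(poly_counts(x[1], x[2], x[3], x[4]))
  }
  stop("cannot interpret 'x' as a shared/private 2x2 count table")
}

stop_zero_cell <- function(x, cells) {
  bad <- cells[unclass(x)[cells] == 0]
  if (length(bad))
    stop("statistic undefined: zero count in cell(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
}

#' The Z statistic for balancing selection
#'
#' Z is the ratio of the nonsynonymous:synonymous ratio among polymorphisms
#' shared between two populations to the same ratio among polymorphisms
#' private to one of them:
#' \deqn{Z = \frac{S_N/S_S}{R_N/R_S}.}
#' Under neutrality (or any model in which shared and private polymorphisms
#' are drawn from the same mix of selective effects) Z = 1; balancing
#' selection inflates the shared nonsynonymous class and drives Z above 1,
#' while purifying selection on its own pushes Z below 1, making the test
#' conservative.
#'
#' @param counts A [poly_counts()] table (or anything coercible to one).
#' @return The Z ratio, a single number.
#' @examples
#' compute_z(poly_counts(20, 10, 10, 10)) # 2
#' @seealso [compute_alpha_b()], [zb_test()]
#' @export
compute_z <- function(counts) {
  x <- as_poly_counts(counts)
  stop_zero_cell(x, c("s_s", "r_n", "r_s"))
  unname((x["s_n"] / x["s_s"]) / (x["r_n"] / x["r_s"]))
}

#' Proportion of shared nonsynonymous polymorphisms under balancing selection
#'
#' Estimates \eqn{\alpha_b = 1 - 1/Z = 1 - (S_S R_N)/(S_N R_S)}, the
#' proportion of shared nonsynonymous polymorphisms directly maintained by
#' balancing selection under the simple expectation model of
#' [expected_counts()]. Negative values (Z < 1) are reported as-is; they
#' arise when segregating deleterious mutations depress the shared
#' nonsynonymous class.
#'
#' @inheritParams compute_z
#' @return The estimate of alpha_b (may be negative).
#' @examples
#' compute_alpha_b(poly_counts(20, 10, 10, 10)) # 0.5
#' @export
compute_alpha_b <- function(counts) {
  x <- as_poly_counts(counts)
  stop_zero_cell(x, c("s_n", "r_s"))
  unname(1 - (x["s_s"] * x["r_n"]) / (x["s_n"] * x["r_s"]))
}

#' Number of balanced polymorphisms implied by alpha_b
#'
#' b = alpha_b * S_N: the number of shared nonsynonymous polymorphisms
#' directly maintained by balancing selection.
#'
#' @param alpha_b Estimate from [compute_alpha_b()].
#' @param s_n Number of shared nonsynonymous polymorphisms.
#' @return A list with the raw (real-valued) estimate `b` and its nearest
#'   integer `b_rounded`.
#' @export
estimate_b <- function(alpha_b, s_n) {
  if (s_n < 0) stop("s_n must be non-negative")
  b <- alpha_b * s_n
  list(b = b, b_rounded = round(b))
}

#' Expected shared/private counts under the simple balancing-selection model
#'
#' Analytic expectations for the four cells of the shared/private table.
#' With theta = 4*Ne*u the per-site scaled mutation rate, rho the proportion
#' of polymorphisms private to the population, W Watterson's coefficient
#' (treated as a supplied dimensionless factor; it cancels from Z and
#' alpha_b), f the proportion of nonsynonymous mutations that are neutral,
#' b the number of balanced nonsynonymous polymorphisms and x the number of
#' neutral mutations held in linkage disequilibrium per balanced
#' polymorphism:
#' \deqn{R_S = \theta\rho W,\quad R_N = \theta\rho W f,}
#' \deqn{S_S = \theta(1-\rho)W + bx,\quad S_N = \theta(1-\rho)W f + b + bxf.}
#' These satisfy the closure \eqn{\alpha_b(\mathrm{expected}) = b / S_N}
#' exactly, which is the identity the estimator rests on.
#'
#' @param theta Scaled mutation rate (4*Ne*u); alternatively supply `n_e`
#'   and `u`.
#' @param rho Proportion of polymorphisms private to the population, in
#'   \[0,1\].
#' @param watterson_w Watterson's coefficient W (dimensionless factor).
#' @param f Proportion of nonsynonymous mutations that are neutral, in
#'   \[0,1\].
#' @param b Number of balanced nonsynonymous polymorphisms (>= 0).
#' @param x Neutral hitchhikers maintained in LD per balanced polymorphism
#'   (>= 0).
#' @param n_e,u Optional effective population size and per-site mutation
#'   rate; if both are given, `theta` is computed as 4*n_e*u (and must not
#'   disagree with a supplied `theta`).
#' @return A real-valued expectation table of class
#'   `c("poly_expect", "poly_counts")`.
#' @examples
#' p <- expected_counts(theta = 10, rho = 0.6, watterson_w = 1, f = 0.4,
#'                      b = 2, x = 1)
#' compute_alpha_b(p) * p["s_n"] # recovers b = 2
#' @export
expected_counts <- function(theta = NULL, rho, watterson_w = 1, f, b = 0,
                            x = 0, n_e = NULL, u = NULL) {
  if (!is.null(n_e) && !is.null(u)) {
    th <- 4 * n_e * u
    if (!is.null(theta) && abs(theta - th) > 1e-8 * max(1, th))
      stop("theta disagrees with 4 * n_e * u")
    theta <- th
  }
  if (is.null(theta)) stop("supply theta, or both n_e and u")
  vals <- c(theta = theta, rho = rho, W = watterson_w, f = f, b = b, x = x)
  if (anyNA(vals) || any(vals < 0))
    stop("model parameters must be non-negative and non-missing")
  if (rho > 1 || f > 1) stop("rho and f must lie in [0, 1]")
  out <- poly_counts(
    s_n = theta * (1 - rho) * watterson_w * f + b + b * x * f,
    s_s = theta * (1 - rho) * watterson_w + b * x,
    r_n = theta * rho * watterson_w * f,
    r_s = theta * rho * watterson_w
  )
  class(out) <- c("poly_expect", class(out))
  attr(out, "params") <- as.list(vals)
  out
}

#' Expected random overlap between a candidate set and a background fraction
#'
#' How many of `candidate_count` candidate genes would be expected to
#' overlap an independent gene list covering a fraction
#' `background_fraction` of the genome by chance alone.
#'
#' @param candidate_count Number of candidate genes (>= 0).
#' @param background_fraction Fraction of genes in the background list, in
#'   \[0,1\].
#' @return A list with the raw `expected` value and its nearest integer
#'   `rounded`.
#' @examples
#' expected_random_overlap(514, 0.079) # 40.606, rounds to 41
#' @export
expected_random_overlap <- function(candidate_count, background_fraction) {
  if (candidate_count < 0 || background_fraction < 0 ||
      background_fraction > 1)
    stop("candidate_count must be >= 0 and background_fraction in [0, 1]")
  e <- candidate_count * background_fraction
  list(expected = e, rounded = round(e))
}
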