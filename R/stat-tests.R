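#' Chi-squared test of independence on the shared/private table
#'
#' Pearson's chi-squared test of independence on the 2x2 table
#' {S_N, S_S; R_N, R_S}, 1 degree of freedom. By default no Yates
#' continuity correction is applied: the test is normally run on counts
#' pooled over many genes, where the correction is second order.
#'
#' @inheritParams compute_z
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return A list of class `zb_htest` with elements `statistic`, `p_value`
#'   and `method = "chi2"`.
#' @examples
#' chi2_test(poly_counts(30, 10, 10, 30))
#' @export
chi2_test <- function(counts, correct = FALSE) {
  x <- as_poly_counts(counts)
  m <- as.matrix(x)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: a row or column marginal is zero")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  structure(list(statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value),
                 method = "chi2"),
            class = "zb_htest")
}

#' One-tailed Fisher's exact test for an excess of shared nonsynonymous
#' polymorphisms
#'
#' Exact hypergeometric test of the 2x2 shared/private table, one-tailed in
#' the direction Z > 1 (an excess of S_N relative to independence given the
#' margins). Used for single genes, where counts are small.
#'
#' @inheritParams compute_z
#' @return A list of class `zb_htest` with elements `statistic` (the
#'   conditional odds-ratio estimate), `p_value` and
#'   `method = "fisher_one_tailed"`. Degenerate tables (an empty row or
#'   column) give p = 1.
#' @examples
#' fisher_exact_one_tailed(poly_counts(5, 0, 0, 5))
#' @export
fisher_exact_one_tailed <- function(counts) {
  x <- as_poly_counts(counts)
  m <- round(as.matrix(x))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(structure(list(statistic = NA_real_, p_value = 1,
                          method = "fisher_one_tailed"),
                     class = "zb_htest"))
  }
  ht <- stats::fisher.test(m, alternative = "greater")
  structure(list(statistic = unname(ht$estimate),
                 p_value = unname(ht$p.value),
                 method = "fisher_one_tailed"),
            class = "zb_htest")
}

#' @method print zb_htest
#' @export
print.zb_htest <- function(x, ...) {
  cat(sprintf("%s test: statistic = %s, p = %.4g\n", x$method,
              format(x$statistic, digits = 4), x$p_value))
  invisible(x)
}
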