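#' Shared-vs-private polymorphism test for balancing selection
#'
#' Fits the shared/private contingency test to a pooled 2x2 count table or
#' to a set of per-gene tables. The statistic is
#' \eqn{Z = (S_N/S_S)/(R_N/R_S)}: the nonsynonymous:synonymous ratio among
#' polymorphisms shared between two populations divided by the same ratio
#' among private polymorphisms. Values of Z above 1 indicate balancing
#' selection; segregating deleterious mutations can only depress Z, so the
#' test is conservative. The companion estimators are
#' \eqn{\alpha_b = 1 - 1/Z}, the proportion of shared nonsynonymous
#' polymorphisms directly maintained by balancing selection, and
#' \eqn{b = \alpha_b S_N}, their number.
#'
#' When per-gene tables are supplied, the point estimates are computed on
#' the table summed across genes and confidence intervals come from a
#' gene-level bootstrap ([bootstrap_ci()]); a chi-squared test of
#' independence and a one-tailed Fisher exact test (direction Z > 1) are
#' run on the pooled table.
#'
#' @param x A [poly_counts()] table, a 2x2 matrix, or a per-gene data frame
#'   with columns `s_n`, `s_s`, `r_n`, `r_s` (and optionally `gene_id`).
#' @param boot_replicates Bootstrap replicates for the gene-level CI
#'   (default 100); ignored for a single pooled table.
#' @param level Confidence level for the bootstrap intervals.
#' @param seed Optional integer seed for the bootstrap.
#' @param chi2_correct Apply the Yates continuity correction in the
#'   chi-squared test (default `FALSE`).
#' @return An object of class `zb_test` with components `counts` (pooled
#'   table), `z`, `alpha_b`, `b`, `chi2`, `fisher`, and (with per-gene
#'   input) `boot`, a list of `zb_boot` intervals for Z, alpha_b and b.
#' @examples
#' fit <- zb_test(poly_counts(120, 100, 200, 210))
#' fit
#' coef(fit)
#' @seealso [compute_z()], [compute_alpha_b()], [bootstrap_ci()]
#' @export
zb_test <- function(x, boot_replicates = 100, level = 0.95, seed = NULL,
                    chi2_correct = FALSE) {
  per_gene <- is.data.frame(x) && nrow(x) > 1
  if (per_gene) {
    m <- gene_table_matrix(x)
    pooled <- do.call(poly_counts, as.list(colSums(m)))
  } else {
    pooled <- as_poly_counts(if (is.data.frame(x))
      unlist(x[1, c("s_n", "s_s", "r_n", "r_s")]) else x)
  }
  z <- compute_z(pooled)
  ab <- compute_alpha_b(pooled)
  b <- estimate_b(ab, unname(unclass(pooled)["s_n"]))
  chi <- tryCatch(chi2_test(pooled, correct = chi2_correct),
                  error = function(e) NULL)
  fis <- fisher_exact_one_tailed(pooled)
  boot <- NULL
  if (per_gene) {
    boot <- lapply(c(Z = "Z", alpha_b = "alpha_b", b = "b"), function(st)
      bootstrap_ci(x, st, replicates = boot_replicates, level = level,
                   seed = seed))
  }
  structure(list(counts = pooled, z = z, alpha_b = ab, b = b$b,
                 b_rounded = b$b_rounded, chi2 = chi, fisher = fis,
                 boot = boot, level = level),
            class = "zb_test")
}

#' @method print zb_test
#' @export
print.zb_test <- function(x, digits = 4, ...) {
  cat("Shared-vs-private polymorphism test for balancing selection\n\n")
  print(x$counts)
  cat(sprintf("\nZ = %.*g   alpha_b = %.*g   b = %.*g (~%d)\n", digits, x$z,
              digits, x$alpha_b, digits, x$b, x$b_rounded))
  if (!is.null(x$chi2))
    cat(sprintf("chi-squared = %.4g, p = %.4g; one-tailed Fisher p = %.4g\n",
                x$chi2$statistic, x$chi2$p_value, x$fisher$p_value))
  else
    cat(sprintf("one-tailed Fisher p = %.4g (chi-squared degenerate)\n",
                x$fisher$p_value))
  invisible(x)
}

#' @export
summary.zb_test <- function(object, ...) {
  x <- object
  est <- data.frame(
    statistic = c("Z", "alpha_b", "b"),
    estimate = c(x$z, x$alpha_b, x$b),
    ci_low = NA_real_, ci_high = NA_real_, se = NA_real_
  )
  if (!is.null(x$boot)) {
    for (i in seq_len(3)) {
      bt <- x$boot[[i]]
      est$ci_low[i] <- bt$ci_low
      est$ci_high[i] <- bt$ci_high
      est$se[i] <- bt$se
    }
  }
  out <- list(estimates = est, counts = x$counts, chi2 = x$chi2,
              fisher = x$fisher, level = x$level)
  class(out) <- "summary.zb_test"
  out
}

#' @method print summary.zb_test
#' @export
print.summary.zb_test <- function(x, ...) {
  cat("Shared-vs-private polymorphism test for balancing selection\n\n")
  print(x$counts)
  cat("\nEstimates")
  if (!all(is.na(x$estimates$ci_low)))
    cat(sprintf(" (with %.0f%% gene-bootstrap CIs)", 100 * x$level))
  cat(":\n")
  print(x$estimates, row.names = FALSE, digits = 4)
  if (!is.null(x$chi2))
    cat(sprintf("\nchi-squared = %.4g, p = %.4g; one-tailed Fisher p = %.4g\n",
                x$chi2$statistic, x$chi2$p_value, x$fisher$p_value))
  invisible(x)
}

#' @export
coef.zb_test <- function(object, ...) {
  c(Z = object$z, alpha_b = object$alpha_b, b = object$b)
}

#' @export
confint.zb_test <- function(object, parm = c("Z", "alpha_b", "b"),
                            level = NULL, ...) {
  if (is.null(object$boot))
    stop("confidence intervals require per-gene input (gene-level bootstrap)")
  if (!is.null(level) && abs(level - object$level) > 1e-12)
    stop("intervals were computed at level ", object$level,
         "; refit with the desired level")
  parm <- match.arg(parm, several.ok = TRUE)
  out <- t(vapply(parm, function(p) {
    bt <- object$boot[[p]]
    c(bt$ci_low, bt$ci_high)
  }, numeric(2)))
  colnames(out) <- paste0(100 * c((1 - object$level) / 2,
                                  1 - (1 - object$level) / 2), " %")
  out
}
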