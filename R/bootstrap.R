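# Gene-level bootstrap for statistics computed on pooled count tables.

gene_table_matrix <- function(gene_tables) {
  if (is.data.frame(gene_tables)) {
    need <- c("s_n", "s_s", "r_n", "r_s")
    if (!all(need %in% names(gene_tables)))
      stop("per-gene data frame needs columns s_n, s_s, r_n, r_s")
    m <- as.matrix(gene_tables[, need])
    rownames(m) <- if ("gene_id" %in% names(gene_tables))
      as.character(gene_tables$gene_id) else NULL
    return(m)
  }
  if (is.list(gene_tables)) {
    m <- do.call(rbind, lapply(gene_tables, function(g) unclass(as_poly_counts(g))))
    colnames(m) <- c("s_n", "s_s", "r_n", "r_s")
    return(m)
  }
  stop("gene_tables must be a data frame or a list of poly_counts")
}

pooled_statistic <- function(sums, statistic) {
  x <- poly_counts(sums[1], sums[2], sums[3], sums[4])
  switch(statistic,
         Z = compute_z(x),
         alpha_b = compute_alpha_b(x),
         b = compute_alpha_b(x) * unclass(x)["s_n"],
         stop("unknown statistic: ", statistic))
}

#' Gene-level bootstrap confidence interval for Z, alpha_b or b
#'
#' The point estimate is computed on the table obtained by summing S_N,
#' S_S, R_N and R_S across genes; uncertainty is assessed by resampling
#' genes with replacement, re-summing, and recomputing the statistic on
#' each resampled sum. Resampling whole genes captures all sources of
#' variation below the gene level (site sampling, linkage within genes).
#' Percentile intervals are returned; replicates on which the statistic is
#' undefined (a zero cell in the resampled sum) are dropped and counted.
#'
#' @param gene_tables Per-gene count tables: a data frame with columns
#'   `s_n`, `s_s`, `r_n`, `r_s` (and optionally `gene_id`), or a list of
#'   [poly_counts()] tables.
#' @param statistic One of `"Z"`, `"alpha_b"`, `"b"`.
#' @param replicates Number of bootstrap replicates (default 100).
#' @param level Confidence level (default 0.95).
#' @param seed Optional integer seed for the resampling.
#' @return A list of class `zb_boot` with the point `estimate` (on the
#'   un-resampled sum), `ci_low`, `ci_high`, `se` (SD of replicate
#'   statistics), `n_dropped` (replicates with an undefined statistic),
#'   `replicates` (the retained replicate values) and `statistic`.
#' @examples
#' genes <- data.frame(s_n = rpois(30, 8), s_s = rpois(30, 6),
#'                     r_n = rpois(30, 10), r_s = rpois(30, 10))
#' bootstrap_ci(genes, "Z", replicates = 100, seed = 1)
#' @export
bootstrap_ci <- function(gene_tables, statistic = c("Z", "alpha_b", "b"),
                         replicates = 100, level = 0.95, seed = NULL) {
  statistic <- match.arg(statistic)
  m <- gene_table_matrix(gene_tables)
  if (nrow(m) < 2) stop("need at least 2 genes to bootstrap")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  point <- pooled_statistic(colSums(m), statistic)
  n <- nrow(m)
  reps <- numeric(replicates)
  ok <- logical(replicates)
  for (i in seq_len(replicates)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(pooled_statistic(colSums(m[idx, , drop = FALSE]), statistic),
                    error = function(e) NA_real_)
    reps[i] <- val
    ok[i] <- is.finite(val)
  }
  if (!any(ok)) stop("bootstrap failed: statistic undefined on every replicate")
  kept <- reps[ok]
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(kept, c(a, 1 - a), type = 7))
  structure(list(estimate = point, ci_low = ci[1], ci_high = ci[2],
                 se = stats::sd(kept), n_dropped = sum(!ok),
                 replicates = kept, statistic = statistic, level = level),
            class = "zb_boot")
}

#' @method print zb_boot
#' @export
print.zb_boot <- function(x, ...) {
  cat(sprintf("%s = %.4g, %.0f%% bootstrap CI [%.4g, %.4g] (se %.3g, %d of %d replicates dropped)\n",
              x$statistic, x$estimate, 100 * x$level, x$ci_low, x$ci_high,
              x$se, x$n_dropped, x$n_dropped + length(x$replicates)))
  invisible(x)
}
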