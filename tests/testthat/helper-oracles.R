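# Independent oracles, written from first principles and kept separate
# from the implementation paths they check.

# Pearson chi-squared on a 2x2 table via the closed form
# N (ad - bc)^2 / (r1 r2 c1 c2).
oracle_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# One-tailed Fisher p by exhaustive enumeration of all 2x2 tables with the
# observed margins: sum the conditional hypergeometric probability of every
# table whose top-left cell (shared nonsynonymous) is >= the observed one.
oracle_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  p_tab <- function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1)
  sum(vapply(seq.int(a, hi), p_tab, numeric(1)))
}

# Draw a random small 2x2 table with all margins positive.
random_table <- function(max_cell = 30) {
  repeat {
    x <- sample.int(max_cell + 1L, 4, replace = TRUE) - 1L
    m <- matrix(x, 2)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(x)
  }
}

# Per-gene tables whose cells are Poisson around a common expected table;
# the data-generating pooled Z is the ratio of the expected cells.
random_gene_set <- function(n_genes, means = c(8, 6, 10, 10)) {
  data.frame(gene_id = paste0("g", seq_len(n_genes)),
             s_n = stats::rpois(n_genes, means[1]),
             s_s = stats::rpois(n_genes, means[2]),
             r_n = stats::rpois(n_genes, means[3]),
             r_s = stats::rpois(n_genes, means[4]))
}
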