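# Simulation experiment drivers: Z-versus-time curves, demographic
# false-positive sweeps, alpha_b recovery, single-gene power.

# Per-replicate cell counts (s_n, s_s, r_n, r_s) for the focal analysis
# set, optionally restricted to a folded-MAF window (lo, hi]. Rows cover
# every replicate in `reps`, including those with no sites.
rep_cell_matrix <- function(classified, reps, maf_lo = 0, maf_hi = 0.5) {
  d <- classified[classified$in_focal_set &
                    classified$func_class %in% c("nonsynonymous", "synonymous") &
                    classified$focal_maf > maf_lo &
                    classified$focal_maf <= maf_hi, , drop = FALSE]
  sh <- d$category == "shared"
  ns <- d$func_class == "nonsynonymous"
  ind <- cbind(s_n = sh & ns, s_s = sh & !ns, r_n = !sh & ns, r_s = !sh & !ns)
  m <- matrix(0, length(reps), 4,
              dimnames = list(as.character(reps), colnames(ind)))
  if (nrow(d)) {
    rs <- rowsum(ind + 0, group = d$gene_id)
    hit <- match(rownames(rs), rownames(m))
    ok <- !is.na(hit)
    m[hit[ok], ] <- rs[ok, , drop = FALSE]
  }
  m
}

# Bootstrap (over replicates) standard error of the pooled Z.
boot_z_se <- function(repmat, B = 200) {
  n <- nrow(repmat)
  if (n < 2) return(NA_real_)
  vals <- vapply(seq_len(B), function(b) {
    cs <- colSums(repmat[sample.int(n, n, replace = TRUE), , drop = FALSE])
    if (any(cs[-1] == 0)) NA_real_ else (cs[1] / cs[2]) / (cs[3] / cs[4])
  }, numeric(1))
  stats::sd(vals[is.finite(vals)])
}

safe_z <- function(counts) {
  tryCatch(compute_z(counts), error = function(e) NA_real_)
}

#' Z as a function of time since the population split
#'
#' Runs a scenario and reports the pooled Z statistic per sampling time,
#' per folded-MAF bin (plus the pooled MAF > 0.1 set and all frequencies
#' combined), for each focal population in turn. Counts are summed across
#' replicates before the ratio is taken (ratio of sums): the mean of
#' per-replicate Z values is biased for a ratio statistic and is never
#' reported. Monte-Carlo standard errors come from bootstrapping
#' replicates.
#'
#' @inheritParams run_scenario
#' @param bin_width Folded-MAF bin width (default 0.1).
#' @param boot Bootstrap replicates for the Monte-Carlo SE (default 200).
#' @return An object of class `z_curve`: a data frame with columns `time`
#'   (N generations post-split), `focal`, `bin` (`"(0,0.1]"`, ...,
#'   `">0.1"`, `"all"`), the four pooled cells, `z`, `mc_se`, `n_reps`
#'   and `n_discarded`.
#' @export
z_curve_experiment <- function(config, locus = locus_structure(),
                               dfe = NULL, dominance = dominance_model(),
                               balanced = NULL, min_retained = NULL,
                               bin_width = 0.1, boot = 200) {
  sim <- run_scenario(config, locus, dfe, dominance, balanced,
                      min_retained = min_retained)
  edges <- seq(0, 0.5, by = bin_width)
  windows <- data.frame(bin = c(sprintf("(%.2g,%.2g]", edges[-length(edges)],
                                        edges[-1]), ">0.1", "all"),
                        lo = c(edges[-length(edges)], 0.1, 0),
                        hi = c(edges[-1], 0.5, 0.5))
  rows <- list()
  for (i in seq_along(sim$times)) {
    reps <- sim$retained[[i]]
    for (focal in c("pop1", "pop2")) {
      cl <- classify_sim_sites(sim$samples[[i]], focal = focal,
                               reps = reps)$classified
      for (w in seq_len(nrow(windows))) {
        rm_ <- rep_cell_matrix(cl, reps, windows$lo[w], windows$hi[w])
        cs <- colSums(rm_)
        rows[[length(rows) + 1L]] <- data.frame(
          time = sim$times[i], focal = focal, bin = windows$bin[w],
          s_n = cs[1], s_s = cs[2], r_n = cs[3], r_s = cs[4],
          z = safe_z(cs), mc_se = boot_z_se(rm_, boot),
          n_reps = length(reps), n_discarded = sim$discards[i])
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("z_curve", class(out))
  attr(out, "config") <- config
  out
}

#' @method plot z_curve
#' @export
plot.z_curve <- function(x, focal = "pop1", bins = ">0.1", ...) {
  d <- x[x$focal == focal & x$bin %in% bins & is.finite(x$z), ]
  graphics::plot(d$time, d$z, type = "n",
                 xlab = "time since split (N generations)", ylab = "Z", ...)
  for (b in unique(d$bin)) {
    db <- d[d$bin == b, ]
    graphics::lines(db$time, db$z, type = "b",
                    col = match(b, unique(d$bin)))
  }
  graphics::abline(h = 1, lty = 2)
  graphics::legend("topright", legend = unique(d$bin),
                   col = seq_along(unique(d$bin)), lty = 1, bty = "n")
  invisible(x)
}

#' Recovery of alpha_b from mixed simulation pools
#'
#' Pools replicates simulated with and without a balanced polymorphism at
#' each mixing fraction, and compares the inferred
#' \eqn{\alpha_b = 1 - (S_S R_N)/(S_N R_S)} on the pooled counts with the
#' true value, counted directly as the fraction of shared nonsynonymous
#' polymorphisms that are the flagged balanced mutations themselves
#' (hitchhikers are not "true" balanced sites). Negative inferred values
#' are truncated to zero only in the reported `ratio`; the raw inferred
#' value is always retained.
#'
#' @inheritParams run_scenario
#' @param dfe A [dfe_params()] object (used in both pools).
#' @param balanced A [balanced_config()] for the balancing pool.
#' @param mix_fractions Proportions of balancing-selection replicates in
#'   the pool, each in \[0,1\].
#' @param bin_width Folded-MAF bin width.
#' @param focal Focal population.
#' @return An object of class `alpha_recovery`: a data frame with one row
#'   per sampling time x mix fraction x bin, with columns `true_alpha_b`,
#'   `inferred_alpha_b`, `ratio` (truncated inferred / true; `NA` where
#'   the true value is 0), the pooled cells and pool sizes.
#' @export
alpha_recovery_experiment <- function(config, locus = locus_structure(),
                                      dfe = dfe_human(),
                                      dominance = dominance_model(),
                                      balanced = balanced_config(),
                                      mix_fractions = c(0, 0.25, 0.5, 0.75, 1),
                                      min_retained = NULL,
                                      bin_width = 0.1, focal = "pop1") {
  sim_bal <- run_scenario(config, locus, dfe, dominance, balanced,
                          min_retained = min_retained)
  config_null <- config
  config_null$seed <- config$seed + 500000L
  sim_null <- run_scenario(config_null, locus, dfe, dominance, NULL)
  edges <- seq(0, 0.5, by = bin_width)
  nb <- length(edges) - 1L
  rows <- list()
  for (i in seq_along(config$sample_times)) {
    reps_b <- sim_bal$retained[[i]]
    reps_n <- seq_len(sim_null$n_total)
    cl_b <- classify_sim_sites(sim_bal$samples[[i]], focal = focal,
                               reps = reps_b)$classified
    cl_n <- classify_sim_sites(sim_null$samples[[i]], focal = focal,
                               reps = reps_n)$classified
    hi_mix <- max(mix_fractions)
    n_pool <- min(
      if (hi_mix > 0) floor(length(reps_b) / hi_mix) else Inf,
      if (hi_mix < 1 || any(mix_fractions < 1))
        floor(length(reps_n) / max(1 - mix_fractions)) else Inf,
      length(reps_b) + length(reps_n))
    for (mix in mix_fractions) {
      n_b <- round(mix * n_pool)
      n_n <- n_pool - n_b
      use_b <- cl_b[cl_b$gene_id %in% reps_b[seq_len(n_b)], , drop = FALSE]
      use_n <- cl_n[cl_n$gene_id %in% reps_n[seq_len(n_n)], , drop = FALSE]
      pool <- rbind(use_b, use_n)
      for (w in seq_len(nb)) {
        sel <- pool$in_focal_set & pool$focal_maf > edges[w] &
          pool$focal_maf <= edges[w + 1] &
          pool$func_class %in% c("nonsynonymous", "synonymous")
        d <- pool[sel, , drop = FALSE]
        sh_ns <- d$category == "shared" & d$func_class == "nonsynonymous"
        true_ab <- if (sum(sh_ns)) sum(d$balanced[sh_ns]) / sum(sh_ns)
                   else NA_real_
        cs <- unclass(count_table(d))
        inf_ab <- tryCatch(compute_alpha_b(cs), error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          time = config$sample_times[i], mix_fraction = mix,
          bin = sprintf("(%.2g,%.2g]", edges[w], edges[w + 1]),
          true_alpha_b = true_ab, inferred_alpha_b = inf_ab,
          ratio = if (is.finite(true_ab) && true_ab > 0 && is.finite(inf_ab))
            max(0, inf_ab) / true_ab else NA_real_,
          s_n = cs[1], s_s = cs[2], r_n = cs[3], r_s = cs[4],
          n_balanced_reps = n_b, n_null_reps = n_n)
      }
    }
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("alpha_recovery", class(out))
  out
}

#' Power to detect balancing selection in a single gene
#'
#' Simulates a gene-shaped locus (9 exons of 288 bp by default; use
#' `scale = 10` for a tenfold gene) under a vicariance split into two
#' equal halves, with deleterious mutations only and with an additional
#' balanced polymorphism at the centre of each exon, and returns the two
#' per-replicate Z distributions computed on polymorphisms at all
#' frequencies. Replicates on which Z is undefined (a zero cell) are
#' dropped and counted. The overlap summary is the fraction of
#' no-balancing replicates whose Z exceeds the median of the balancing
#' distribution.
#'
#' @param scale Gene-size multiplier (1 or 10).
#' @param replicates Replicates per arm (>= 100).
#' @param seed Integer seed.
#' @param sample_time Sampling time, N generations post-split (default 1).
#' @param dfe,dominance,balanced Model objects; defaults: human DFE,
#'   selection-dependent dominance, NFDS with `Ns_eq` = 20.
#' @param theta_factor Mutation-rate inflation for desk-scale runs.
#' @param n_ancestral Ancestral diploid size (default 200).
#' @return An object of class `power_result`: list with `z_null`, `z_bal`
#'   (per-replicate Z values), `overlap`, `n_dropped_null`,
#'   `n_dropped_bal`, `n_discarded_bal`.
#' @export
single_gene_power_experiment <- function(scale = 1, replicates = 200,
                                         seed = 1, sample_time = 1,
                                         dfe = dfe_human(),
                                         dominance = dominance_model(),
                                         balanced = balanced_config(),
                                         theta_factor = 1,
                                         n_ancestral = 200) {
  if (replicates < 100) stop("replicates must be >= 100")
  locus <- locus_structure(exon_length = 288, n_exons = 9 * scale)
  base <- scenario_config("vicariance", n_ancestral = n_ancestral,
                          split_fractions = c(0.5, 0.5),
                          theta_factor = theta_factor,
                          sample_times = sample_time,
                          replicates = replicates, seed = seed)
  sim_null <- run_scenario(base, locus, dfe, dominance, NULL)
  base_bal <- base
  base_bal$seed <- base$seed + 500000L
  sim_bal <- run_scenario(base_bal, locus, dfe, dominance, balanced,
                          min_retained = replicates)
  per_rep_z <- function(sim) {
    reps <- sim$retained[[1]]
    cl <- classify_sim_sites(sim$samples[[1]], reps = reps)$classified
    m <- rep_cell_matrix(cl, reps)
    z <- ifelse(m[, 2] > 0 & m[, 3] > 0 & m[, 4] > 0 ,
                (m[, 1] / m[, 2]) / (m[, 3] / m[, 4]), NA_real_)
    z
  }
  z0 <- per_rep_z(sim_null)
  z1 <- per_rep_z(sim_bal)
  if (length(z1) > replicates) z1 <- z1[seq_len(replicates)]
  structure(list(z_null = z0[is.finite(z0)], z_bal = z1[is.finite(z1)],
                 overlap = mean(z0[is.finite(z0)] >
                                  stats::median(z1[is.finite(z1)])),
                 n_dropped_null = sum(!is.finite(z0)),
                 n_dropped_bal = sum(!is.finite(z1)),
                 n_discarded_bal = sim_bal$discards[[1]],
                 scale = scale),
            class = "power_result")
}

#' @method print power_result
#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Single-gene power (%dx gene):\n", x$scale))
  cat(sprintf("  Z without balancing: median %.3f (n = %d, %d undefined)\n",
              stats::median(x$z_null), length(x$z_null), x$n_dropped_null))
  cat(sprintf("  Z with balancing:    median %.3f (n = %d, %d undefined)\n",
              stats::median(x$z_bal), length(x$z_bal), x$n_dropped_bal))
  cat(sprintf("  overlap: %.2f of no-balancing replicates exceed the balancing median\n",
              x$overlap))
  invisible(x)
}

#' @method plot power_result
#' @export
plot.power_result <- function(x, ...) {
  rng <- range(c(x$z_null, x$z_bal), finite = TRUE)
  d0 <- stats::density(x$z_null, from = max(0, rng[1]), to = rng[2])
  d1 <- stats::density(x$z_bal, from = max(0, rng[1]), to = rng[2])
  graphics::plot(d0, col = 1,
                 main = sprintf("Per-gene Z distributions (%dx gene)",
                                x$scale),
                 xlab = "Z", ylim = c(0, max(d0$y, d1$y)), ...)
  graphics::lines(d1, col = 2)
  graphics::legend("topright", c("no balancing", "balancing"),
                   col = 1:2, lty = 1, bty = "n")
  invisible(x)
}
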