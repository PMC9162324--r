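#' Exon/intron structure of the simulated locus
#'
#' Loci are gene-shaped: `n_exons` exons of `exon_length` bp separated by
#' introns. The default single 288-bp exon is the average human exon; the
#' average human gene is approximated by 9 exons of 288 bp separated by 8
#' introns of 5,419 bp. Only exonic sites are simulated and tabulated:
#' intronic mutations are neutral and never enter the nonsynonymous/
#' synonymous count tables, and with sites evolving independently they
#' would not influence exonic trajectories (see the methods vignette).
#' Within exons, positions at codon offset 3 are synonymous and offsets
#' 1-2 nonsynonymous (a deterministic 2:1 ratio).
#'
#' @param exon_length Exon length in bp (default 288).
#' @param n_exons Number of exons (default 1).
#' @param intron_length Intron length in bp (default 5419; bookkeeping
#'   only).
#' @return An object of class `locus_structure` with the total exonic
#'   length `lex` and the balanced-polymorphism placement positions
#'   (centre of each exon, shifted to a nonsynonymous offset).
#' @export
locus_structure <- function(exon_length = 288, n_exons = 1,
                            intron_length = 5419) {
  if (exon_length <= 0 || n_exons < 1) stop("invalid locus structure")
  lex <- exon_length * n_exons
  centre <- (seq_len(n_exons) - 1L) * exon_length +
    floor(exon_length / 2) + 1L
  # balanced sites must be nonsynonymous: bump off codon third positions
  centre <- ifelse(centre %% 3L == 0L, centre + 1L, centre)
  structure(list(exon_length = exon_length, n_exons = n_exons,
                 intron_length = intron_length,
                 n_introns = max(0L, n_exons - 1L),
                 lex = as.integer(lex),
                 balanced_positions = as.integer(centre)),
            class = "locus_structure")
}

#' Simulation scenario configuration
#'
#' Describes one population-split scenario: an ancestral diploid
#' population of size `n_ancestral` equilibrates for `burn_in` (in N
#' generations), optionally acquires a balanced polymorphism, and then
#' splits into two daughters by one of three modes: `"duplication"` (both
#' daughters copies of the ancestor at full size), `"vicariance"` (the
#' ancestral individuals are divided between daughters of sizes
#' `split_fractions * N`) or `"dispersal"` (a daughter of size
#' `split_fractions[2] * N` buds off while the ancestor continues at full
#' size). Daughters may expand exponentially and exchange migrants.
#'
#' `theta_factor` inflates the per-site mutation rate so that pooled
#' counts over thousands of replicates reach useful Monte-Carlo error at
#' desk scale; selection parameters are untouched (they are specified on
#' the `N*s` scale). `rescale_factor` instead jointly rescales the
#' population size down and the mutation rate up by the same factor,
#' which inflates `s` implicitly through the `N*s` parameterisation.
#'
#' @param mode Split mode: `"duplication"`, `"vicariance"` or
#'   `"dispersal"`.
#' @param n_ancestral Ancestral diploid population size (default 200).
#' @param split_fractions Daughter sizes as fractions of N (length 2; for
#'   dispersal the second entry is the dispersing daughter).
#' @param expansion `NULL`, or a list with `mult` (length-2 final-size
#'   multipliers per daughter) and `horizon` (N generations to reach them;
#'   default 21) for exponential growth.
#' @param migration_rate Per-generation fraction of each daughter replaced
#'   by migrants from the other (default 0).
#' @param mu Mutation rate per site per generation (default 2.5e-8).
#' @param r Recombination rate per site per generation (default 1.1e-8;
#'   recorded for provenance — sites evolve at linkage equilibrium).
#' @param theta_factor Mutation-rate inflation factor (default 1).
#' @param rescale_factor Joint rescaling of N down / mu up (default 1).
#' @param burn_in Equilibration time in N generations (default 15).
#' @param sample_times Post-split sampling times in N generations.
#' @param replicates Number of replicates per batch.
#' @param seed Integer RNG seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(mode = c("duplication", "vicariance", "dispersal"),
                            n_ancestral = 200,
                            split_fractions = c(0.5, 0.5),
                            expansion = NULL,
                            migration_rate = 0,
                            mu = 2.5e-8, r = 1.1e-8,
                            theta_factor = 1, rescale_factor = 1,
                            burn_in = 15,
                            sample_times = seq(0.05, 20, by = 0.05),
                            replicates = 100, seed = 1) {
  mode <- match.arg(mode)
  if (any(split_fractions <= 0)) stop("split fractions must be > 0")
  if (rescale_factor < 1) stop("rescale_factor must be >= 1")
  n_anc <- as.integer(round(n_ancestral / rescale_factor))
  structure(list(mode = mode, n_ancestral = n_anc,
                 split_fractions = split_fractions,
                 expansion = expansion, migration_rate = migration_rate,
                 mu = mu * theta_factor * rescale_factor, r = r,
                 theta_factor = theta_factor,
                 rescale_factor = rescale_factor,
                 burn_in = burn_in,
                 sample_times = sort(sample_times),
                 replicates = replicates, seed = seed),
            class = "scenario_config")
}

daughter_sizes <- function(config) {
  n <- config$n_ancestral
  switch(config$mode,
         duplication = c(n, n),
         vicariance = as.integer(round(config$split_fractions[1:2] * n)),
         dispersal = c(n, as.integer(round(config$split_fractions[2] * n))))
}

# Per-generation daughter sizes over `ngen` generations post-split.
size_schedule <- function(config, ngen) {
  n0 <- daughter_sizes(config)
  if (is.null(config$expansion))
    return(list(rep_len(n0[1], ngen), rep_len(n0[2], ngen)))
  mult <- rep_len(config$expansion$mult, 2)
  horizon <- (config$expansion$horizon %||% 21) * config$n_ancestral
  tt <- seq_len(ngen)
  lapply(1:2, function(k)
    as.integer(round(n0[k] * mult[k]^(pmin(tt, horizon) / horizon))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_batch <- function(config, locus, dfe, dominance, balanced, seed,
                      rep_offset) {
  set.seed(seed)
  n <- config$n_ancestral
  nrep <- config$replicates
  lex <- locus$lex
  s0 <- if (is.null(balanced)) 0 else balanced$scaled_ns_at_eq / n
  st <- st_new()
  st <- advance_single(st, round(config$burn_in * n), n, config$mu, lex,
                       dfe, dominance, n, s0, nrep)
  if (!is.null(balanced)) {
    npos <- length(locus$balanced_positions)
    peq <- balanced$eq_freq_distribution(nrep * npos)
    two_n <- 2L * n
    cnt <- pmin(pmax(round(peq * two_n), 1L), two_n - 1L)
    add <- list(rep = rep(seq_len(nrep), each = npos),
                pos = rep(locus$balanced_positions, times = nrep),
                syn = rep(FALSE, nrep * npos),
                s = numeric(nrep * npos),
                h = rep(0.5, nrep * npos),
                bal = rep(TRUE, nrep * npos),
                peq = peq, p1 = cnt / two_n,
                p2 = numeric(nrep * npos))
    st <- st_bind(st, add)
    st <- advance_single(st, round(balanced$intro_time * n), n, config$mu,
                         lex, dfe, dominance, n, s0, nrep)
  }
  nd <- daughter_sizes(config)
  st <- split_population(st, config$mode, n, nd[1], nd[2])
  gens <- round(config$sample_times * n)
  max_gen <- max(gens)
  sched <- size_schedule(config, max_gen)
  samples <- vector("list", length(gens))
  prev <- 0L
  for (i in seq_along(gens)) {
    span <- seq.int(prev + 1L, gens[i])
    if (gens[i] > prev)
      st <- advance_two(st, length(span), sched[[1]][span], sched[[2]][span],
                        config$migration_rate, config$mu, lex, dfe,
                        dominance, n, s0, nrep)
    seg <- (st$p1 > 0 & st$p1 < 1) | (st$p2 > 0 & st$p2 < 1)
    samples[[i]] <- data.frame(rep = st$rep[seg] + rep_offset,
                               pos = st$pos[seg], syn = st$syn[seg],
                               balanced = st$bal[seg],
                               p1 = st$p1[seg], p2 = st$p2[seg])
    prev <- gens[i]
  }
  samples
}

retained_reps <- function(sample_df, all_reps, balanced) {
  if (is.null(balanced)) return(all_reps)
  b <- sample_df[sample_df$balanced &
                   sample_df$p1 > 0 & sample_df$p1 < 1 &
                   sample_df$p2 > 0 & sample_df$p2 < 1, "rep"]
  intersect(all_reps, unique(b))
}

#' Run a Wright-Fisher population-split scenario
#'
#' Simulates `config$replicates` independent loci through burn-in,
#' optional introduction of a negative frequency-dependent balanced
#' polymorphism, the population split, and post-split evolution, taking a
#' frequency snapshot of both daughters at each `sample_times` point.
#'
#' When a balanced polymorphism is requested, replicates in which it is no
#' longer segregating in both populations at a sampling time are discarded
#' at that time (their other sites are dropped from the pooled analysis),
#' and if `min_retained` is given, additional batches are run with fresh
#' derived seeds until at least that many replicates are retained at every
#' sampling time (up to `max_batches` batches, then an error).
#'
#' @param config A [scenario_config()].
#' @param locus A [locus_structure()].
#' @param dfe `NULL` (all mutations neutral) or a [dfe_params()] object
#'   for deleterious nonsynonymous mutations.
#' @param dominance A [dominance_model()].
#' @param balanced `NULL` or a [balanced_config()].
#' @param min_retained Minimum retained replicates per sampling time
#'   (balanced scenarios only).
#' @param max_batches Retry cap for topping up retained replicates.
#' @return An object of class `wf_sim`: a list with `samples` (one data
#'   frame per sampling time: `rep`, `pos`, `syn`, `balanced`, `p1`,
#'   `p2`), `times`, `retained` (replicate ids per time), `n_total`,
#'   `discards` (per time), `config` and the model objects.
#' @export
run_scenario <- function(config, locus = locus_structure(), dfe = NULL,
                         dominance = dominance_model(), balanced = NULL,
                         min_retained = NULL, max_batches = 20) {
  times <- config$sample_times
  samples <- vector("list", length(times))
  retained <- vector("list", length(times))
  n_total <- 0L
  batch <- 0L
  repeat {
    batch <- batch + 1L
    seed_b <- config$seed + (batch - 1L)
    sm <- run_batch(config, locus, dfe, dominance, balanced, seed_b,
                    rep_offset = n_total)
    all_reps <- n_total + seq_len(config$replicates)
    for (i in seq_along(times)) {
      samples[[i]] <- if (is.null(samples[[i]])) sm[[i]] else
        rbind(samples[[i]], sm[[i]])
      retained[[i]] <- c(retained[[i]],
                         retained_reps(sm[[i]], all_reps, balanced))
    }
    n_total <- n_total + config$replicates
    if (is.null(min_retained) || is.null(balanced)) break
    if (min(lengths(retained)) >= min_retained) break
    if (batch >= max_batches)
      stop("balanced polymorphism retention unattainable: only ",
           min(lengths(retained)), " replicates retained after ",
           batch, " batches")
  }
  names(samples) <- names(retained) <- format(times)
  structure(list(samples = samples, times = times, retained = retained,
                 n_total = n_total,
                 discards = n_total - lengths(retained),
                 config = config, locus = locus, dfe = dfe,
                 dominance = dominance, balanced = balanced,
                 n_batches = batch),
            class = "wf_sim")
}

#' @method print wf_sim
#' @export
print.wf_sim <- function(x, ...) {
  cat(sprintf("Wright-Fisher %s scenario: N = %d, %d replicates (%d batch%s)\n",
              x$config$mode, x$config$n_ancestral, x$n_total, x$n_batches,
              if (x$n_batches > 1) "es" else ""))
  cat(sprintf("sample times (N gens): %s\n",
              paste(format(x$times), collapse = ", ")))
  if (!is.null(x$balanced))
    cat(sprintf("balanced polymorphism: Ns_eq = %g; discards per time: %s\n",
                x$balanced$scaled_ns_at_eq,
                paste(x$discards, collapse = ", ")))
  invisible(x)
}

#' Convert a simulation snapshot into a site table
#'
#' Bridges simulator output into the site-classification machinery: each
#' segregating site becomes a biallelic A/T site record (an orientation
#' unaffected by GC-biased gene conversion), the replicate plays the role
#' of the gene, and the two daughter populations are named `pop1`, `pop2`.
#'
#' @param sample_df One element of a `wf_sim`'s `samples`.
#' @param reps Optional replicate ids to keep (e.g. the retained set).
#' @return A site table suitable for [classify_shared_private()], with the
#'   extra logical column `balanced`.
#' @export
sim_site_table <- function(sample_df, reps = NULL) {
  d <- sample_df
  if (!is.null(reps)) d <- d[d$rep %in% reps, , drop = FALSE]
  n <- nrow(d)
  data.frame(chrom = rep("sim", n), pos = d$pos, ref = rep("A", n),
             alt = rep("T", n),
             func_class = ifelse(d$syn, "synonymous", "nonsynonymous"),
             gene_id = d$rep, balanced = d$balanced,
             pop1 = d$p1, pop2 = d$p2)
}

#' Classify and bin one simulation snapshot
#'
#' Applies the shared/private classification and folded-MAF binning rules
#' to a simulation snapshot, restricted to the retained replicates.
#'
#' @param sample_df One element of a `wf_sim`'s `samples`.
#' @param focal `"pop1"` or `"pop2"`: the population whose private
#'   polymorphisms (and folding) are used.
#' @param reps Optional replicate ids to keep.
#' @param bin_width Folded-MAF bin width (default 0.1).
#' @return A list with `classified` (the classified site table) and
#'   `binned` (a [bin_by_frequency()] result).
#' @export
classify_sim_sites <- function(sample_df, focal = "pop1", reps = NULL,
                               bin_width = 0.1) {
  st <- sim_site_table(sample_df, reps)
  cl <- classify_shared_private(st, "pop1", "pop2", focal = focal)
  list(classified = cl, binned = bin_by_frequency(cl, bin_width = bin_width))
}
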