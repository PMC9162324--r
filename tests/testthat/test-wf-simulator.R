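test_that("gamma DFE draws have the stated mean and shape moments", {
  set.seed(61)
  expect_length(sample_dfe(dfe_human(), 0, n_e = 200), 0)
  s <- sample_dfe(dfe_human(), 1e6, n_e = 200)
  expect_true(all(s <= 0))
  nes <- 200 * abs(s)
  expect_equal(mean(nes), 425, tolerance = 0.01)
  # gamma CV^2 = 1/shape
  expect_equal(var(nes) / mean(nes)^2, 1 / 0.23, tolerance = 0.05)
  d <- sample_dfe(dfe_drosophila(), 2e5, n_e = 1000)
  expect_equal(mean(1000 * abs(d)), 1800, tolerance = 0.02)
})

test_that("selection-dependent dominance is anchored at h = 0.5 for neutral
           mutations and decays towards recessivity", {
  m <- dominance_model()
  expect_identical(huber_dominance(0, m), 0.5)
  expect_equal(huber_dominance(-0.001, m), 1 / (2 + 41.22556),
               tolerance = 1e-9)
  s <- -10^seq(-5, 2, by = 0.5)          # |s| increasing
  h <- huber_dominance(s, m)
  expect_true(all(diff(h) < 0))           # h decreasing in |s|
  expect_true(all(h > 0 & h <= 0.5))
  expect_lt(huber_dominance(-1e6, m), 1e-9)
  expect_equal(huber_dominance(c(-1, 0), dominance_model(fixed_h = 0.3)),
               c(0.3, 0.3))
})

test_that("frequency dependence gives a restoring force with a stable
           equilibrium", {
  expect_equal(nfds_selection(0.5, p_eq = 0.5), 0)
  expect_gt(nfds_selection(0.2, p_eq = 0.5), 0)
  expect_lt(nfds_selection(0.8, p_eq = 0.5), 0)
  expect_equal(nfds_selection(0, p_eq = 0.4, scaled_ns_at_eq = 20, n = 200),
               0.1)
  # long single-population runs hover at the equilibrium frequency; walkers
  # that drift to an absorbing boundary stay there (the restoring force
  # vanishes with p(1-p)), which is what the discard rule exists for, so
  # the stationarity check conditions on survival
  set.seed(71)
  n_dip <- 200L
  for (peq in c(0.3, 0.5, 0.7)) {
    nsite <- 200L
    st <- list(rep = seq_len(nsite), pos = seq_len(nsite),
               syn = rep(FALSE, nsite), s = numeric(nsite),
               h = rep(0.5, nsite), bal = rep(TRUE, nsite),
               peq = rep(peq, nsite), p1 = rep(peq, nsite),
               p2 = numeric(nsite))
    st <- balsel:::advance_single(st, 1500L, n_dip, mu = 0, lex = 1000L,
                                  dfe = NULL, dominance = dominance_model(),
                                  n_anc = n_dip, s0 = 20 / n_dip,
                                  nrep = nsite, mutate = FALSE)
    seg <- st$p1 > 0 & st$p1 < 1
    expect_gt(mean(seg), 0.15)
    expect_equal(mean(st$p1[seg]), peq, tolerance = 0.05 / peq)
  }
})

test_that("neutral heterozygosity decays at rate 1/(2N) per generation", {
  set.seed(81)
  n_dip <- 50L
  nsite <- 4000L
  st <- list(rep = seq_len(nsite), pos = seq_len(nsite),
             syn = rep(TRUE, nsite), s = numeric(nsite),
             h = rep(0.5, nsite), bal = rep(TRUE, nsite),  # bal blocks purging
             peq = rep(NA_real_, nsite), p1 = rep(0.5, nsite),
             p2 = numeric(nsite))
  st$bal <- rep(TRUE, nsite); st$peq <- rep(0.5, nsite)
  # neutral drift: make the "balanced" flag inert by zero restoring force
  ngen <- 40L
  st <- balsel:::advance_single(st, ngen, n_dip, mu = 0, lex = 5000L,
                                dfe = NULL, dominance = dominance_model(),
                                n_anc = n_dip, s0 = 0, nrep = nsite,
                                mutate = FALSE)
  het <- 2 * st$p1 * (1 - st$p1)
  expected <- 0.5 * (1 - 1 / (2 * n_dip))^ngen
  se <- stats::sd(het) / sqrt(nsite)
  expect_lt(abs(mean(het) - expected), 3 * se)
})

test_that("an NFDS-maintained allele persists an order of magnitude longer
           than a neutral one started at the same frequency", {
  set.seed(91)
  n_dip <- 100L
  nsite <- 300L
  mk <- function(s0_on) list(
    rep = seq_len(nsite), pos = seq_len(nsite), syn = rep(FALSE, nsite),
    s = numeric(nsite), h = rep(0.5, nsite), bal = rep(TRUE, nsite),
    peq = rep(0.5, nsite), p1 = rep(0.5, nsite), p2 = numeric(nsite))
  survival_median <- function(s0, max_gen = 6000L, step = 20L) {
    st <- mk()
    lost_at <- rep(NA_real_, nsite)
    g <- 0L
    while (g < max_gen && anyNA(lost_at)) {
      st <- balsel:::advance_single(st, step, n_dip, mu = 0, lex = 1000L,
                                    dfe = NULL,
                                    dominance = dominance_model(),
                                    n_anc = n_dip, s0 = s0, nrep = nsite,
                                    mutate = FALSE)
      g <- g + step
      gone <- is.na(lost_at) & (st$p1 == 0 | st$p1 == 1)
      lost_at[gone] <- g
      if (mean(!is.na(lost_at)) > 0.55 && s0 == 0) break
    }
    # sites still segregating at the horizon are right-censored
    stats::median(ifelse(is.na(lost_at), Inf, lost_at))
  }
  med_neutral <- survival_median(0)
  med_nfds <- survival_median(20 / n_dip)
  expect_true(is.finite(med_neutral))
  # median persistence under NFDS exceeds 10x the neutral median (censoring
  # at the run horizon only strengthens the claim)
  expect_gt(med_nfds, 10 * med_neutral)
})

test_that("population splits conserve or copy allele counts as the mode
           demands", {
  set.seed(101)
  n <- 100L
  st <- list(rep = 1:50, pos = 1:50, syn = rep(TRUE, 50), s = numeric(50),
             h = rep(0.5, 50), bal = rep(FALSE, 50), peq = rep(NA_real_, 50),
             p1 = round(runif(50, 1, 199)) / 200, p2 = numeric(50))
  dup <- balsel:::split_population(st, "duplication", n, n, n)
  expect_identical(dup$p2, dup$p1)
  vic <- balsel:::split_population(st, "vicariance", n, 75L, 25L)
  # alleles divided without replacement: counts sum to the ancestral count
  expect_equal(vic$p1 * 150 + vic$p2 * 50, st$p1 * 200)
  dis <- balsel:::split_population(st, "dispersal", n, n, 25L)
  expect_identical(dis$p1, st$p1)
  expect_true(all(dis$p2 >= 0 & dis$p2 <= 1))
})

test_that("simulation snapshots flow through the site classifier", {
  empty <- data.frame(rep = integer(0), pos = integer(0),
                      syn = logical(0), balanced = logical(0),
                      p1 = numeric(0), p2 = numeric(0))
  b0 <- classify_sim_sites(empty)$binned
  expect_equal(sum(unclass(b0$total)), 0)

  hand <- data.frame(
    rep = 1L, pos = 1:9,
    syn = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    balanced = FALSE,
    p1 = c(0.4, 0.3, 0.2, 0.1, 0.1, 0.2, 0.3, 0.2, 0.1),
    p2 = c(0.5, 0.1, 0.6, 0, 0, 0, 0, 0, 0))
  b <- classify_sim_sites(hand)$binned
  expect_equal(unname(unclass(b$total)), c(2, 1, 3, 3))
})

test_that("migration erodes the private fraction of polymorphisms", {
  rho_at <- function(m, seed) {
    cfg <- scenario_config("duplication", n_ancestral = 100,
                           migration_rate = m, theta_factor = 300,
                           sample_times = 1, replicates = 300, seed = seed)
    sim <- run_scenario(cfg)
    cl <- classify_sim_sites(sim$samples[[1]])$classified
    use <- cl$in_focal_set
    sum(cl$category[use] != "shared") / sum(use)
  }
  rhos <- vapply(c(0, 0.01, 0.1), rho_at, numeric(1), seed = 111)
  expect_true(all(diff(rhos) < 0))
})

test_that("replicates that lose the balanced polymorphism are discarded and
           the retained ones all carry it in both populations", {
  cfg <- scenario_config("duplication", n_ancestral = 100,
                         theta_factor = 100, sample_times = c(0.2, 1),
                         replicates = 150, seed = 121)
  sim <- run_scenario(cfg, locus_structure(), dfe = NULL,
                      balanced = balanced_config(), min_retained = 150)
  expect_gte(min(lengths(sim$retained)), 150)
  expect_equal(sim$discards, sim$n_total - lengths(sim$retained))
  for (i in seq_along(sim$times)) {
    s <- sim$samples[[i]]
    keep <- sim$retained[[i]]
    seg_both <- s$balanced & s$p1 > 0 & s$p1 < 1 & s$p2 > 0 & s$p2 < 1
    expect_setequal(intersect(unique(s$rep[seg_both]), keep), keep)
  }
  # an impossible retention demand fails loudly
  cfg2 <- scenario_config("duplication", n_ancestral = 50, theta_factor = 10,
                          sample_times = 1, replicates = 5, seed = 131)
  expect_error(
    run_scenario(cfg2, locus_structure(), balanced =
                   balanced_config(eq_freq_distribution =
                                     function(n) rep(0.004, n)),
                 min_retained = 5, max_batches = 2),
    "retention")
})
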