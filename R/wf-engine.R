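# Internal Wright-Fisher engine.
#
# All replicates of a scenario are advanced in lockstep: the state holds one
# row per segregating site per replicate, as parallel vectors, and every
# generation applies selection, migration, binomial drift, mutation influx
# and purging as vectorised operations across the whole cohort. Sites evolve
# as independent biallelic loci (linkage equilibrium across sites; see the
# methods vignette).

st_new <- function() {
  list(rep = integer(0), pos = integer(0), syn = logical(0),
       s = numeric(0), h = numeric(0), bal = logical(0),
       peq = numeric(0), p1 = numeric(0), p2 = numeric(0))
}

st_subset <- function(st, keep) {
  lapply(st, `[`, keep)
}

st_bind <- function(st, add) {
  Map(c, st, add)
}

# Post-selection expected frequency for genotype fitnesses 1, 1+hs, 1+s
# (derived allele at frequency p). Balanced sites use the NFDS coefficient
# s(p) = s0*(1 - p/peq) with h = 0.5. Fitnesses are clamped at zero, so
# draws with s < -1 act as recessive-scaled lethals.
sel_freq <- function(p, s, h, bal, peq, s0) {
  if (any(bal)) {
    sb <- s0 * (1 - p[bal] / peq[bal])
    s <- `[<-`(s, bal, sb)
    h <- `[<-`(h, bal, 0.5)
  }
  sel <- s != 0
  if (!any(sel)) return(p)
  ps <- p[sel]; ss <- s[sel]; hs <- h[sel]
  w2 <- pmax(0, 1 + ss)
  w1 <- pmax(0, 1 + hs * ss)
  q <- 1 - ps
  wbar <- ps * ps * w2 + 2 * ps * q * w1 + q * q
  out <- p
  out[sel] <- ifelse(wbar > 0, (ps * ps * w2 + ps * q * w1) / wbar, 0)
  out
}

# New mutations entering one population: Poisson number per replicate,
# uniform position over the exonic sites, class by codon offset (third
# positions synonymous, giving a 2:1 nonsynonymous:synonymous ratio),
# selection coefficients from the DFE for nonsynonymous sites. A mutation
# hitting an already-segregating site is redrawn once and dropped if it
# still collides (finite-sites biallelic model; occupancy is low).
st_mutate <- function(st, nrep, two_n, mu, lex, dfe, dominance, n_anc,
                      pop = 1L) {
  lambda <- two_n * mu * lex
  k <- stats::rpois(nrep, lambda)
  total <- sum(k)
  if (total == 0L) return(st)
  rep_id <- rep.int(seq_len(nrep), k)
  pos <- sample.int(lex, total, replace = TRUE)
  key <- rep_id * (lex + 1L) + pos
  exist <- st$rep * (lex + 1L) + st$pos
  clash <- (key %in% exist) | duplicated(key)
  if (any(clash)) {
    pos[clash] <- sample.int(lex, sum(clash), replace = TRUE)
    key <- rep_id * (lex + 1L) + pos
    clash <- (key %in% exist) | duplicated(key)
    if (any(clash)) {
      rep_id <- rep_id[!clash]; pos <- pos[!clash]
    }
  }
  n <- length(pos)
  if (n == 0L) return(st)
  syn <- pos %% 3L == 0L
  s <- numeric(n)
  if (!is.null(dfe) && any(!syn))
    s[!syn] <- sample_dfe(dfe, sum(!syn), n_e = n_anc)
  h <- rep(0.5, n)
  if (any(s != 0)) h[s != 0] <- huber_dominance(s[s != 0], dominance)
  p_new <- 1 / two_n
  add <- list(rep = rep_id, pos = pos, syn = syn, s = s, h = h,
              bal = rep(FALSE, n), peq = rep(NA_real_, n),
              p1 = if (pop == 1L) rep(p_new, n) else numeric(n),
              p2 = if (pop == 2L) rep(p_new, n) else numeric(n))
  st_bind(st, add)
}

# Advance a single (pre-split) population `ngen` generations.
advance_single <- function(st, ngen, n_dip, mu, lex, dfe, dominance, n_anc,
                           s0, nrep, mutate = TRUE) {
  two_n <- 2L * n_dip
  for (g in seq_len(ngen)) {
    ps <- sel_freq(st$p1, st$s, st$h, st$bal, st$peq, s0)
    st$p1 <- stats::rbinom(length(ps), two_n, ps) / two_n
    keep <- st$bal | (st$p1 > 0 & st$p1 < 1)
    if (!all(keep)) st <- st_subset(st, keep)
    if (mutate)
      st <- st_mutate(st, nrep, two_n, mu, lex, dfe, dominance, n_anc,
                      pop = 1L)
  }
  st
}

# Advance the two descendant populations `ngen` generations. n1, n2 are
# scalars or per-generation vectors (expansion); m is the per-generation
# symmetric migration fraction.
advance_two <- function(st, ngen, n1, n2, m, mu, lex, dfe, dominance, n_anc,
                        s0, nrep, mutate = TRUE) {
  n1 <- rep_len(n1, ngen); n2 <- rep_len(n2, ngen)
  for (g in seq_len(ngen)) {
    a1 <- 2L * n1[g]; a2 <- 2L * n2[g]
    p1s <- sel_freq(st$p1, st$s, st$h, st$bal, st$peq, s0)
    p2s <- sel_freq(st$p2, st$s, st$h, st$bal, st$peq, s0)
    if (m > 0) {
      p1m <- (1 - m) * p1s + m * p2s
      p2m <- (1 - m) * p2s + m * p1s
      p1s <- p1m; p2s <- p2m
    }
    st$p1 <- stats::rbinom(length(p1s), a1, p1s) / a1
    st$p2 <- stats::rbinom(length(p2s), a2, p2s) / a2
    keep <- st$bal | (st$p1 > 0 & st$p1 < 1) | (st$p2 > 0 & st$p2 < 1)
    if (!all(keep)) st <- st_subset(st, keep)
    if (mutate) {
      st <- st_mutate(st, nrep, a1, mu, lex, dfe, dominance, n_anc, pop = 1L)
      st <- st_mutate(st, nrep, a2, mu, lex, dfe, dominance, n_anc, pop = 2L)
    }
  }
  st
}

# Split the ancestral population into two daughters.
split_population <- function(st, mode, n_anc, n1, n2) {
  two_n <- 2L * n_anc
  cnt <- round(st$p1 * two_n)
  if (mode == "duplication") {
    st$p2 <- st$p1
  } else if (mode == "vicariance") {
    a1 <- 2L * n1; a2 <- 2L * n2
    c1 <- stats::rhyper(length(cnt), m = cnt, n = two_n - cnt, k = a1)
    st$p1 <- c1 / a1
    st$p2 <- (cnt - c1) / a2
  } else if (mode == "dispersal") {
    a2 <- 2L * n2
    st$p2 <- stats::rbinom(length(cnt), a2, st$p1) / a2
  } else stop("unknown split mode: ", mode)
  st
}
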