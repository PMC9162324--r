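---
title: "Methods: the shared-vs-private polymorphism test for balancing selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the shared-vs-private polymorphism test for balancing selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(balsel)
```

## The test

Balancing selection maintains polymorphism, and polymorphisms it maintains
persist far longer than neutral or deleterious variants. A balanced
polymorphism that predates the split of an ancestral population into two
descendants is therefore disproportionately likely to still segregate in
*both* descendants, while ordinary variants drift in and out of each
population independently. `balsel` exploits this: classify biallelic SNPs
in a two-population comparison as *shared* (segregating in both) or
*private* (segregating in exactly one), count nonsynonymous and synonymous
polymorphisms in each class, and form

$$Z = \frac{S_N / S_S}{R_N / R_S},$$

where $S_N, S_S$ are shared nonsynonymous/synonymous counts and $R_N, R_S$
the private ones. Synonymous sites calibrate the mutational input in each
class, so under any model in which nonsynonymous variants are neutral or
deleterious, $Z \le 1$: purifying selection makes nonsynonymous variants
younger and *less* likely to be shared, never more. $Z > 1$ requires a
force that preferentially preserves nonsynonymous polymorphism across the
split — balancing selection. That deleterious segregation pushes $Z$
*down* is what makes the test conservative: demographic history moves
shared and private classes together and cancels in the double ratio.

Under a simple model in which $b$ balanced nonsynonymous polymorphisms
(each dragging $x$ neutral hitchhikers) are added to a neutral/deleterious
background, the four expected counts are (see `expected_counts()`)

$$R_S = \theta\rho W,\quad R_N = \theta\rho W f,\quad
  S_S = \theta(1-\rho)W + bx,\quad S_N = \theta(1-\rho)Wf + b + bxf,$$

with $\theta$ the scaled mutation rate, $\rho$ the private proportion,
$W$ Watterson's coefficient and $f$ the neutral fraction of nonsynonymous
mutations. Substituting gives the estimator

$$\alpha_b = 1 - \frac{1}{Z} = 1 - \frac{S_S R_N}{S_N R_S} = \frac{b}{S_N},$$

the proportion of shared nonsynonymous polymorphisms directly maintained
by balancing selection, and $b = \alpha_b S_N$ their number. The identity
$\alpha_b(\text{expected counts}) = b/S_N$ holds exactly for every valid
parameter combination; the test suite verifies it to machine precision
over 1,000 random draws. $W$ is treated as a supplied dimensionless
factor: it cancels from $Z$ and $\alpha_b$, so nothing depends on an
operational definition. $\alpha_b$ is negative whenever $Z < 1$ (the
deleterious-load regime); it is always reported unclamped, and only the
display ratio in the recovery experiment truncates at zero.

## Site classification rules

* A site is polymorphic in a population when its alt-allele frequency is
  strictly between 0 and 1 in that sample. Fixed differences and
  monomorphic sites enter no cell.
* Frequencies use the folded spectrum, `fold_maf(f) = min(f, 1 - f)`;
  ancestral-state inference is deliberately avoided because polarisation
  errors concentrate in the high-frequency bins the test cares most about.
* The folded MAF of a *shared* polymorphism is taken in the focal
  population — the population supplying the private polymorphisms — so
  both classes are measured on the same sample. Private polymorphisms of
  the other population are excluded from that focal analysis set.
* Bins are half-open, `(lo, hi]`, width 0.1 over (0, 0.5]. A MAF of
  exactly 0.1 falls in the lowest bin and is excluded from the pooled
  "> 0.1" set (the pooling criterion is strict inequality); a MAF of 0.5
  falls in the top bin.
* Only `nonsynonymous` and `synonymous` sites enter tables; anything else
  (`other`) is dropped. Indels, multinucleotide and multiallelic records
  are removed at read time with logged counts.
* The GC-biased gene conversion control keeps only A↔T and G↔C
  mutations, whose alleles have equal GC content.
* The recombination split partitions *genes* (per-gene mean rate) at the
  median, ties to the low partition; gene-set pooling flags sets with
  fewer than 100 polymorphisms above MAF 0.1 rather than dropping them.
  Both thresholds (20 per cell for bin display, 100 per set) are
  arguments, defaulting to the conventional values.
* Shared status requires the same ref/alt pair in both populations; the
  input contract is a single biallelic record per site carrying one
  frequency per population.

## Significance machinery

Pooled tables use Pearson's chi-squared test of independence without the
Yates correction (`correct = TRUE` is available); the pooled counts the
test is meant for are large enough that the correction is second-order.
Single genes use a one-tailed Fisher exact test in the direction $Z > 1$
(an excess of $S_N$ given the margins); both are checked in the test
suite against a closed-form Pearson oracle and exhaustive enumeration of
tables with fixed margins.

Confidence intervals come from a gene-level bootstrap: genes are resampled
with replacement, the four cells re-summed, and the statistic recomputed;
resampling whole genes encompasses all sub-gene sources of variance
(site-level sampling and within-gene linkage). Intervals are percentile
intervals at level 0.95 with 100 replicates by default — the interval
type is our choice, the level and replicate count the conventional ones —
and the standard error is the SD of replicate statistics. Replicates with
a zero cell are dropped and counted, not imputed; `zb_test()` reports the
drop count.

## The simulator

`run_scenario()` implements discrete-generation Wright–Fisher dynamics
for a cohort of replicate loci: an ancestral diploid population of
$N = 200$ equilibrates for $15N$ generations, optionally acquires a
balanced polymorphism $5N$ generations before the split, then splits by
duplication, vicariance or dispersal; daughters may expand exponentially
(to 2–10× over a $21N$ horizon) and exchange migrants at a
per-generation fraction $m$.

Key design choices:

* **Sites evolve independently** (linkage equilibrium; free
  recombination). Every segregating site follows its own biallelic WF
  process with genotype fitnesses $1,\ 1+hs,\ 1+s$ (multiplicative across
  sites, fitnesses clamped at zero, so $s < -1$ acts as a recessive-scaled
  lethal), selection then binomial resampling of $2N$ alleles. At the
  default parameters the per-locus recombination rate is so low that real
  loci are nearly fully linked; the linkage-equilibrium engine therefore
  does not emulate hitchhiking (the $x$ term of the analytic model) or
  associative overdominance, and this is the main respect in which its
  output is idealised relative to haplotype-level simulation. The
  frequency trajectories that the $Z$ statistic consumes — ages and
  sharing of individual variants under selection, drift, splits and
  migration — are the marginal dynamics and are captured exactly.
* **Mutation** is finite-sites biallelic: a Poisson number
  ($2N\mu L_{ex}$) of new singleton mutations per population per
  generation, uniform over exonic positions; a mutation hitting an
  already-segregating site is redrawn once and otherwise dropped
  (occupancy is a few percent at the scales used). Codon third positions
  are synonymous, offsets 1–2 nonsynonymous — a deterministic 2:1 ratio,
  configurable through the position rule. Intronic sites are neutral,
  never tabulated, and (being independent) cannot influence exonic
  trajectories, so they are not simulated at all; the gene-shaped locus
  (9 × 288 bp exons, 8 × 5,419 bp introns) keeps introns as bookkeeping.
* **Deleterious effects**: nonsynonymous mutations draw $N_e|s|$ from a
  gamma distribution — human preset shape 0.23, mean 425; Drosophila
  0.35, 1800 — de-scaled by the *ancestral* $N$. Dominance follows the
  selection-dependent model $h(s) = 1/(1/\theta_{int} - \theta_{rate} s)$
  with $\theta_{int} = 0.5$ (neutral mutations codominant) and
  $\theta_{rate} = 41225.56$, so strongly deleterious mutations are
  nearly recessive; a fixed $h$ can override it.
* **Balancing selection** is negative frequency dependence: the balanced
  allele experiences $s(p) = s_0(1 - p/p_{eq})$ with $h = 0.5$,
  equilibrium frequency $p_{eq} \sim U(0,1)$ per replicate and
  $N s_0 = 20$. This realises "scaled strength 20 at equilibrium" as the
  restoring force anchored at $s(p_{eq}) = 0$; the exact functional form
  behind that scaled strength is a stated modelling choice. Because the
  force scales with $p(1-p)$ it vanishes at the boundaries, so walkers
  with extreme equilibria are eventually absorbed — lost for low
  $p_{eq}$, fixed for high — which is precisely why the retention rule
  exists. The polymorphism is introduced *at* its equilibrium frequency
  (introducing it as a singleton would discard the large majority of
  replicates before the split without changing the conditional state 5N
  generations later), placed at the centre of each exon, bumped off codon
  third positions so it is always nonsynonymous.
* **Retention**: at each sampling time, replicates in which the balanced
  polymorphism no longer segregates in both populations are discarded;
  `min_retained` tops the cohort up with fresh-seeded batches and errors
  out after `max_batches`. Discard counts are reported. The surviving
  $p_{eq}$ distribution is consequently biased toward intermediate
  frequencies, which is a property of the study design, not an artefact.
* **Reproducibility**: one seed per scenario; batch $k$ uses
  `seed + (k - 1)`. The recovery experiment derives the seed of its
  no-balancing arm as `seed + 500000`.

### Desk-scale conditions

The study conditions (N = 200, burn-in 15N, intro 5N pre-split, human
$\mu = 2.5\times10^{-8}$, $r = 1.1\times10^{-8}$) give a per-locus
$\theta$ so small that millions of replicates are needed for stable
pooled counts. Instead of replicating that compute, `theta_factor`
inflates $\mu$ alone — selection parameters, which are specified on the
$N s$ scale, are untouched — and replicate counts of $10^3$–$10^4$ then
give pooled cells in the thousands. The sizes used by the shipped
experiments are: neutral and DFE-only duplication and the demographic
sweeps at `theta_factor = 300` with 1,000–5,000 replicates; scenarios
containing a balanced polymorphism at `theta_factor = 100` with
1,200–2,000 retained replicates (the lower factor keeps the background
from diluting the single balanced site per locus, and the replicate
counts keep Monte-Carlo standard errors several times below the
tolerances being checked). A `rescale_factor` is also available; it
divides $N$ and multiplies $\mu$ jointly, inflating $s$ implicitly
through the $Ns$ parameterisation.

Pooled statistics are always **ratios of summed counts** across
replicates, never means of per-replicate ratios (which are biased for
ratio statistics); Monte-Carlo standard errors bootstrap whole
replicates, mirroring the gene-level bootstrap on real data.

## The fixture generator

`generate_fixture()` emits a deterministic VCF + population map +
annotation whose classify→bin→count output equals a requested per-bin
table exactly: sites are placed at bin-centre frequencies that are exact
multiples of $1/2n$ for the chosen sample size, shared sites segregate at
0.5 in the non-focal population, and ref/alt pairs alternate A/T and C/G
so the BGC filter is a no-op. It emulates the *bookkeeping* of
1000-Genomes-style two-population data (biallelic SNPs, genotype-derived
frequencies, per-site functional annotation), not its population
genetics: frequencies are placed, not drifted, and there is no LD, no
sample-size variation and no missingness beyond what a test injects. A
green fixture pipeline therefore validates classification, binning and
IO arithmetic — inference behaviour on realistic data is what the WF
simulator experiments are for. Simulation snapshots are labelled A/T for
the same reason and carry the replicate as the "gene", making the
discard/bootstrap units explicit.

## Numerical and degenerate-input conventions

* `compute_z`/`compute_alpha_b` raise an error naming the offending zero
  cell rather than returning `Inf`/`NaN`; pooled experiment tables report
  such bins as missing.
* The Fisher test returns $p = 1$ on degenerate tables (an empty row or
  column); the chi-squared test refuses them.
* Bootstrap replicates with undefined statistics are dropped and counted;
  an all-undefined bootstrap is an error.
* Vicariance divides allele copies without replacement (hypergeometric),
  duplication copies them, dispersal samples them binomially; expansion
  rounds $N_0 m^{t/(21N)}$ to integers.
* Equilibrium initial counts are clamped to $[1, 2N-1]$ copies.
* Ties at the median recombination rate go to the low partition, so
  uniform-rate data are all "low".

## Limitations

* The engine's linkage-equilibrium assumption excludes hitchhiking and
  associative overdominance; $x > 0$ scenarios of the analytic model have
  no simulated counterpart.
* No ancestral-state polarisation, LD computation, annotation from
  sequence, or multiple-testing machinery beyond reporting Bonferroni
  thresholds is provided.
* The demography schema covers the generic split scenarios; published
  multi-population human models are encodable in principle but ship
  untested.
* Real-data applications at the scale of full variation panels (the
  regime where $Z$ is near 1 and $\alpha_b$ of a few percent is
  detectable) are out of scope for the shipped experiments, which operate
  at rescaled $\theta$.
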