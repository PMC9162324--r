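# Classification of two-population SNP data into shared/private categories,
# folded-MAF bins and stratified count tables.

#' Validate a table of biallelic SNP site records
#'
#' A site table is an ordinary data frame with one row per biallelic SNP
#' and columns `chrom`, `pos` (1-based), `ref`, `alt` (single nucleotides),
#' `func_class` (`"nonsynonymous"`, `"synonymous"` or `"other"`),
#' `gene_id`, one numeric column of alt-allele frequencies per population
#' (named by the population label), and optionally `recomb_rate`.
#'
#' @param sites Data frame of site records.
#' @param pops Character vector of population column names that must be
#'   present.
#' @return The validated data frame (invisibly usable in a pipeline).
#' @export
site_records <- function(sites, pops = character()) {
  need <- c("chrom", "pos", "ref", "alt", "func_class", "gene_id", pops)
  miss <- setdiff(need, names(sites))
  if (length(miss))
    stop("site table is missing column(s): ", paste(miss, collapse = ", "))
  nt <- c("A", "C", "G", "T")
  bad <- !(sites$ref %in% nt) | !(sites$alt %in% nt) | sites$ref == sites$alt
  if (any(bad))
    stop(sum(bad), " site(s) have invalid or identical ref/alt alleles")
  for (p in pops) {
    f <- sites[[p]]
    if (any(f < 0 | f > 1, na.rm = TRUE))
      stop("frequencies in population '", p, "' fall outside [0, 1]")
  }
  sites
}

#' Fold an allele frequency onto the minor-allele scale
#'
#' `fold_maf(f) = min(f, 1 - f)`: the folded site frequency spectrum is
#' used throughout because ancestral-state misinference (CpG hypermutation,
#' context-independent rate variation) inflates the apparent high-frequency
#' derived class; folding avoids polarisation entirely.
#'
#' @param freq Allele frequency (vectorised), each in \[0,1\].
#' @return Folded minor-allele frequency in \[0, 0.5\].
#' @export
fold_maf <- function(freq) {
  if (any(freq < 0 | freq > 1, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  pmin(freq, 1 - freq)
}

#' Classify sites as shared or private between two populations
#'
#' A site is *shared* when it segregates (0 < alt frequency < 1) in both
#' populations, *private* to a population when it segregates there only,
#' a *fixed difference* when the populations are fixed for different
#' alleles, and *monomorphic* otherwise. The folded minor-allele frequency
#' is computed in the focal population — the population from which the
#' private polymorphisms are drawn — for both shared and focal-private
#' sites, so that shared and private spectra are measured on the same
#' sample. Sites with a missing frequency are rejected and the rejection
#' reasons recorded in the `"rejected"` attribute.
#'
#' @param sites Site table (see [site_records()]).
#' @param pop1,pop2 Names of the two population frequency columns.
#' @param focal Focal population; one of `pop1`, `pop2` (default `pop1`).
#' @return The site table with added columns `category`, `focal_maf`, and
#'   `in_focal_set` (`TRUE` for shared and focal-private polymorphisms,
#'   the rows that enter count tables). Attributes: `focal`, `rejected`.
#' @export
classify_shared_private <- function(sites, pop1, pop2, focal = pop1) {
  site_records(sites, pops = c(pop1, pop2))
  if (!focal %in% c(pop1, pop2))
    stop("focal must be one of pop1, pop2")
  f1 <- sites[[pop1]]
  f2 <- sites[[pop2]]
  ok <- !is.na(f1) & !is.na(f2)
  rejected <- data.frame(reason = "missing frequency", n = sum(!ok))
  sites <- sites[ok, , drop = FALSE]
  f1 <- f1[ok]; f2 <- f2[ok]
  seg1 <- f1 > 0 & f1 < 1
  seg2 <- f2 > 0 & f2 < 1
  category <- rep("monomorphic", length(f1))
  category[seg1 & seg2] <- "shared"
  category[seg1 & !seg2] <- "private_pop1"
  category[!seg1 & seg2] <- "private_pop2"
  category[!seg1 & !seg2 & (abs(f1 - f2) == 1)] <- "fixed_difference"
  ff <- if (focal == pop1) f1 else f2
  private_focal <- if (focal == pop1) "private_pop1" else "private_pop2"
  in_focal <- category == "shared" | category == private_focal
  focal_maf <- ifelse(in_focal, fold_maf(ff), NA_real_)
  out <- cbind(sites, category = category, focal_maf = focal_maf,
               in_focal_set = in_focal)
  attr(out, "focal") <- focal
  attr(out, "rejected") <- rejected
  out
}

#' Restrict to mutations unaffected by GC-biased gene conversion
#'
#' GC-biased gene conversion favours G/C over A/T alleles in recombining
#' regions and can mimic selection; A<->T and G<->C mutations are immune
#' because both alleles have the same GC content. Keeps only sites whose
#' unordered `{ref, alt}` pair is `{A,T}` or `{C,G}`.
#'
#' @param sites Site table.
#' @return The filtered site table.
#' @export
bgc_filter <- function(sites) {
  pair <- paste(pmin(sites$ref, sites$alt), pmax(sites$ref, sites$alt))
  sites[pair %in% c("A T", "C G"), , drop = FALSE]
}

empty_counts <- function() poly_counts(0, 0, 0, 0)

count_table <- function(classified) {
  sh <- classified$category == "shared"
  ns <- classified$func_class == "nonsynonymous"
  sy <- classified$func_class == "synonymous"
  pr <- classified$in_focal_set & !sh
  poly_counts(sum(sh & ns), sum(sh & sy), sum(pr & ns), sum(pr & sy))
}

#' Bin classified sites by folded minor-allele frequency
#'
#' Sites in the focal analysis set (shared and focal-private) with
#' `func_class` nonsynonymous or synonymous are tabulated into
#' [poly_counts()] tables per folded-MAF bin. Bins are half-open intervals
#' `(lo, hi]` of width `bin_width` covering (0, 0.5]; with the default
#' width 0.1 the bins are (0,0.1], (0.1,0.2], ..., (0.4,0.5]. A pooled
#' table for all sites with focal MAF strictly above 0.1 is also returned
#' (a MAF of exactly 0.1 falls in the lowest bin and is excluded from the
#' pooled set).
#'
#' @param classified Output of [classify_shared_private()].
#' @param bin_width Bin width; must divide 0.5 evenly (default 0.1).
#' @return An object of class `binned_counts`: a list with `bin_edges`,
#'   `per_bin` (named list of [poly_counts()]), `combined_above` (the
#'   pooled MAF > 0.1 table), `total` (unbinned table) and `flagged`
#'   (filled by [apply_min_count_filter()]).
#' @export
bin_by_frequency <- function(classified, bin_width = 0.1) {
  nb <- 0.5 / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_width must divide 0.5 evenly")
  nb <- as.integer(round(nb))
  edges <- seq(0, 0.5, by = bin_width)
  use <- classified$in_focal_set &
    classified$func_class %in% c("nonsynonymous", "synonymous")
  d <- classified[use, , drop = FALSE]
  # (lo, hi] bins; MAF 0 would be non-segregating and cannot occur here
  idx <- findInterval(d$focal_maf, edges, left.open = TRUE, rightmost.closed = TRUE)
  per_bin <- lapply(seq_len(nb), function(i)
    count_table(d[idx == i, , drop = FALSE]))
  names(per_bin) <- sprintf("(%.2g,%.2g]", edges[-length(edges)], edges[-1])
  combined <- count_table(d[d$focal_maf > 0.1, , drop = FALSE])
  structure(list(bin_edges = edges, per_bin = per_bin,
                 combined_above = combined, total = count_table(d),
                 flagged = rep(FALSE, nb)),
            class = "binned_counts")
}

#' @method print binned_counts
#' @export
print.binned_counts <- function(x, ...) {
  m <- t(vapply(x$per_bin, unclass, numeric(4)))
  m <- rbind(m, `>0.1 pooled` = unclass(x$combined_above),
             total = unclass(x$total))
  flag <- c(ifelse(x$flagged, "*", ""), "", "")
  cat("Counts per folded-MAF bin (s_n, s_s, r_n, r_s):\n")
  print(cbind(as.data.frame(m), flagged = flag))
  if (any(x$flagged))
    cat("* bin flagged unreliable by the minimum-count filter\n")
  invisible(x)
}

#' Flag frequency bins with too few polymorphisms
#'
#' Bins where any of the four cells falls below `min_polymorphisms` are
#' flagged as unreliable (they are retained, not deleted); ratio statistics
#' on sparse tables are unstable and are conventionally not displayed.
#'
#' @param binned A [bin_by_frequency()] result.
#' @param min_polymorphisms Minimum count required in every cell
#'   (default 20).
#' @return The `binned_counts` object with its `flagged` vector updated.
#' @export
apply_min_count_filter <- function(binned, min_polymorphisms = 20) {
  if (min_polymorphisms < 0) stop("min_polymorphisms must be >= 0")
  binned$flagged <- vapply(binned$per_bin, function(b)
    any(unclass(b) < min_polymorphisms), logical(1))
  binned
}

#' Split genes at the median recombination rate
#'
#' Genes (not sites) are partitioned at the median gene-level recombination
#' rate; every site follows its gene. Genes at or below the median go to
#' the low partition, so a data set with uniform rates is all "low". Genes
#' without a rate are excluded and reported.
#'
#' @param sites Site table with a `gene_id` column.
#' @param gene_rates Optional named numeric vector (gene -> rate). If
#'   omitted, per-gene mean of the sites' `recomb_rate` column is used.
#' @return A list with `low` and `high` site tables, `median` (the split
#'   point) and `excluded` (genes lacking a rate).
#' @export
split_by_recombination <- function(sites, gene_rates = NULL) {
  if (is.null(gene_rates)) {
    if (!"recomb_rate" %in% names(sites))
      stop("supply gene_rates or a recomb_rate column")
    gene_rates <- tapply(sites$recomb_rate, sites$gene_id,
                         mean, na.rm = TRUE)
  }
  genes <- unique(as.character(sites$gene_id))
  rates <- gene_rates[genes]
  excluded <- genes[is.na(rates)]
  known <- genes[!is.na(rates)]
  med <- stats::median(rates[!is.na(rates)])
  low_genes <- known[rates[known] <= med]
  list(low = sites[sites$gene_id %in% low_genes, , drop = FALSE],
       high = sites[sites$gene_id %in% setdiff(known, low_genes), ,
                    drop = FALSE],
       median = med, excluded = excluded)
}

#' Pool classified sites by gene set
#'
#' Builds one binned count table per gene set (e.g. HLA genes, GO
#' categories). Sets with fewer than `min_polys_above_01` polymorphisms at
#' focal MAF > 0.1 (shared plus focal-private, both functional classes)
#' are flagged: ratio estimates on smaller sets are too noisy to interpret.
#' Complement sets ("all genes not in X") can be requested.
#'
#' @param classified Output of [classify_shared_private()].
#' @param set_map Data frame with columns `gene_id`, `set_id` (a gene may
#'   belong to several sets).
#' @param min_polys_above_01 Minimum number of MAF > 0.1 polymorphisms for
#'   a set to be considered reliable (default 100).
#' @param complement Character vector of set ids for which the complement
#'   set (`"non_<set>"`) should also be returned.
#' @param bin_width Passed to [bin_by_frequency()].
#' @return Named list of `binned_counts`, one per set, each with attribute
#'   `flagged_set` (`TRUE` if below the polymorphism minimum).
#' @export
group_by_gene_set <- function(classified, set_map, min_polys_above_01 = 100,
                              complement = character(), bin_width = 0.1) {
  sets <- split(as.character(set_map$gene_id), as.character(set_map$set_id))
  for (s in complement)
    sets[[paste0("non_", s)]] <-
      setdiff(unique(as.character(classified$gene_id)), sets[[s]])
  out <- lapply(sets, function(genes) {
    sub <- classified[classified$gene_id %in% genes, , drop = FALSE]
    b <- bin_by_frequency(sub, bin_width = bin_width)
    n_above <- sum(unclass(b$combined_above))
    attr(b, "flagged_set") <- n_above < min_polys_above_01
    attr(b, "n_above_01") <- n_above
    b
  })
  out
}
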