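# Readers, writers and the deterministic fixture generator.

#' Read two-population SNP data from a VCF plus annotation
#'
#' Reads a VCF (v4.x), keeps biallelic SNPs only (indels, multinucleotide
#' polymorphisms and multiallelic records are dropped, with per-reason
#' counts in the `"drops"` attribute), computes per-population alt-allele
#' frequencies from the genotypes (allele count / called alleles; missing
#' genotypes reduce the denominator), and joins the per-site annotation
#' table on `chrom, pos, ref, alt`. If the VCF has no genotype columns,
#' per-population frequencies are taken from INFO fields named
#' `AF_<pop>`.
#'
#' @param vcf_path Path to the VCF file.
#' @param pop_map_path TSV with columns `sample`, `pop` assigning each
#'   sample column to a population.
#' @param annotation_path TSV keyed by `chrom, pos, ref, alt` with columns
#'   `func_class`, `gene_id` and optionally `recomb_rate`.
#' @param strict Fail instead of skip-and-log on unannotated sites.
#' @return A site table (see [site_records()]) with one frequency column
#'   per population and attribute `drops` (named integer vector of
#'   per-reason drop counts).
#' @export
read_sites <- function(vcf_path, pop_map_path, annotation_path,
                       strict = FALSE) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  pop_map <- utils::read.delim(pop_map_path, stringsAsFactors = FALSE,
                               colClasses = "character")
  # read as character so allele columns like "T" are not parsed as logicals
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  ann$pos <- as.integer(ann$pos)
  if ("recomb_rate" %in% names(ann))
    ann$recomb_rate <- as.numeric(ann$recomb_rate)
  drops <- c(multiallelic = 0L, indel_or_mnp = 0L, unannotated = 0L,
             missing_freq = 0L)
  if (nrow(vcf@fix) == 0L) {
    warning("empty VCF: no variant records")
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      func_class = character(0), gene_id = character(0))
    attr(out, "drops") <- drops
    return(out)
  }
  fix <- as.data.frame(vcf@fix[, c("CHROM", "POS", "REF", "ALT"),
                               drop = FALSE], stringsAsFactors = FALSE)
  names(fix) <- c("chrom", "pos", "ref", "alt")
  fix$pos <- as.integer(fix$pos)
  multi <- grepl(",", fix$alt, fixed = TRUE)
  snp <- !multi & nchar(fix$ref) == 1L & nchar(fix$alt) == 1L &
    fix$ref %in% c("A", "C", "G", "T") & fix$alt %in% c("A", "C", "G", "T")
  drops["multiallelic"] <- sum(multi)
  drops["indel_or_mnp"] <- sum(!multi & !snp)
  pops <- unique(pop_map$pop)
  keep <- which(snp)
  out <- fix[keep, , drop = FALSE]
  has_gt <- nrow(vcf@gt) > 0 && ncol(vcf@gt) > 1
  if (has_gt) {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    gt <- gt[keep, , drop = FALSE]
    for (p in pops) {
      smp <- intersect(pop_map$sample[pop_map$pop == p], colnames(gt))
      if (!length(smp))
        stop("no VCF sample columns found for population '", p, "'")
      sub <- gt[, smp, drop = FALSE]
      alt_n <- rowSums(matrix(vapply(sub, function(g) {
        if (is.na(g)) 0L else sum(strsplit(g, "[/|]")[[1]] == "1")
      }, integer(1)), nrow = nrow(sub)))
      called <- rowSums(matrix(vapply(sub, function(g) {
        if (is.na(g)) 0L else sum(strsplit(g, "[/|]")[[1]] %in% c("0", "1"))
      }, integer(1)), nrow = nrow(sub)))
      out[[p]] <- ifelse(called > 0, alt_n / called, NA_real_)
    }
  } else {
    for (p in pops) {
      af <- vcfR::extract.info(vcf, element = paste0("AF_", p),
                               as.numeric = TRUE)
      if (all(is.na(af)))
        stop("VCF has no genotypes and no INFO field AF_", p)
      out[[p]] <- af[keep]
    }
  }
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  hit <- match(key(out), key(ann))
  if (anyNA(hit)) {
    if (strict) stop(sum(is.na(hit)), " site(s) lack annotation")
    drops["unannotated"] <- sum(is.na(hit))
    out <- out[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  extra <- setdiff(names(ann), c("chrom", "pos", "ref", "alt"))
  for (cc in extra) out[[cc]] <- ann[[cc]][hit]
  rownames(out) <- NULL
  attr(out, "drops") <- drops
  attr(out, "pops") <- pops
  out
}

#' Specification for a deterministic two-population SNP fixture
#'
#' Describes a synthetic data set whose classify-bin-count pipeline output
#' is known by construction: for each folded-MAF bin, the target numbers
#' of shared nonsynonymous/synonymous and focal-private nonsynonymous/
#' synonymous polymorphisms.
#'
#' @param per_bin Targets: either a 5 x 4 matrix (rows = MAF bins (0,0.1]
#'   ... (0.4,0.5], columns `s_n, s_s, r_n, r_s`) or a single length-4
#'   vector, which is placed in the (0.2,0.3] bin (so it is also the
#'   pooled MAF > 0.1 table).
#' @param n_genes Number of gene labels to spread sites over (default 5).
#' @param n_diploid Diploid samples per population (default 20, so
#'   frequencies are multiples of 1/40).
#' @param seed Seed recorded with the fixture (generation is fully
#'   deterministic).
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(per_bin, n_genes = 5, n_diploid = 20, seed = 1) {
  if (is.null(dim(per_bin))) {
    m <- matrix(0, 5, 4)
    m[3, ] <- per_bin
    per_bin <- m
  }
  if (!all(dim(per_bin) == c(5, 4)) || any(per_bin < 0) ||
      any(per_bin != round(per_bin)))
    stop("per_bin must be a 5 x 4 matrix of non-negative integer targets")
  colnames(per_bin) <- c("s_n", "s_s", "r_n", "r_s")
  structure(list(per_bin = per_bin, n_genes = n_genes,
                 n_diploid = n_diploid, seed = seed),
            class = "fixture_spec")
}

#' Generate a VCF + population map + annotation fixture
#'
#' Emits files such that running [read_sites()] then
#' [classify_shared_private()] and [bin_by_frequency()] with focal
#' population `"pop1"` reproduces the spec's per-bin count targets
#' exactly. Shared sites carry the bin-centre frequency in the focal
#' population (and 0.5 in the other); focal-private sites carry the
#' bin-centre frequency in the focal population only. Ref/alt pairs
#' alternate A/T and C/G, so the fixture passes [bgc_filter()] unchanged.
#' Output is byte-deterministic.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return Named list of the three file paths (`vcf`, `pop_map`,
#'   `annotation`).
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nd <- spec$n_diploid
  na <- 2L * nd
  centres <- c(0.05, 0.15, 0.25, 0.35, 0.45)
  if (any(abs(centres * na - round(centres * na)) > 1e-9))
    stop("n_diploid incompatible with exact bin-centre frequencies")
  rows <- list()
  for (b in 1:5) {
    for (cell in 1:4) {
      n <- spec$per_bin[b, cell]
      if (n == 0) next
      shared <- cell <= 2
      ns <- cell %in% c(1, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        maf = centres[b], shared = shared,
        func_class = if (ns) "nonsynonymous" else "synonymous",
        idx = seq_len(n))
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(maf = numeric(0), shared = logical(0),
               func_class = character(0), idx = integer(0))
  n_sites <- nrow(sites)
  gt_col <- function(k) { # k alt alleles among na, as phased genotypes
    hom <- k %/% 2L; het <- k %% 2L
    c(rep("1|1", hom), rep("0|1", het), rep("0|0", nd - hom - het))
  }
  header <- c("##fileformat=VCFv4.2",
              "##source=balsel_fixture_synthetic",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT",
                      sprintf("s%03d", seq_len(2L * nd))), collapse = "\t"))
  body <- character(n_sites)
  ann <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    ref <- if (i %% 2L == 1L) "A" else "C"
    alt <- if (i %% 2L == 1L) "T" else "G"
    k1 <- as.integer(round(sites$maf[i] * na))
    k2 <- if (sites$shared[i]) nd else 0L  # 0.5 in pop2, or absent
    fields <- c("1", i, ".", ref, alt, ".", "PASS", ".", "GT",
                gt_col(k1), gt_col(k2))
    body[i] <- paste(fields, collapse = "\t")
    ann[[i]] <- data.frame(chrom = "1", pos = i, ref = ref, alt = alt,
                           func_class = sites$func_class[i],
                           gene_id = sprintf("g%02d",
                                             1L + (i - 1L) %% spec$n_genes))
  }
  paths <- list(vcf = file.path(dir, "sites.vcf"),
                pop_map = file.path(dir, "pop_map.tsv"),
                annotation = file.path(dir, "annotation.tsv"))
  writeLines(c(header, body), paths$vcf)
  pop_map <- data.frame(sample = sprintf("s%03d", seq_len(2L * nd)),
                        pop = rep(c("pop1", "pop2"), each = nd))
  utils::write.table(pop_map, paths$pop_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ann_df <- if (n_sites) do.call(rbind, ann) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), func_class = character(0),
               gene_id = character(0))
  utils::write.table(ann_df, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}

#' Write result tables and a run manifest
#'
#' Writes tidy TSVs for a fitted [zb_test()] (estimates and, if present,
#' bootstrap intervals), optional binned count tables, and a JSON manifest
#' recording the package version, seed, thresholds and drop counts, so
#' that a run can be reproduced exactly.
#'
#' @param fit A [zb_test()] object (or `NULL`).
#' @param binned A [bin_by_frequency()] result (or `NULL`).
#' @param dir Output directory.
#' @param seed Seed to record.
#' @param extra Named list merged into the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(fit = NULL, binned = NULL, dir, seed = NULL,
                          extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  if (!is.null(fit)) {
    s <- summary(fit)$estimates
    s$p_chi2 <- c(if (is.null(fit$chi2)) NA_real_ else fit$chi2$p_value,
                  NA, NA)
    s$p_fisher <- c(fit$fisher$p_value, NA, NA)
    s$n_boot_dropped <- if (is.null(fit$boot)) NA_integer_ else
      vapply(fit$boot, `[[`, integer(1) + 0L, "n_dropped")
    p <- file.path(dir, "estimates.tsv")
    utils::write.table(s, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(binned)) {
    m <- t(vapply(binned$per_bin, unclass, numeric(4)))
    d <- data.frame(bin = rownames(m), m, flagged = binned$flagged)
    d <- rbind(d, data.frame(bin = ">0.1",
                             t(unclass(binned$combined_above)),
                             flagged = NA))
    p <- file.path(dir, "binned_counts.tsv")
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  manifest <- c(list(package = "balsel",
                     version = as.character(utils::packageVersion("balsel")),
                     seed = seed), extra)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, p, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  invisible(c(paths, p))
}

#' Read and write per-gene count tables
#'
#' Per-gene count TSVs have columns `gene_id, s_n, s_s, r_n, r_s`.
#'
#' @param path TSV path.
#' @return `read_gene_counts`: a data frame of per-gene tables.
#' @export
read_gene_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "s_n", "s_s", "r_n", "r_s")
  if (!all(need %in% names(d)))
    stop("count TSV needs columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname read_gene_counts
#' @param counts Data frame of per-gene tables.
#' @export
write_gene_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
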