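make_sites <- function(f1, f2, func_class = "synonymous",
                       gene = "g1", ref = "A", alt = "T") {
  n <- length(f1)
  data.frame(chrom = "1", pos = seq_len(n), ref = rep_len(ref, n),
             alt = rep_len(alt, n),
             func_class = rep_len(func_class, n),
             gene_id = rep_len(gene, n),
             pop1 = f1, pop2 = f2)
}

test_that("folding maps frequencies onto [0, 0.5] and is symmetric", {
  expect_equal(fold_maf(0.5), 0.5)
  expect_equal(fold_maf(0.9), 0.1)
  expect_equal(fold_maf(0.0), 0.0)
  f <- runif(100)
  expect_equal(fold_maf(f), fold_maf(1 - f))
  expect_equal(fold_maf(fold_maf(f)), fold_maf(f))
  expect_error(fold_maf(1.2), "\\[0, 1\\]")
})

test_that("sites are classified into exactly one category with the focal MAF
           taken in the focal population", {
  s <- make_sites(c(0.3, 0.6, 1.0, 0.0, 1.0, 0.4, 0.0),
                  c(0.0, 0.2, 0.0, 0.4, 1.0, 0.4, 0.0))
  cl <- classify_shared_private(s, "pop1", "pop2", focal = "pop1")
  expect_equal(cl$category,
               c("private_pop1", "shared", "fixed_difference",
                 "private_pop2", "monomorphic", "shared", "monomorphic"))
  expect_equal(cl$focal_maf[1], 0.3)
  expect_equal(cl$focal_maf[2], 0.4)  # folded from 0.6
  expect_true(is.na(cl$focal_maf[4])) # non-focal private excluded
  expect_false(cl$in_focal_set[3])    # fixed difference never counted
  # swapping the focal population changes folding, not categories
  cl2 <- classify_shared_private(s, "pop1", "pop2", focal = "pop2")
  expect_equal(cl$category, cl2$category)
  expect_equal(cl2$focal_maf[2], 0.2)
  expect_true(cl2$in_focal_set[4])
  expect_false(cl2$in_focal_set[1])
})

test_that("every retained site gets exactly one category and rejections are
           logged", {
  set.seed(21)
  n <- 500
  s <- make_sites(sample(c(0, runif(5), 1), n, TRUE),
                  sample(c(0, runif(5), 1), n, TRUE))
  s$pop1[1:7] <- NA
  cl <- classify_shared_private(s, "pop1", "pop2")
  expect_equal(nrow(cl), n - 7)
  expect_equal(attr(cl, "rejected")$n, 7)
  expect_true(all(cl$category %in% c("shared", "private_pop1",
                                     "private_pop2", "monomorphic",
                                     "fixed_difference")))
})

test_that("the BGC filter keeps exactly the GC-conservative mutation pairs
           and is idempotent", {
  s <- data.frame(chrom = "1", pos = 1:6,
                  ref = c("A", "A", "C", "G", "T", "G"),
                  alt = c("T", "G", "G", "C", "A", "A"),
                  func_class = "synonymous", gene_id = "g",
                  pop1 = 0.2, pop2 = 0.3)
  kept <- bgc_filter(s)
  expect_equal(kept$pos, c(1L, 3L, 4L, 5L))   # A/T, C/G, G/C, T/A
  expect_identical(bgc_filter(kept), kept)
})

test_that("frequency binning conserves counts and pools MAF > 0.1 strictly", {
  s1 <- make_sites(0.05, 0.5, func_class = "nonsynonymous")
  cl1 <- classify_shared_private(s1, "pop1", "pop2")
  b1 <- bin_by_frequency(cl1)
  expect_equal(unname(unclass(b1$per_bin[[1]])), c(1, 0, 0, 0))
  expect_equal(sum(unclass(b1$combined_above)), 0)

  # a site at exactly MAF 0.1 stays in the lowest bin, out of the pooled set
  s2 <- make_sites(c(0.1, 0.15, 0.25, 0.45, 0.5), rep(0.3, 5))
  cl2 <- classify_shared_private(s2, "pop1", "pop2")
  b2 <- bin_by_frequency(cl2)
  expect_equal(unname(unclass(b2$per_bin[[1]])["s_s"]), 1)
  expect_equal(unname(unclass(b2$combined_above)["s_s"]), 4)
  expect_equal(unname(unclass(b2$per_bin[[5]])["s_s"]), 2) # 0.45 and 0.5

  set.seed(31)
  n <- 10000
  s3 <- make_sites(runif(n), runif(n),
                   func_class = sample(c("nonsynonymous", "synonymous",
                                         "other"), n, TRUE))
  cl3 <- classify_shared_private(s3, "pop1", "pop2")
  b3 <- bin_by_frequency(cl3)
  percell <- Reduce(`+`, lapply(b3$per_bin, unclass))
  expect_equal(percell, unclass(b3$total))
  above <- Reduce(`+`, lapply(b3$per_bin[2:5], unclass))
  expect_equal(above, unclass(b3$combined_above))
  # "other" functional class never enters the table
  expect_equal(sum(unclass(b3$total)),
               sum(cl3$in_focal_set &
                     cl3$func_class %in% c("nonsynonymous", "synonymous")))
  expect_error(bin_by_frequency(cl3, bin_width = 0.15), "divide")
})

test_that("sparse bins are flagged, not deleted", {
  s <- make_sites(rep(c(0.25, 0.26), c(25, 25)), 0.5,
                  func_class = rep(c("nonsynonymous", "synonymous"), 25))
  cl <- classify_shared_private(s, "pop1", "pop2")
  b <- apply_min_count_filter(bin_by_frequency(cl), 20)
  expect_true(all(b$flagged))  # private cells are all zero here
  b0 <- apply_min_count_filter(b, 0)
  expect_false(any(b0$flagged))
  full <- bin_by_frequency(cl)
  full$per_bin <- lapply(full$per_bin, function(...) poly_counts(25, 25, 25, 25))
  expect_false(any(apply_min_count_filter(full, 20)$flagged))
  expect_true(any(apply_min_count_filter(
    within_bin <- local({ x <- full; x$per_bin[[1]] <- poly_counts(19, 100, 100, 100); x }),
    20)$flagged))
})

test_that("genes split at the median recombination rate with ties going low", {
  s <- data.frame(chrom = "1", pos = 1:8, ref = "A", alt = "T",
                  func_class = "synonymous",
                  gene_id = rep(c("g1", "g2", "g3", "g4"), each = 2),
                  pop1 = 0.2, pop2 = 0.2)
  sp <- split_by_recombination(s, gene_rates = c(g1 = 1, g2 = 2, g3 = 3,
                                                 g4 = 4))
  expect_setequal(unique(sp$low$gene_id), c("g1", "g2"))
  expect_setequal(unique(sp$high$gene_id), c("g3", "g4"))
  sp_eq <- split_by_recombination(s, gene_rates = c(g1 = 2, g2 = 2, g3 = 2,
                                                    g4 = 2))
  expect_equal(nrow(sp_eq$high), 0)
  sp_na <- split_by_recombination(s, gene_rates = c(g1 = 1, g2 = 2, g3 = 3,
                                                    g4 = NA))
  expect_equal(sp_na$excluded, "g4")
  set.seed(41)
  rates <- stats::setNames(runif(1001), paste0("G", 1:1001))
  sbig <- data.frame(chrom = "1", pos = 1:1001, ref = "A", alt = "T",
                     func_class = "synonymous", gene_id = names(rates),
                     pop1 = 0.2, pop2 = 0.2)
  spb <- split_by_recombination(sbig, rates)
  expect_lte(abs(length(unique(spb$low$gene_id)) -
                   length(unique(spb$high$gene_id))), 1)
})

test_that("gene-set pooling conserves counts and flags underpowered sets", {
  set.seed(51)
  n <- 2000
  s <- make_sites(runif(n), runif(n),
                  func_class = sample(c("nonsynonymous", "synonymous"),
                                      n, TRUE),
                  gene = sample(paste0("g", 1:20), n, TRUE))
  cl <- classify_shared_private(s, "pop1", "pop2")
  set_map <- data.frame(gene_id = paste0("g", 1:20),
                        set_id = rep(c("A", "B"), each = 10))
  gs <- group_by_gene_set(cl, set_map, min_polys_above_01 = 100)
  pooled <- Reduce(`+`, lapply(gs, function(g) unclass(g$total)))
  expect_equal(pooled, unclass(bin_by_frequency(cl)$total))
  # complement of A equals B when A and B partition the genes
  gs2 <- group_by_gene_set(cl, set_map, complement = "A")
  expect_equal(unclass(gs2$non_A$total), unclass(gs2$B$total))
  # a set below the MAF > 0.1 polymorphism minimum is flagged
  tiny_map <- data.frame(gene_id = "g1", set_id = "tiny")
  gst <- group_by_gene_set(cl, tiny_map, min_polys_above_01 = 1e6)
  expect_true(attr(gst$tiny, "flagged_set"))
  empty_map <- data.frame(gene_id = "nonexistent", set_id = "empty")
  gse <- group_by_gene_set(cl, empty_map, min_polys_above_01 = 1)
  expect_equal(sum(unclass(gse$empty$total)), 0)
  expect_true(attr(gse$empty, "flagged_set"))
})
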