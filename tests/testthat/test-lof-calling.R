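# HC filtering, zygosity, gene copy-loss mechanisms, compound-het
# detection, frequencies and mismatched genes.

test_that("zygosity counts alternate alleles and is swap-invariant", {
  expect_identical(variant_zygosity(c(0L, 1L, 1L, NA), c(0L, 0L, 1L, NA)),
                   c(0L, 1L, 2L, NA))
  expect_identical(variant_zygosity(0L, 1L), variant_zygosity(1L, 0L))
})

test_that("only variants with >= 1 HC transcript survive HC filtering", {
  co <- make_cohort(rbind("0|1", "0|1", "0|1"),
                    gene = c("G1", "G1", "G2"),
                    lof = c("LC", "HC", "NONE"))
  hc <- filter_hc(co)
  expect_identical(nrow(hc$cohort$variants), 1L)
  expect_identical(hc$gene_map$gene_id, "G1")
  # brute-force text-scan oracle over the raw CSQ strings
  raw_hc <- vapply(strsplit(co$csq$raw, "|", fixed = TRUE),
                   function(p) p[6] == "HC", TRUE)
  expect_identical(nrow(hc$gene_map), sum(raw_hc))
})

test_that("a variant annotated HC for two genes feeds both gene rows", {
  co <- make_cohort(rbind("1|0"))
  extra <- co$csq
  extra$gene_id <- "G2"; extra$gene_symbol <- "G2"
  co$csq <- rbind(co$csq, extra)
  res <- lof_call(co)
  expect_setequal(res$genes$gene_id, c("G1", "G2"))
  expect_identical(nrow(res$variants), 2L)   # one row per (variant, gene)
  expect_identical(unname(res$gene_matrix["G1", ]),
                   unname(res$gene_matrix["G2", ]))
})

test_that("haplotype configurations resolve to copies lost and mechanism", {
  cases <- list(
    list(gt = c("1|1"),               copies = 2L, mech = "HOMOZYGOUS"),
    list(gt = c("1|0", "0|1"),        copies = 2L, mech = "COMPOUND_HET"),
    list(gt = c("1|0", "1|0"),        copies = 1L, mech = "MULTI_CIS"),
    list(gt = c("1|0"),               copies = 1L, mech = "SINGLE_HET"),
    list(gt = c("0|0", "0|0"),        copies = 0L, mech = "NONE"),
    list(gt = c("1|1", "1|0", "0|1"), copies = 2L, mech = "HOM_AND_CH"),
    list(gt = c("1|1", "1|0"),        copies = 2L, mech = "HOMOZYGOUS"),
    list(gt = c("./.", "0|1"),        copies = 1L, mech = "SINGLE_HET"),
    list(gt = c("./.", "./."),        copies = NA_integer_,
         mech = NA_character_))
  for (cs in cases) {
    co <- make_cohort(matrix(cs$gt, ncol = 1))
    loss <- gene_copy_loss(co)
    expect_identical(unname(loss$copies[1, 1]), cs$copies,
                     label = paste(cs$gt, collapse = ","))
    expect_identical(unname(loss$mechanism[1, 1]), cs$mech,
                     label = paste(cs$gt, collapse = ","))
  }
})

test_that("unphased data never yields a compound het", {
  co <- strip_phase(make_cohort(rbind("1|0", "0|1")))
  loss <- gene_copy_loss(co)
  expect_identical(unname(loss$copies[1, 1]), 1L)
  expect_identical(unname(loss$mechanism[1, 1]), "MULTI_CIS")
  expect_true(loss$ambiguous[1, 1])
  expect_warning(ev <- detect_ch_events(co), "phased")
  expect_identical(nrow(ev), 0L)
  # a homozygote still knocks out both copies without phase
  co2 <- strip_phase(make_cohort(rbind("1|1", "0|1")))
  loss2 <- gene_copy_loss(co2)
  expect_identical(unname(loss2$copies[1, 1]), 2L)
  expect_identical(unname(loss2$mechanism[1, 1]), "HOMOZYGOUS")
})

test_that("copy-loss engine matches the haplotype-string oracle (k <= 4)", {
  for (k in 1:4) {
    gts <- all_configs(k)
    co <- make_cohort(gts)
    loss <- gene_copy_loss(co)
    want <- apply(gts, 2, oracle_gene_loss)
    expect_identical(unname(loss$copies[1, ]),
                     vapply(want, `[[`, NA_integer_, "copies"),
                     label = paste("k =", k))
    expect_identical(unname(loss$mechanism[1, ]),
                     vapply(want, `[[`, NA_character_, "mechanism"),
                     label = paste("k =", k))
  }
})

test_that("the reported CH pair is the lowest-position trans pair", {
  # hets at pos 100 (hap A), 200 (hap A), 300 (hap B): trans pairs are
  # (100,300) and (200,300); the rule picks the lowest on each haplotype
  co <- make_cohort(rbind("1|0", "1|0", "0|1"))
  ev <- detect_ch_events(co)
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$variant1, "chr1_100_A_T")
  expect_identical(ev$variant2, "chr1_300_A_T")
  all_ev <- detect_ch_events(co, all_pairs = TRUE)
  expect_identical(nrow(all_ev), 2L)
})

test_that("two-copy mechanism partition is disjoint and complete", {
  sim <- simulate_lof_cohort(sim_config(n_samples = 60, n_genes = 80,
                                        seed = 5))
  res <- lof_call(sim$cohort)
  two_copy_genes <- rownames(res$gene_matrix)[
    rowSums(res$gene_matrix == 2, na.rm = TRUE) > 0]
  expect_setequal(res$gene_class$gene_id, two_copy_genes)
  expect_false(anyDuplicated(res$gene_class$gene_id) > 0)
  expect_true(all(res$gene_class$class %in% c("hom_only", "ch_only", "both")))
  expect_identical(res$gene_class[, c("gene_id", "class")],
                   sim$truth$gene_class)
  # a sample with both a homozygote and a trans pair forces "both"
  co <- make_cohort(rbind("1|1", "1|0", "0|1"))
  expect_identical(lof_call(co)$gene_class$class, "both")
})

test_that("frequencies are carrier-state fractions over non-missing calls", {
  m <- rbind(c(1L, 1L, 2L), c(0L, 0L, 0L), c(1L, NA, 2L), c(NA, NA, NA))
  f <- compute_frequencies(m)
  expect_equal(f$freq1, c(2 / 3, 0, 1 / 2, NA))
  expect_equal(f$freq2, c(1 / 3, 0, 1 / 2, NA))
  expect_equal(f$allele_frequency, c((2 + 2) / 6, 0, 3 / 4, NA))
  # brute-force recount on a random matrix
  set.seed(1)
  r <- matrix(sample(c(0:2, NA), 200, replace = TRUE), 20)
  fr <- compute_frequencies(r)
  for (i in 1:20) {
    x <- r[i, !is.na(r[i, ])]
    expect_equal(fr$freq1[i], sum(x == 1) / length(x))
    expect_equal(fr$freq2[i], sum(x == 2) / length(x))
  }
  # conservation: f(0) + f(1) + f(2) = 1 on rows with data
  f0 <- rowSums(r == 0, na.rm = TRUE) / rowSums(!is.na(r))
  expect_equal(f0 + fr$freq1 + fr$freq2, rep(1, 20))
})

test_that("mismatched genes are directional and skip missing entries", {
  loss <- list(genes = c("G1", "G2", "G3", "G4"),
               copies = matrix(c(0L, 2L, 2L, NA,
                                 2L, 2L, 0L, 2L), 4,
                               dimnames = list(NULL, c("A", "B"))))
  mm <- mismatch_genes(loss, data.frame(sample_a = "A", sample_b = "B"))
  expect_identical(mm$gene_id[mm$direction == "a_to_b"], "G1")  # B out, A ok
  expect_identical(mm$gene_id[mm$direction == "b_to_a"], "G3")  # A out, B ok
  expect_false("G2" %in% mm$gene_id)   # inactive in both
  expect_false("G4" %in% mm$gene_id)   # missing in A
  expect_error(
    mismatch_genes(loss, data.frame(sample_a = "A", sample_b = "X")), "X")
})

test_that("all outputs are invariant under a global haplotype swap", {
  sim <- simulate_lof_cohort(sim_config(n_samples = 40, n_genes = 50,
                                        seed = 11))
  co <- sim$cohort
  res <- lof_call(co)
  swapped <- lof_call(swap_haplotypes(co))
  expect_identical(res$variant_matrix, swapped$variant_matrix)
  expect_identical(res$gene_matrix, swapped$gene_matrix)
  expect_identical(res$mechanism, swapped$mechanism)
  expect_identical(res$ch_events[, c("sample_id", "gene_id", "variant1",
                                     "variant2")],
                   swapped$ch_events[, c("sample_id", "gene_id", "variant1",
                                         "variant2")])
  expect_identical(res$variants, swapped$variants)
  expect_identical(res$genes, swapped$genes)
})
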