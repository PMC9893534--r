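# Compound-het transmission validation in trios and call-set comparison.

# A cohort of one gene with two variants across proband + parents, with
# configurable parental genotypes.
trio_cohort <- function(father_gt, mother_gt) {
  gt <- cbind(P = c("1|0", "0|1"), FA = father_gt, MO = mother_gt)
  co <- make_cohort(gt)
  co$samples <- c("P", "FA", "MO")
  colnames(co$geno_a) <- colnames(co$geno_b) <-
    colnames(co$phased_call) <- co$samples
  co
}
one_trio <- data.frame(proband_id = "P", father_id = "FA", mother_id = "MO",
                       stringsAsFactors = FALSE)

test_that("transmission verdicts follow parental carrier status", {
  run <- function(father_gt, mother_gt) {
    co <- trio_cohort(father_gt, mother_gt)
    validate_ch_transmission(one_trio, detect_ch_events(co), co)
  }
  # each parent donates one allele of the pair -> true, in either assignment
  expect_identical(run(c("1|0", "0|0"), c("0|0", "0|1"))$results$verdict,
                   "true_transmission")
  expect_identical(run(c("0|0", "1|0"), c("0|1", "0|0"))$results$verdict,
                   "true_transmission")
  # a homozygous parent still carries
  expect_identical(run(c("1|1", "0|0"), c("0|0", "0|1"))$results$verdict,
                   "true_transmission")
  # both variants from the same parent -> false
  r <- run(c("0|0", "0|0"), c("1|0", "0|1"))
  expect_identical(r$results$verdict, "false_transmission")
  expect_false(r$results$de_novo)
  # variant absent from both parents -> false with de novo flag
  r <- run(c("0|0", "0|0"), c("0|0", "0|1"))
  expect_identical(r$results$verdict, "false_transmission")
  expect_true(r$results$de_novo)
  # parent missing at both variants -> false with missing-data flag, and the
  # exclusive rate denominator drops the event
  r <- run(c("./.", "./."), c("0|0", "0|1"))
  expect_identical(r$results$verdict, "false_transmission")
  expect_true(r$results$missing_data)
  expect_identical(r$rates$n_events, 1L)
  expect_identical(r$rates$n_events_complete, 0L)
})

test_that("pedigree parsing extracts complete trios only", {
  path <- withr::local_tempfile(fileext = ".ped")
  writeLines(c("F1\tP\tFA\tMO\t0\t0",
               "F1\tFA\t0\t0\t1\t0",
               "F1\tMO\t0\t0\t2\t0"), path)
  ped <- read_pedigree(path)
  expect_identical(nrow(ped), 3L)
  expect_true(is.na(ped$father_id[2]))
  trios <- trios_from_pedigree(ped)
  expect_identical(trios, one_trio)
})

test_that("error-free Mendelian trios validate at 100%", {
  sim <- simulate_trios(sim_config(n_genes = 80, n_trios = 40, seed = 6))
  co <- sim$cohort
  ev <- detect_ch_events(co)
  expect_identical(ev[, c("sample_id", "gene_id", "variant1", "variant2")],
                   sim$truth$ch_events[, c("sample_id", "gene_id",
                                           "variant1", "variant2")])
  tx <- validate_ch_transmission(sim$trios, ev, co)
  expect_identical(tx$rates$rate_inclusive, 1)
  expect_identical(tx$rates$n_true, nrow(sim$truth$ch_events))
})

test_that("parental genotype errors lower the transmission rate", {
  noisy <- simulate_trios(sim_config(n_genes = 80, n_trios = 60,
                                     error_rate = 0.3, seed = 6))
  ev <- detect_ch_events(noisy$cohort)
  tx <- validate_ch_transmission(noisy$trios, ev, noisy$cohort)
  expect_lt(tx$rates$rate_inclusive, 1)
  # generator-side verdicts agree with the validator
  key <- function(d) paste(d$sample_id, d$gene_id, d$variant1, d$variant2)
  m <- match(key(tx$results), key(noisy$truth$ch_events))
  expect_identical(tx$results$verdict, noisy$truth$ch_events$verdict[m])
})

test_that("call-set comparison counts FP/FN per sample symmetrically", {
  sim <- simulate_lof_cohort(sim_config(n_samples = 30, n_genes = 40,
                                        seed = 13))
  co <- sim$cohort
  res <- lof_call(co)
  # identity
  cmp <- compare_callsets(res, res)
  expect_true(all(cmp$per_sample$fp == 0) && all(cmp$per_sample$fn == 0))
  # drop one variant from the test set: FN mean = carriers / n samples
  drop_id <- res$variants$variant_id[which.max(res$variants$het_frequency)]
  keep <- setdiff(co$variants$id, drop_id)
  test_co <- subset_cohort(co, variants = keep)
  cmp <- compare_callsets(res, lof_call(test_co))
  carriers <- sum(res$variant_matrix[
    match(drop_id, rownames(res$variant_matrix)), ] >= 1, na.rm = TRUE)
  expect_equal(cmp$fn_mean, carriers / length(co$samples))
  expect_equal(cmp$fp_mean, 0)
  # symmetry: A-vs-B false positives are B-vs-A false negatives
  other <- simulate_lof_cohort(sim_config(n_samples = 30, n_genes = 40,
                                          seed = 14))$cohort
  other$samples <- co$samples
  colnames(other$geno_a) <- colnames(other$geno_b) <-
    colnames(other$phased_call) <- co$samples
  ab <- compare_callsets(co, other)
  ba <- compare_callsets(other, co)
  expect_identical(ab$per_sample$fp, ba$per_sample$fn)
  expect_identical(ab$per_sample$fn, ba$per_sample$fp)
  expect_error(compare_callsets(res, lof_call(sim$cohort)[
    c("variant_matrix")]), "lof_cohort")
})
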