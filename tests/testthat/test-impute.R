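# IMPUTE2 quality filtering, genotype calling from probabilities, and
# conversion to phased VCF.

local_impute2 <- function(n_samples = 25, n_variants = 80, seed = 5,
                          prob_noise = 0.15) {
  simulate_impute2(sim_config(n_samples = n_samples, prob_noise = prob_noise,
                              seed = seed),
                   dir = withr::local_tempdir(.local_envir = parent.frame()),
                   n_variants = n_variants)
}

test_that("info filtering is strict and matches direct enumeration", {
  im <- local_impute2(n_variants = 100)
  rec <- read_impute2(im$paths$gen, im$paths$haps, im$paths$sample,
                      im$paths$info)
  one <- rec
  one$variants$info <- 0.85
  expect_identical(nrow(filter_by_info(one, 0.9)$variants), 0L)  # dropped
  expect_identical(nrow(filter_by_info(rec, 0)$variants),
                   sum(rec$variants$info > 0))
  for (thr in c(0.3, 0.6, 0.9)) {
    expect_identical(nrow(filter_by_info(rec, thr)$variants),
                     sum(im$truth$variants$info > thr))  # brute force
  }
  expect_identical(filter_by_info(rec, 0.5)$variants$snp_id,
                   rec$variants$snp_id[rec$variants$info > 0.5])  # order
})

test_that("genotype calls take the argmax, with missingness below 1-cutoff", {
  expect_identical(call_genotype(c(1, 0, 0)), 0L)
  expect_identical(call_genotype(c(0, 0, 1)), 2L)
  expect_identical(call_genotype(c(0.5, 0.3, 0.2), 0.05), NA_integer_)
  expect_identical(call_genotype(c(0.02, 0.96, 0.02), 0.05), 1L)
  # ties break toward missing
  expect_identical(call_genotype(c(0.5, 0.5, 0), 0.6), NA_integer_)
  expect_error(call_genotype(c(-0.1, 0.6, 0.5)), "negative")
})

test_that("missing-call rate matches a brute-force recount of 10k triples", {
  set.seed(404)
  # Dirichlet(1,1,1) triples via normalized exponentials
  e <- matrix(stats::rexp(30000), ncol = 3)
  p <- e / rowSums(e)
  for (cutoff in c(0.01, 0.05, 0.1)) {
    got <- call_genotype(p, cutoff)
    want_missing <- apply(p, 1, max) < 1 - cutoff  # ties have measure zero
    expect_identical(is.na(got), unname(want_missing))
    amax <- apply(p, 1, which.max) - 1L
    expect_identical(got[!want_missing], amax[!want_missing])
  }
})

test_that("conversion filters, phases from haplotypes, and round-trips", {
  im <- local_impute2()
  out <- withr::local_tempfile(fileext = ".vcf")
  convert_to_vcf(im$paths$gen, im$paths$haps, im$paths$sample,
                 im$paths$info, out, min_info = 0.3, prob_cutoff = 0.05)
  co <- read_annotated_vcf(out)
  keep <- im$truth$variants$info > 0.3
  expect_identical(nrow(co$variants), sum(keep))   # survivor count
  expect_true(co$phased)
  # surviving non-missing calls reproduce the planted haplotypes
  ids <- im$truth$variants$snp_id[keep]
  ha <- im$truth$hap_a[keep, , drop = FALSE]
  hb <- im$truth$hap_b[keep, , drop = FALSE]
  m <- match(ids, co$variants$id)
  nm <- !is.na(co$geno_a[m, ])
  expect_identical(co$geno_a[m, ][nm], ha[nm])
  expect_identical(co$geno_b[m, ][nm], hb[nm])
  # missing exactly where the best probability is uncertain (brute force)
  rec <- read_impute2(im$paths$gen, im$paths$haps, im$paths$sample,
                      im$paths$info)
  pm <- pmax(rec$p0, rec$p1, rec$p2)[keep, , drop = FALSE]
  expect_identical(unname(is.na(co$geno_a[m, ])), unname(pm < 0.95))
})

test_that("retention is monotone in both quality thresholds", {
  im <- local_impute2(n_variants = 120, seed = 17)
  rec <- read_impute2(im$paths$gen, im$paths$haps, im$paths$sample,
                      im$paths$info)
  infos <- c(0.3, 0.6, 0.9)
  cuts <- c(0.1, 0.05, 0.01)   # decreasing cutoff = stricter certainty
  kept <- sapply(infos, function(t) nrow(filter_by_info(rec, t)$variants))
  expect_true(all(diff(kept) <= 0))
  nonmiss <- sapply(cuts, function(cc)
    sum(!is.na(call_genotype(list(rec$p0, rec$p1, rec$p2), cc))))
  expect_true(all(diff(nonmiss) <= 0))
})

test_that("a .gen variant missing from .haps is fatal (phase is required)", {
  im <- local_impute2(n_variants = 10)
  haps <- readLines(im$paths$haps)
  writeLines(haps[-1], im$paths$haps)
  expect_error(read_impute2(im$paths$gen, im$paths$haps, im$paths$sample,
                            im$paths$info), "absent from .haps")
})

test_that("an info/record mismatch is fatal and names the offending key", {
  im <- local_impute2(n_variants = 10)
  info <- readLines(im$paths$info)
  parts <- strsplit(info[2], " ")[[1]]
  bad_key <- parts[1]
  parts[1] <- "chr9_999_A_T"
  info[2] <- paste(parts, collapse = " ")
  writeLines(info, im$paths$info)
  expect_error(read_impute2(im$paths$gen, im$paths$haps, im$paths$sample,
                            im$paths$info), "mismatch")
})

test_that("empty input converts to a valid header-only VCF", {
  dir <- withr::local_tempdir()
  gen <- file.path(dir, "e.gen"); writeLines(character(0), gen)
  haps <- file.path(dir, "e.haps"); writeLines(character(0), haps)
  smp <- file.path(dir, "e.sample")
  writeLines(c("ID_1 ID_2 missing", "0 0 0", "S1 S1 0"), smp)
  info <- file.path(dir, "e.info")
  writeLines("snp_id rs_id position a0 a1 info", info)
  out <- file.path(dir, "e.vcf")
  convert_to_vcf(gen, haps, smp, info, out)
  co <- read_annotated_vcf(out)
  expect_identical(nrow(co$variants), 0L)
  expect_identical(co$samples, "S1")
})
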