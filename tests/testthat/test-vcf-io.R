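# Reading/writing annotated, phased VCFs and multi-allelic normalization.

vcf_header <- function(samples, fmt = "Allele|Consequence|SYMBOL|Gene|Feature|LoF|LoF_flags") {
  c("##fileformat=VCFv4.2",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence ',
           'annotations from Ensembl VEP. Format: ', fmt, '">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_tmp_vcf <- function(lines) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("genotype strings map to calls, phase and missingness", {
  csq <- "CSQ=T|stop_gained|G1|G1|T1|HC|"
  rows <- c(
    paste("chr1", 100, ".", "A", "T", ".", "PASS", csq, "GT",
          "1|0", "0/1", "./.", sep = "\t"),
    paste("chr1", 200, ".", "G", "C", ".", "PASS",
          "CSQ=C|stop_gained|G1|G1|T2|HC|", "GT",
          "1|1", ".", "1", sep = "\t"))
  expect_message(
    co <- read_annotated_vcf(write_tmp_vcf(c(vcf_header(c("A", "B", "C")),
                                             rows))),
    "hemizygous")
  expect_identical(co$samples, c("A", "B", "C"))
  expect_identical(co$geno_a[1, ], c(A = 1L, B = 0L, C = NA_integer_))
  expect_identical(co$geno_b[1, ], c(A = 0L, B = 1L, C = NA_integer_))
  expect_true(co$phased_call[1, "A"])
  expect_false(co$phased_call[1, "B"])          # "/" separator
  expect_false(co$phased)                       # cohort-level: mixed phase
  # "." fully missing; hemizygous "1" treated as homozygous
  expect_identical(unname(co$geno_a[2, ]), c(1L, NA, 1L))
  expect_identical(unname(co$geno_b[2, ]), c(1L, NA, 1L))
})

test_that("malformed genotypes are rejected with their line number", {
  rows <- paste("chr1", 100, ".", "A", "T", ".", "PASS",
                "CSQ=T|stop_gained|G1|G1|T1|HC|", "GT", "1|x", sep = "\t")
  expect_error(read_annotated_vcf(write_tmp_vcf(c(vcf_header("A"), rows))),
               "line 5")
})

test_that("multi-allelic records split into per-alt biallelic variants", {
  csq <- paste0("CSQ=T|stop_gained|G1|G1|T1|HC|,",
                "G|frameshift_variant|G1|G1|T1|LC|")
  rows <- paste("chr1", 100, ".", "A", "T,G", ".", "PASS", csq, "GT",
                "1|2", "0|1", sep = "\t")
  co <- read_annotated_vcf(write_tmp_vcf(c(vcf_header(c("A", "B")), rows)))
  expect_identical(nrow(co$variants), 2L)  # one variant per alt
  expect_identical(co$variants$id, c("chr1_100_A_G", "chr1_100_A_T"))
  # GT 1|2: the T-variant sees 1|0, the G-variant sees 0|1
  t_row <- match("chr1_100_A_T", co$variants$id)
  g_row <- match("chr1_100_A_G", co$variants$id)
  expect_identical(unname(co$geno_a[t_row, ]), c(1L, 0L))
  expect_identical(unname(co$geno_b[t_row, ]), c(0L, 1L))
  expect_identical(unname(co$geno_a[g_row, ]), c(0L, 0L))
  expect_identical(unname(co$geno_b[g_row, ]), c(1L, 0L))
  # consequences routed to the matching alt via the CSQ Allele sub-field
  expect_identical(co$csq$lof_class[co$csq$variant == t_row], "HC")
  expect_identical(co$csq$lof_class[co$csq$variant == g_row], "LC")
})

test_that("unknown LoF tokens demote to NONE with a warning", {
  rows <- paste("chr1", 100, ".", "A", "T", ".", "PASS",
                "CSQ=T|stop_gained|G1|G1|T1|OS|", "GT", "0|1", sep = "\t")
  expect_warning(
    co <- read_annotated_vcf(write_tmp_vcf(c(vcf_header("A"), rows))),
    "unrecognized LoF")
  expect_identical(co$csq$lof_class, "NONE")
  expect_identical(nrow(filter_hc(co)$gene_map), 0L)
})

test_that("a written cohort re-reads identically (round trip)", {
  sim <- simulate_lof_cohort(sim_config(n_samples = 12, n_genes = 15,
                                        missing_rate = 0.05, seed = 42))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(sim$cohort, path)
  back <- read_annotated_vcf(path)
  expect_identical(back$samples, sim$cohort$samples)
  expect_identical(back$variants$id, sim$cohort$variants$id)
  expect_identical(back$geno_a, sim$cohort$geno_a)
  expect_identical(back$geno_b, sim$cohort$geno_b)
  expect_identical(back$phased_call, sim$cohort$phased_call)
  expect_identical(back$csq$raw, sim$cohort$csq$raw)
  # a second write reproduces the data lines byte for byte
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(back, path2)
  body <- function(p) grep("^##", readLines(p), value = TRUE, invert = TRUE)
  expect_identical(body(path), body(path2))
})

test_that("fixture cohort call counts match the simulator truth table", {
  sim <- simulate_lof_cohort(sim_config(n_samples = 3, n_genes = 5,
                                        variants_per_gene = 1L,
                                        missing_rate = 0, seed = 9))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(sim$cohort, path)
  co <- read_annotated_vcf(path)
  expect_identical(dim(co$geno_a), c(5L, 3L))   # 5 variants x 3 samples
  hc <- filter_hc(co)
  z <- zygosity_matrix(hc$cohort)[hc$gene_map$variant, , drop = FALSE]
  expect_identical(unname(z),
                   align_variant_matrix(lof_call(co), sim$truth)$matrix)
})

test_that("HC-only output keeps only HC variants plus a provenance line", {
  sim <- simulate_lof_cohort(sim_config(n_samples = 5, n_genes = 10,
                                        fraction_hc = 0.5, seed = 3))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(sim$cohort, path, hc_only = TRUE)
  lines <- readLines(path)
  expect_true(any(grepl("^##lofcall_provenance=", lines)))
  back <- read_annotated_vcf(path)
  hc_ids <- unique(sim$cohort$variants$id[
    sim$cohort$csq$variant[sim$cohort$csq$lof_class == "HC"]])
  expect_setequal(back$variants$id, hc_ids)
})
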