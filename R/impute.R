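# Preprocessing of IMPUTE2-format imputed genotypes: imputation-quality
# filtering, genotype calling from posterior probabilities, and conversion
# to phased VCF.

#' Read an IMPUTE2 file set
#'
#' Reads the four files describing one imputed chromosome chunk: the `.gen`
#' genotype-probability file (5 leading columns `snp_id rs_id pos alleleA
#' alleleB`, then a probability triple `p(AA) p(AB) p(BB)` per sample), the
#' SHAPEIT2-style `.haps` phased-haplotype file (same 5 leading columns,
#' then two 0/1 alleles per sample), the `.sample` file (two header rows,
#' then one row per sample) and a SNPTEST-style per-variant info file with a
#' named imputation-quality column. Allele A is taken as the reference
#' allele. The chromosome is parsed from `snp_id` when it is formatted
#' `chrom_pos_ref_alt` or `chrom:pos...`; otherwise `chrom` applies.
#'
#' @param gen_path,haps_path,sample_path,info_path The four file paths.
#' @param info_col Name of the info-score column, default `"info"`.
#' @param chrom Fallback chromosome name, default `"1"`.
#' @return Object of class `impute2_data`: list with `variants`
#'   (`data.frame`: `snp_id`, `chrom`, `pos`, `ref`, `alt`, `info`),
#'   probability matrices `p0`, `p1`, `p2` (variants x samples), haplotype
#'   matrices `hap_a`, `hap_b`, and `samples`.
#' @export
read_impute2 <- function(gen_path, haps_path, sample_path, info_path,
                         info_col = "info", chrom = "1") {
  for (p in c(gen_path, haps_path, sample_path, info_path)) {
    if (!file.exists(p)) fail("input file not found: ", p)
  }
  smp <- utils::read.table(sample_path, header = TRUE,
                           stringsAsFactors = FALSE)[-1, , drop = FALSE]
  if (length(readLines(gen_path, n = 1)) == 0) {
    # degenerate but legal: no variants
    samples <- as.character(smp[[1]])
    z <- matrix(numeric(), 0, length(samples),
                dimnames = list(NULL, samples))
    return(structure(list(
      variants = data.frame(snp_id = character(), chrom = character(),
                            pos = integer(), ref = character(),
                            alt = character(), info = numeric(),
                            stringsAsFactors = FALSE),
      p0 = z, p1 = z, p2 = z, hap_a = z, hap_b = z, samples = samples),
      class = "impute2_data"))
  }
  gen <- utils::read.table(gen_path, header = FALSE,
                           stringsAsFactors = FALSE)
  haps <- utils::read.table(haps_path, header = FALSE,
                            stringsAsFactors = FALSE)
  info <- utils::read.table(info_path, header = TRUE,
                            stringsAsFactors = FALSE)
  samples <- as.character(smp[[1]])
  n_samp <- length(samples)
  n_var <- nrow(gen)
  if (ncol(gen) != 5 + 3 * n_samp) {
    fail(".gen has ", ncol(gen), " columns; expected ", 5 + 3 * n_samp,
         " for ", n_samp, " samples")
  }
  if (ncol(haps) != 5 + 2 * n_samp) {
    fail(".haps has ", ncol(haps), " columns; expected ", 5 + 2 * n_samp)
  }
  key <- function(d) paste(d[[1]], d[[3]], d[[4]], d[[5]])
  gk <- key(gen)
  hk <- key(haps)
  absent <- setdiff(gk, hk)
  if (length(absent) > 0) {
    fail("variant present in .gen but absent from .haps (phase is required ",
         "downstream): ", absent[1])
  }
  hidx <- match(gk, hk)
  if (!(info_col %in% names(info))) {
    fail("info file has no column named '", info_col, "'")
  }
  if (nrow(info) != n_var) {
    fail("info file has ", nrow(info), " records but .gen has ", n_var)
  }
  if ("snp_id" %in% names(info)) {
    mism <- which(info$snp_id != gen[[1]])
    if (length(mism) > 0) {
      fail("info file/record mismatch at key ", gen[[1]][mism[1]])
    }
  }
  info_score <- as.numeric(info[[info_col]])
  if (any(info_score < 0 | info_score > 1, na.rm = TRUE)) {
    fail("info scores outside [0,1]")
  }
  pm <- as.matrix(gen[, -(1:5), drop = FALSE])
  p0 <- pm[, seq(1, 3 * n_samp, by = 3), drop = FALSE]
  p1 <- pm[, seq(2, 3 * n_samp, by = 3), drop = FALSE]
  p2 <- pm[, seq(3, 3 * n_samp, by = 3), drop = FALSE]
  if (any(pm < 0)) fail("negative genotype probabilities in .gen")
  bad_sum <- abs(p0 + p1 + p2 - 1) > 1e-3
  if (any(bad_sum)) {
    fail("genotype probability triple does not sum to 1 (tolerance 1e-3) ",
         "for variant ", gen[[1]][which(rowSums(bad_sum) > 0)[1]])
  }
  hm <- as.matrix(haps[hidx, -(1:5), drop = FALSE])
  hap_a <- hm[, seq(1, 2 * n_samp, by = 2), drop = FALSE]
  hap_b <- hm[, seq(2, 2 * n_samp, by = 2), drop = FALSE]
  snp_id <- as.character(gen[[1]])
  chrom_of <- function(id) {
    us <- sub("^([^_:]+)[_:].*$", "\\1", id)
    ifelse(grepl("[_:]", id), us, chrom)
  }
  variants <- data.frame(
    snp_id = snp_id, chrom = chrom_of(snp_id), pos = as.integer(gen[[3]]),
    ref = as.character(gen[[4]]), alt = as.character(gen[[5]]),
    info = info_score, stringsAsFactors = FALSE)
  dimnames(p0) <- dimnames(p1) <- dimnames(p2) <-
    dimnames(hap_a) <- dimnames(hap_b) <- list(snp_id, samples)
  structure(list(variants = variants, p0 = p0, p1 = p1, p2 = p2,
                 hap_a = hap_a, hap_b = hap_b, samples = samples),
            class = "impute2_data")
}

#' @export
print.impute2_data <- function(x, ...) {
  cat("IMPUTE2 data:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Filter imputed variants on imputation quality
#'
#' Retains variants whose info score strictly exceeds `min_info` (so
#' `min_info = 0.9` keeps "INFO above 0.9"). Order is preserved.
#'
#' @param records An `impute2_data` object.
#' @param min_info Info-score threshold in \[0, 1\].
#' @return The filtered `impute2_data`.
#' @export
filter_by_info <- function(records, min_info) {
  stopifnot(inherits(records, "impute2_data"),
            min_info >= 0, min_info <= 1)
  keep <- records$variants$info > min_info
  records$variants <- records$variants[keep, , drop = FALSE]
  for (f in c("p0", "p1", "p2", "hap_a", "hap_b")) {
    records[[f]] <- records[[f]][keep, , drop = FALSE]
  }
  records
}

#' Call genotypes from posterior probability triples
#'
#' Selects the most likely genotype from each `(p(hom-ref), p(het),
#' p(hom-alt))` triple. The call is set missing when the best genotype's
#' probability falls below `1 - prob_cutoff` (the probability cutoff is a
#' distance from certainty), and ties for the maximum are broken toward
#' missing.
#'
#' @param probs Numeric length-3 vector, or an n x 3 matrix, or a list of
#'   three equal-shaped matrices `(p0, p1, p2)`.
#' @param prob_cutoff Distance-from-certainty cutoff in \[0, 1\], default
#'   0.05 (keep calls with max probability >= 0.95).
#' @return Integer genotype code(s): 0, 1, 2 or `NA` (missing).
#' @examples
#' call_genotype(c(1, 0, 0))            # 0
#' call_genotype(c(0.5, 0.3, 0.2), 0.05)  # NA: 0.5 < 0.95
#' @export
call_genotype <- function(probs, prob_cutoff = 0.05) {
  stopifnot(prob_cutoff >= 0, prob_cutoff <= 1)
  if (is.list(probs)) {
    p0 <- probs[[1]]; p1 <- probs[[2]]; p2 <- probs[[3]]
  } else if (is.matrix(probs)) {
    p0 <- probs[, 1]; p1 <- probs[, 2]; p2 <- probs[, 3]
  } else {
    stopifnot(length(probs) == 3)
    p0 <- probs[1]; p1 <- probs[2]; p2 <- probs[3]
  }
  if (any(p0 < 0 | p1 < 0 | p2 < 0, na.rm = TRUE)) {
    fail("negative genotype probabilities")
  }
  pmax_ <- pmax(p0, p1, p2)
  g <- ifelse(p0 == pmax_, 0L, ifelse(p1 == pmax_, 1L, 2L))
  tie <- (p0 == pmax_) + (p1 == pmax_) + (p2 == pmax_) > 1
  out <- ifelse(pmax_ < 1 - prob_cutoff | tie, NA_integer_, g)
  if (is.matrix(p0)) dim(out) <- dim(p0)
  out
}

#' Convert filtered IMPUTE2 data to a phased VCF
#'
#' Applies the info-score filter, calls genotypes from the probability
#' triples, and writes a phased VCF whose `GT` alleles come from the
#' haplotypes file; calls failing [call_genotype()] become `./.` and
#' variants failing [filter_by_info()] are omitted. When the called genotype
#' disagrees with the haplotype dosage, the haplotypes decide the phase and
#' the probabilities decide only missingness; disagreements are counted in a
#' log message. The emitted VCF carries a CSQ header stub so it can be
#' annotated externally (or read back directly, without consequences).
#'
#' @param gen_path,haps_path,sample_path,info_path IMPUTE2 file set (see
#'   [read_impute2()]).
#' @param out_path Output VCF path.
#' @param min_info Info-score threshold, default 0.3.
#' @param prob_cutoff Genotype-probability cutoff, default 0.05.
#' @param info_col,chrom Passed to [read_impute2()].
#' @return `out_path`, invisibly.
#' @export
convert_to_vcf <- function(gen_path, haps_path, sample_path, info_path,
                           out_path, min_info = 0.3, prob_cutoff = 0.05,
                           info_col = "info", chrom = "1") {
  rec <- read_impute2(gen_path, haps_path, sample_path, info_path,
                      info_col = info_col, chrom = chrom)
  rec <- filter_by_info(rec, min_info)
  impute2_to_vcf(rec, out_path, prob_cutoff = prob_cutoff)
}

#' Write already-loaded IMPUTE2 data as a phased VCF
#'
#' The serialization step of [convert_to_vcf()], exposed for staged use.
#'
#' @param rec An `impute2_data` (typically already info-filtered).
#' @param out_path Output VCF path.
#' @param prob_cutoff Genotype-probability cutoff, see [call_genotype()].
#' @return `out_path`, invisibly.
#' @export
impute2_to_vcf <- function(rec, out_path, prob_cutoff = 0.05) {
  g <- call_genotype(list(rec$p0, rec$p1, rec$p2), prob_cutoff)
  dosage <- rec$hap_a + rec$hap_b
  conflict <- !is.na(g) & g != dosage
  if (any(conflict)) {
    lof_log(sum(conflict), " call(s) where the most likely genotype ",
            "disagrees with the haplotype pair; haplotypes kept for phase")
  }
  gt <- matrix(paste0(rec$hap_a, "|", rec$hap_b),
               nrow(rec$hap_a), ncol(rec$hap_a))
  gt[is.na(g)] <- "./."
  v <- rec$variants
  meta <- minimal_meta()
  header_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rec$samples),
                       collapse = "\t")
  body <- if (nrow(v) > 0) {
    b <- paste(v$chrom, v$pos, variant_id(v$chrom, v$pos, v$ref, v$alt),
               v$ref, v$alt, ".", "PASS", ".", "GT", sep = "\t")
    if (length(rec$samples) > 0) {
      b <- paste(b, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    }
    b
  } else character(0)
  writeLines(c(meta, header_line, body), out_path)
  invisible(out_path)
}
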