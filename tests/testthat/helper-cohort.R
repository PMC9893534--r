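# Builders and independent oracles used across the test files.

# Build a cohort programmatically from genotype strings ("0|1", "0/1",
# "./."), one row per variant. `gene` and `lof` assign each variant's single
# LoF annotation.
make_cohort <- function(gt, gene = rep("G1", nrow(gt)),
                        lof = rep("HC", nrow(gt)),
                        consequence = rep("stop_gained", nrow(gt)),
                        chrom = rep("chr1", nrow(gt)),
                        pos = 100L * seq_len(nrow(gt))) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  a <- apply(gt, 2, function(col) {
    x <- sub("^([^/|]).*$", "\\1", col)
    suppressWarnings(as.integer(x))
  })
  b <- apply(gt, 2, function(col) {
    x <- sub("^.[/|](.)$", "\\1", col)
    suppressWarnings(as.integer(x))
  })
  a <- matrix(a, n); b <- matrix(b, n)
  miss <- is.na(a) | is.na(b)
  a[miss] <- NA_integer_; b[miss] <- NA_integer_
  phased <- matrix(grepl("|", gt, fixed = TRUE) | miss, n)
  variants <- data.frame(chrom = chrom, pos = pos,
                         ref = rep("A", n), alt = rep("T", n),
                         stringsAsFactors = FALSE)
  lof_field <- ifelse(lof == "NONE", "", lof)
  csq <- data.frame(
    variant = seq_len(n), allele = "T", consequence = consequence,
    gene_symbol = gene, gene_id = gene,
    transcript_id = sprintf("T%03d", seq_len(n)),
    lof_class = lof, lof_flags = "",
    raw = paste("T", consequence, gene, gene,
                sprintf("T%03d", seq_len(n)), lof_field, "", sep = "|"),
    stringsAsFactors = FALSE)
  samples <- sprintf("S%02d", seq_len(ncol(gt)))
  lof_cohort(samples = samples, variants = variants, csq = csq,
             geno_a = a, geno_b = b, phased = phased, sort = FALSE)
}

# Independent brute-force oracle for gene copy loss: materializes the two
# haplotype allele-strings of one sample across one gene's variants and
# reads the answer off the strings.
oracle_gene_loss <- function(gt_vec) {
  gt_vec <- gt_vec[gt_vec != "./."]
  if (length(gt_vec) == 0) {
    return(list(copies = NA_integer_, mechanism = NA_character_))
  }
  hapA <- paste(substr(gt_vec, 1, 1), collapse = "")
  hapB <- paste(substr(gt_vec, 3, 3), collapse = "")
  lostA <- grepl("1", hapA)
  lostB <- grepl("1", hapB)
  copies <- as.integer(lostA) + as.integer(lostB)
  n_hom <- sum(gt_vec == "1|1")
  n_hetA <- sum(gt_vec == "1|0")
  n_hetB <- sum(gt_vec == "0|1")
  trans_pair <- n_hetA > 0 && n_hetB > 0
  mech <-
    if (n_hom > 0 && trans_pair) "HOM_AND_CH"
    else if (n_hom > 0) "HOMOZYGOUS"
    else if (trans_pair) "COMPOUND_HET"
    else if (n_hetA + n_hetB >= 2) "MULTI_CIS"
    else if (n_hetA + n_hetB == 1) "SINGLE_HET"
    else "NONE"
  list(copies = copies, mechanism = mech)
}

# All 4^k single-gene genotype configurations for k variants, as a
# (k x 4^k) matrix of genotype strings.
all_configs <- function(k) {
  codes <- c("0|0", "1|0", "0|1", "1|1")
  idx <- as.matrix(expand.grid(rep(list(1:4), k)))
  matrix(codes[idx], ncol = k, byrow = FALSE) |> t()
}

# Align an lof_call variant matrix with a simulator truth matrix by
# (variant_id, gene_id) key; returns list(found, matrix) for comparison.
align_variant_matrix <- function(result, truth) {
  key_r <- paste(result$variants$variant_id, result$variants$gene_id)
  key_t <- paste(truth$variants$variant_id, truth$variants$gene_id)
  list(same_rows = setequal(key_r, key_t),
       matrix = unname(result$variant_matrix[match(key_t, key_r), ,
                                             drop = FALSE]))
}
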