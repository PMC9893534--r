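# The in-memory cohort container: normalized biallelic variants with their
# transcript consequences, plus per-sample phased genotype calls.

#' Construct a cohort of annotated, phased genotype calls
#'
#' The central container for a cohort: a set of normalized biallelic variants
#' with VEP/LOFTEE transcript consequences and one genotype call per
#' (variant, sample). Usually built by [read_annotated_vcf()] or
#' [simulate_lof_cohort()]; the constructor is exported for programmatic
#' assembly and testing.
#'
#' @param samples Character vector of sample identifiers (order is preserved
#'   in every downstream output).
#' @param variants `data.frame` with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per biallelic variant; multi-allelic records must be split
#'   beforehand, see [split_multiallelic()]).
#' @param csq `data.frame` of transcript consequences with columns `variant`
#'   (row index into `variants`), `consequence`, `gene_symbol`, `gene_id`,
#'   `transcript_id`, `lof_class` (`"HC"`, `"LC"` or `"NONE"`), `lof_flags`,
#'   and `raw` (the verbatim CSQ entry).
#' @param geno_a,geno_b Integer matrices (variants x samples) of first/second
#'   haplotype allele indices in `{0, 1}`; `NA` in both marks a missing call.
#' @param phased Logical matrix (variants x samples): whether each call's
#'   allele order is haplotype-resolved.
#' @param sort Reorder variants deterministically by (chrom, pos, ref, alt)?
#' @return An object of class `lof_cohort`. Its `phased` element is the
#'   cohort-level flag: `TRUE` only if every non-missing call is phased.
#' @seealso [read_annotated_vcf()], [lof_call()], [strip_phase()]
#' @export
lof_cohort <- function(samples, variants, csq, geno_a, geno_b,
                       phased = NULL, sort = TRUE) {
  n_var <- nrow(variants)
  n_samp <- length(samples)
  if (anyDuplicated(samples)) fail("duplicate sample ids in cohort")
  geno_a <- matrix(as.integer(geno_a), n_var, n_samp)
  geno_b <- matrix(as.integer(geno_b), n_var, n_samp)
  if (is.null(phased)) phased <- matrix(TRUE, n_var, n_samp)
  phased <- matrix(as.logical(phased), n_var, n_samp)
  if (!identical(dim(geno_a), c(n_var, n_samp)) ||
      !identical(dim(geno_b), c(n_var, n_samp))) {
    fail("genotype matrix dimensions do not match variants x samples")
  }
  half_missing <- xor(is.na(geno_a), is.na(geno_b))
  if (any(half_missing)) {
    fail("half-missing genotype calls (one allele NA) are not permitted")
  }
  phased[is.na(geno_a)] <- TRUE  # a missing call carries no phase information
  if (n_var > 0 && any(!is.na(geno_a))) {
    rng <- range(c(geno_a, geno_b), na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      fail("allele indices outside {0,1}: multi-allelic records must be split")
    }
  }
  variants$id <- variant_id(variants$chrom, variants$pos,
                            variants$ref, variants$alt)
  if (anyDuplicated(variants$id)) {
    fail("duplicate variant ids after normalization: ",
         paste(utils::head(variants$id[duplicated(variants$id)], 3),
               collapse = ", "))
  }
  if (sort && n_var > 1) {
    o <- variant_order(variants$chrom, variants$pos,
                       variants$ref, variants$alt)
    variants <- variants[o, , drop = FALSE]
    rownames(variants) <- NULL
    geno_a <- geno_a[o, , drop = FALSE]
    geno_b <- geno_b[o, , drop = FALSE]
    phased <- phased[o, , drop = FALSE]
    csq$variant <- match(csq$variant, o)
  }
  dimnames(geno_a) <- dimnames(geno_b) <- dimnames(phased) <-
    list(variants$id, samples)
  obj <- structure(list(
    samples  = samples,
    variants = variants,
    csq      = csq,
    geno_a   = geno_a,
    geno_b   = geno_b,
    phased_call = phased,
    phased   = all(phased[!is.na(geno_a)])
  ), class = "lof_cohort")
  obj
}

#' @export
print.lof_cohort <- function(x, ...) {
  cat("Annotated cohort:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  n_hc <- length(unique(x$csq$variant[x$csq$lof_class == "HC"]))
  cat("  phased:", if (x$phased) "yes" else "no (or mixed)",
      "| variants with >=1 HC LoF annotation:", n_hc, "\n")
  invisible(x)
}

#' Remove haplotype phase from a cohort
#'
#' Marks every call unphased (as if genotypes were written with `/`),
#' preserving allele counts. Used to study the degradation of
#' compound-heterozygote detection without phase information.
#'
#' @param cohort An `lof_cohort`.
#' @return The cohort with all calls unphased.
#' @export
strip_phase <- function(cohort) {
  stopifnot(inherits(cohort, "lof_cohort"))
  cohort$phased_call[] <- FALSE
  cohort$phased <- FALSE
  cohort
}

#' Swap the two haplotypes of selected samples
#'
#' Exchanges `allele_a` and `allele_b` for whole samples. Haplotype labels
#' are arbitrary, so every downstream result (matrices, events, frequencies)
#' is invariant under this operation; the function exists to express and test
#' that property.
#'
#' @param cohort An `lof_cohort`.
#' @param samples Sample ids (or indices) to swap; default all.
#' @return The cohort with haplotypes swapped in the selected samples.
#' @export
swap_haplotypes <- function(cohort, samples = cohort$samples) {
  stopifnot(inherits(cohort, "lof_cohort"))
  j <- if (is.numeric(samples)) samples else match(samples, cohort$samples)
  if (anyNA(j)) fail("unknown sample id(s) in swap_haplotypes")
  tmp <- cohort$geno_a[, j, drop = FALSE]
  cohort$geno_a[, j] <- cohort$geno_b[, j, drop = FALSE]
  cohort$geno_b[, j] <- tmp
  cohort
}

#' Subset a cohort by variant and/or sample
#'
#' @param cohort An `lof_cohort`.
#' @param variants Variant row indices or ids to keep (default all).
#' @param samples Sample indices or ids to keep (default all).
#' @return The subsetted `lof_cohort`.
#' @export
subset_cohort <- function(cohort, variants = NULL, samples = NULL) {
  stopifnot(inherits(cohort, "lof_cohort"))
  i <- seq_len(nrow(cohort$variants))
  if (!is.null(variants)) {
    i <- if (is.numeric(variants)) as.integer(variants)
         else match(variants, cohort$variants$id)
    if (anyNA(i)) fail("unknown variant id(s) in subset_cohort")
  }
  j <- seq_along(cohort$samples)
  if (!is.null(samples)) {
    j <- if (is.numeric(samples)) as.integer(samples)
         else match(samples, cohort$samples)
    if (anyNA(j)) fail("unknown sample id(s) in subset_cohort")
  }
  csq <- cohort$csq[cohort$csq$variant %in% i, , drop = FALSE]
  csq$variant <- match(csq$variant, i)
  lof_cohort(samples = cohort$samples[j],
             variants = cohort$variants[i, c("chrom", "pos", "ref", "alt"),
                                        drop = FALSE],
             csq = csq,
             geno_a = cohort$geno_a[i, j, drop = FALSE],
             geno_b = cohort$geno_b[i, j, drop = FALSE],
             phased = cohort$phased_call[i, j, drop = FALSE],
             sort = FALSE)
}
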