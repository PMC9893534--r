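# Core computation: restrict a cohort to high-confidence LoF variants, build
# the variant zygosity and gene copy-loss matrices, resolve haplotype
# configurations into knockout mechanisms, and detect compound heterozygotes.

mechanism_levels <- c("NONE", "SINGLE_HET", "MULTI_CIS", "HOMOZYGOUS",
                      "COMPOUND_HET", "HOM_AND_CH")

#' Restrict a cohort to high-confidence LoF variants
#'
#' A variant is retained if at least one of its transcript consequences is
#' classified `HC` by LOFTEE (optionally only on canonical transcripts, and
#' optionally ignoring HC annotations that carry `LoF_flags`). A retained
#' variant is mapped to every gene for which it has a qualifying HC
#' annotation; a variant annotated HC for several genes contributes to each.
#'
#' @param cohort An [lof_cohort()].
#' @param transcript_policy `"any"` (HC on any transcript qualifies, the
#'   default) or `"canonical"` (only HC annotations on canonical transcripts
#'   qualify; requires a `CANONICAL` sub-field in the CSQ schema).
#' @param keep_flagged Keep HC annotations whose `LoF_flags` is non-empty?
#'   Default `TRUE` (flags are surfaced, not filtered).
#' @return List with `cohort` (the restricted `lof_cohort`) and `gene_map`,
#'   a `data.frame` with one row per (variant, gene) pair: `variant` (row
#'   index into the restricted cohort), `variant_id`, `gene_id`,
#'   `gene_symbol`, `consequence` (the first qualifying HC consequence term),
#'   `lof_flags`.
#' @export
filter_hc <- function(cohort, transcript_policy = c("any", "canonical"),
                      keep_flagged = TRUE) {
  stopifnot(inherits(cohort, "lof_cohort"))
  transcript_policy <- match.arg(transcript_policy)
  csq <- cohort$csq
  qual <- csq$lof_class == "HC"
  if (!keep_flagged) qual <- qual & csq$lof_flags == ""
  if (transcript_policy == "canonical") {
    schema <- cohort$schema
    if (is.null(schema) || !("CANONICAL" %in% schema$field_names)) {
      fail("transcript_policy = 'canonical' requires a CANONICAL CSQ sub-field")
    }
    k <- match("CANONICAL", schema$field_names)
    canon <- vapply(strsplit(csq$raw, "|", fixed = TRUE),
                    function(p) if (length(p) >= k) p[[k]] else "", "")
    qual <- qual & canon == "YES"
  }
  hits <- csq[qual, , drop = FALSE]
  if (nrow(hits) == 0) {
    empty_map <- data.frame(variant = integer(), variant_id = character(),
                            gene_id = character(), gene_symbol = character(),
                            consequence = character(), lof_flags = character(),
                            stringsAsFactors = FALSE)
    return(list(cohort = subset_cohort(cohort, variants = integer()),
                gene_map = empty_map))
  }
  # one row per (variant, gene), keeping the first qualifying annotation
  key <- paste(hits$variant, hits$gene_id, sep = "\r")
  first <- !duplicated(key)
  map <- hits[first, c("variant", "gene_id", "gene_symbol",
                       "consequence", "lof_flags"), drop = FALSE]
  # the first listed consequence term labels the row
  map$consequence <- sub(",.*$", "", sub("&.*$", "", map$consequence))
  keep <- sort(unique(map$variant))
  restricted <- subset_cohort(cohort, variants = keep)
  map$variant <- match(map$variant, keep)
  map$variant_id <- restricted$variants$id[map$variant]
  map <- map[order(map$gene_id, map$variant), , drop = FALSE]
  rownames(map) <- NULL
  list(cohort = restricted,
       gene_map = map[, c("variant", "variant_id", "gene_id", "gene_symbol",
                          "consequence", "lof_flags")])
}

#' Zygosity code of genotype calls
#'
#' Counts alternate alleles per call: 0 = not carrying, 1 = heterozygous,
#' 2 = homozygous for the LoF allele; missing propagates as `NA`. Invariant
#' under haplotype swap.
#'
#' @param allele_a,allele_b Integer allele indices in `{0, 1}` (`NA` =
#'   missing), as stored in an [lof_cohort()].
#' @return Integer vector/matrix of the same shape.
#' @examples
#' variant_zygosity(c(0L, 1L, 1L, NA), c(0L, 0L, 1L, NA))  # 0 1 2 NA
#' @export
variant_zygosity <- function(allele_a, allele_b) {
  allele_a + allele_b
}

#' Variant zygosity matrix of a cohort
#'
#' @param cohort An [lof_cohort()].
#' @return Integer matrix (variants x samples) of zygosity codes.
#' @export
zygosity_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "lof_cohort"))
  variant_zygosity(cohort$geno_a, cohort$geno_b)
}

#' Per-row carrier-state frequencies of a zygosity or copy-loss matrix
#'
#' For each row, computes the fraction of non-missing samples in state 1 and
#' in state 2, and the alternate-allele frequency
#' `(n1 + 2 n2) / (2 n_non_missing)`. For a variant matrix these are the
#' heterozygous/homozygous LoF frequencies; for a gene matrix the single- and
#' two-copy loss frequencies. All-missing rows yield `NA` frequencies.
#'
#' @param m Integer matrix with entries in `{0, 1, 2, NA}`.
#' @return `data.frame` with columns `freq1`, `freq2`, `allele_frequency`,
#'   `n_nonmissing`.
#' @export
compute_frequencies <- function(m) {
  n1 <- rowSums(m == 1, na.rm = TRUE)
  n2 <- rowSums(m == 2, na.rm = TRUE)
  nn <- rowSums(!is.na(m))
  f1 <- ifelse(nn > 0, n1 / nn, NA_real_)
  f2 <- ifelse(nn > 0, n2 / nn, NA_real_)
  af <- ifelse(nn > 0, (n1 + 2 * n2) / (2 * nn), NA_real_)
  data.frame(freq1 = f1, freq2 = f2, allele_frequency = af,
             n_nonmissing = nn)
}

# Vectorized gene-level copy-loss engine. For each (gene, sample) cell:
#   phased:   a haplotype is lost iff it carries >=1 alternate allele across
#             the gene's HC variants; copies_lost = lost haplotypes.
#   unphased: a homozygous variant loses both copies; heterozygotes without a
#             homozygote lose one copy at most (cis/trans unresolvable, so a
#             compound heterozygote is never called).
# A cell is treated as unphased if any non-missing call there is unphased.
gene_loss_core <- function(cohort, gene_map) {
  genes <- sort(unique(gene_map$gene_id))
  n_samp <- length(cohort$samples)
  if (length(genes) == 0 || n_samp == 0) {
    z <- matrix(integer(), length(genes), n_samp,
                dimnames = list(genes, cohort$samples))
    return(list(genes = genes, copies = z,
                mechanism = matrix(character(), length(genes), n_samp,
                                   dimnames = list(genes, cohort$samples)),
                ambiguous = z == 1))
  }
  vi <- gene_map$variant
  A <- cohort$geno_a[vi, , drop = FALSE]
  B <- cohort$geno_b[vi, , drop = FALSE]
  nonmiss <- !is.na(A)
  hom  <- !is.na(A) & A == 1L & B == 1L
  hetA <- !is.na(A) & A == 1L & B == 0L
  hetB <- !is.na(A) & A == 0L & B == 1L
  unph <- nonmiss & !cohort$phased_call[vi, , drop = FALSE]
  grp <- gene_map$gene_id
  cnt <- function(x) rowsum(x + 0L, grp)  # rows ordered by sorted gene id
  homN  <- cnt(hom)
  hetAN <- cnt(hetA)
  hetBN <- cnt(hetB)
  missN <- cnt(nonmiss)
  unphN <- cnt(unph)
  hetN <- hetAN + hetBN
  ph <- unphN == 0L

  lostA <- homN > 0L | hetAN > 0L
  lostB <- homN > 0L | hetBN > 0L
  copies <- matrix(NA_integer_, nrow(homN), ncol(homN))
  copies[ph] <- (lostA + lostB)[ph]
  copies[!ph] <- ifelse(homN[!ph] > 0L, 2L, pmin(hetN[!ph], 1L))
  copies[missN == 0L] <- NA_integer_

  mech <- matrix("NONE", nrow(homN), ncol(homN))
  mech[hetN == 1L] <- "SINGLE_HET"
  mech[hetN >= 2L] <- "MULTI_CIS"
  mech[ph & hetAN > 0L & hetBN > 0L] <- "COMPOUND_HET"
  mech[homN > 0L] <- "HOMOZYGOUS"
  mech[ph & homN > 0L & hetAN > 0L & hetBN > 0L] <- "HOM_AND_CH"
  mech[missN == 0L] <- NA_character_
  ambiguous <- !ph & hetN >= 2L & missN > 0L

  dn <- list(rownames(homN), cohort$samples)
  dimnames(copies) <- dimnames(mech) <- dimnames(ambiguous) <- dn
  list(genes = rownames(homN), copies = copies, mechanism = mech,
       ambiguous = ambiguous)
}

#' Gene copy-loss and knockout mechanism
#'
#' Computes, for every (gene, sample), how many gene copies are lost to
#' high-confidence LoF variants and by which mechanism. On phased data a
#' haplotype counts as lost when it carries at least one HC LoF alternate
#' allele anywhere in the gene; two lost haplotypes via two heterozygous
#' variants in trans is a compound-heterozygous knockout. On unphased data
#' (any unphased call in the cell) compound heterozygotes are never called:
#' heterozygotes without a homozygote lose at most one copy and multi-het
#' cells are flagged ambiguous. A cell is missing only when all of the
#' gene's variant calls are missing for that sample.
#'
#' @param cohort An [lof_cohort()] (it will be HC-restricted internally).
#' @param transcript_policy,keep_flagged Passed to [filter_hc()].
#' @return List with `copies` (integer genes x samples matrix, entries
#'   0/1/2/`NA`), `mechanism` (character matrix over
#'   `NONE`, `SINGLE_HET`, `MULTI_CIS`, `HOMOZYGOUS`, `COMPOUND_HET`,
#'   `HOM_AND_CH`), `ambiguous` (logical matrix: unresolved cis/trans), and
#'   the `gene_map` used.
#' @export
gene_copy_loss <- function(cohort, transcript_policy = "any",
                           keep_flagged = TRUE) {
  hc <- filter_hc(cohort, transcript_policy, keep_flagged)
  core <- gene_loss_core(hc$cohort, hc$gene_map)
  core$gene_map <- hc$gene_map
  core
}

#' Detect compound-heterozygous knockout events
#'
#' Finds every (sample, gene) in which two heterozygous HC LoF variants lie
#' on opposite haplotypes. When more than one trans pair qualifies, the
#' reported pair is deterministic: the lowest-position heterozygous variant
#' on each haplotype (equivalently the position-wise smallest trans pair);
#' with `all_pairs = TRUE` every trans pair is reported.
#'
#' @param cohort An [lof_cohort()]; must be phased — an unphased cohort
#'   yields zero events with a prominent warning.
#' @param transcript_policy,keep_flagged Passed to [filter_hc()].
#' @param all_pairs Report every trans pair per (sample, gene)?
#' @return `data.frame` with columns `sample_id`, `gene_id`, `variant1`,
#'   `variant2` (ids ordered by position), `hap_of_variant1` (`"A"` or
#'   `"B"`: which haplotype carries `variant1`).
#' @export
detect_ch_events <- function(cohort, transcript_policy = "any",
                             keep_flagged = TRUE, all_pairs = FALSE) {
  hc <- filter_hc(cohort, transcript_policy, keep_flagged)
  core <- gene_loss_core(hc$cohort, hc$gene_map)
  if (!cohort$phased) {
    warning("cohort is not (fully) phased: compound heterozygotes cannot ",
            "be detected; returning zero events", call. = FALSE)
  }
  ch_events_from_core(hc$cohort, hc$gene_map, core, all_pairs)
}

# Detection proper, given an HC-restricted cohort, its gene map and the
# copy-loss core result.
ch_events_from_core <- function(co, gm, core, all_pairs = FALSE) {
  empty <- data.frame(sample_id = character(), gene_id = character(),
                      variant1 = character(), variant2 = character(),
                      hap_of_variant1 = character(), stringsAsFactors = FALSE)
  ch_cells <- which(!is.na(core$mechanism) &
                    core$mechanism %in% c("COMPOUND_HET", "HOM_AND_CH"),
                    arr.ind = TRUE)
  if (nrow(ch_cells) == 0) return(empty)
  pos <- co$variants$pos
  out <- vector("list", nrow(ch_cells))
  for (i in seq_len(nrow(ch_cells))) {
    g <- core$genes[ch_cells[i, 1]]
    s <- ch_cells[i, 2]
    vi <- gm$variant[gm$gene_id == g]
    a <- co$geno_a[vi, s]
    b <- co$geno_b[vi, s]
    onA <- vi[!is.na(a) & a == 1L & b == 0L]
    onB <- vi[!is.na(a) & a == 0L & b == 1L]
    if (all_pairs) {
      pairs <- expand.grid(vA = onA, vB = onB)
    } else {
      pairs <- data.frame(vA = onA[which.min(pos[onA])],
                          vB = onB[which.min(pos[onB])])
    }
    swap <- pos[pairs$vB] < pos[pairs$vA]
    v1 <- ifelse(swap, pairs$vB, pairs$vA)
    v2 <- ifelse(swap, pairs$vA, pairs$vB)
    out[[i]] <- data.frame(
      sample_id = co$samples[s], gene_id = g,
      variant1 = co$variants$id[v1], variant2 = co$variants$id[v2],
      hap_of_variant1 = ifelse(swap, "B", "A"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$gene_id, res$sample_id, res$variant1), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify how each knocked-out gene loses both copies
#'
#' Partitions genes that are fully inactivated (2 copies lost) in at least
#' one sample by the mechanisms observed across samples: `hom_only` if every
#' two-copy sample is knocked out by a homozygous variant, `ch_only` if every
#' such sample is a compound heterozygote, `both` otherwise (including any
#' sample with both a homozygote and a trans het pair). Genes with no
#' two-copy sample are excluded.
#'
#' @param loss Result of [gene_copy_loss()] (or the corresponding elements of
#'   an [lof_call()] result).
#' @return `data.frame` with columns `gene_id`, `class` in
#'   `{"hom_only", "ch_only", "both"}`, and counts `n_two_copy`, `n_hom`,
#'   `n_ch`, `n_hom_and_ch` of two-copy samples per mechanism.
#' @export
classify_two_copy_mechanism <- function(loss) {
  two <- !is.na(loss$copies) & loss$copies == 2L
  keep <- rowSums(two) > 0
  genes <- loss$genes[keep]
  out <- data.frame(gene_id = genes, class = character(length(genes)),
                    n_two_copy = integer(length(genes)),
                    n_hom = integer(length(genes)),
                    n_ch = integer(length(genes)),
                    n_hom_and_ch = integer(length(genes)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    mechs <- loss$mechanism[loss$genes == genes[i], ][two[loss$genes == genes[i], ]]
    out$n_two_copy[i] <- length(mechs)
    out$n_hom[i] <- sum(mechs == "HOMOZYGOUS")
    out$n_ch[i] <- sum(mechs == "COMPOUND_HET")
    out$n_hom_and_ch[i] <- sum(mechs == "HOM_AND_CH")
    out$class[i] <-
      if (out$n_hom[i] == out$n_two_copy[i]) "hom_only"
      else if (out$n_ch[i] == out$n_two_copy[i]) "ch_only"
      else "both"
  }
  out
}

#' Mismatched knockout genes between paired samples
#'
#' For each sample pair (A, B), lists genes completely inactive (2 copies
#' lost) in one member while the other retains at least one active copy
#' (entry 0 or 1) — e.g. donor-vs-recipient or maternal-vs-fetal genome
#' comparisons. A gene with a missing entry in either member is excluded from
#' both directions for that pair.
#'
#' @param loss Result of [gene_copy_loss()] / the gene matrix of [lof_call()].
#' @param pairs `data.frame` with columns `sample_a`, `sample_b`.
#' @return `data.frame` with columns `sample_a`, `sample_b`, `direction`
#'   (`"a_to_b"`: knocked out in B, active in A; `"b_to_a"` converse),
#'   `gene_id`.
#' @export
mismatch_genes <- function(loss, pairs) {
  m <- loss$copies
  unknown <- setdiff(unique(c(pairs$sample_a, pairs$sample_b)), colnames(m))
  if (length(unknown) > 0) {
    fail("sample id(s) in pairs not present in the cohort: ",
         paste(unknown, collapse = ", "))
  }
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- m[, pairs$sample_a[i]]
    b <- m[, pairs$sample_b[i]]
    ok <- !is.na(a) & !is.na(b)
    a2b <- loss$genes[ok & b == 2L & a <= 1L]
    b2a <- loss$genes[ok & a == 2L & b <= 1L]
    out[[i]] <- data.frame(
      sample_a = pairs$sample_a[i], sample_b = pairs$sample_b[i],
      direction = rep(c("a_to_b", "b_to_a"), c(length(a2b), length(b2a))),
      gene_id = c(a2b, b2a), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(sample_a = character(),
                                      sample_b = character(),
                                      direction = character(),
                                      gene_id = character(),
                                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Call LoF variants and knockout genes in a cohort
#'
#' The package's main entry point: restricts the cohort to high-confidence
#' LoF variants, builds the variant zygosity matrix (one row per
#' (variant, gene) pair) and the gene copy-loss matrix with carrier-state
#' frequencies, resolves knockout mechanisms from haplotype phase, detects
#' compound-heterozygous events, and classifies two-copy genes by mechanism.
#'
#' @param cohort An [lof_cohort()], e.g. from [read_annotated_vcf()].
#' @param transcript_policy,keep_flagged Passed to [filter_hc()].
#' @return An object of class `lof_result` with elements:
#'   `variants` (`data.frame`: `variant_id`, `gene_id`, `consequence`,
#'   `het_frequency`, `hom_frequency`, `allele_frequency`),
#'   `variant_matrix` (integer (variant, gene)-rows x samples),
#'   `genes` (`data.frame`: `gene_id`, `gene_symbol`, `one_copy_frequency`,
#'   `two_copy_frequency`), `gene_matrix` (integer genes x samples),
#'   `mechanism` and `ambiguous` matrices, `ch_events`, `gene_class`,
#'   `samples`, `phased`, and the HC-restricted `cohort` and `gene_map`.
#' @seealso [summary.lof_result()], [write_lof_result()]
#' @export
lof_call <- function(cohort, transcript_policy = "any", keep_flagged = TRUE) {
  hc <- filter_hc(cohort, transcript_policy, keep_flagged)
  gm <- hc$gene_map
  core <- gene_loss_core(hc$cohort, gm)
  zyg <- zygosity_matrix(hc$cohort)
  vmat <- zyg[gm$variant, , drop = FALSE]
  rownames(vmat) <- gm$variant_id
  vfreq <- compute_frequencies(vmat)
  variants <- data.frame(
    variant_id = gm$variant_id, gene_id = gm$gene_id,
    consequence = gm$consequence, lof_flags = gm$lof_flags,
    het_frequency = vfreq$freq1, hom_frequency = vfreq$freq2,
    allele_frequency = vfreq$allele_frequency, stringsAsFactors = FALSE)
  gfreq <- compute_frequencies(core$copies)
  gene_first <- gm[!duplicated(gm$gene_id), , drop = FALSE]
  genes <- data.frame(
    gene_id = core$genes,
    gene_symbol = gene_first$gene_symbol[match(core$genes,
                                               gene_first$gene_id)],
    one_copy_frequency = gfreq$freq1, two_copy_frequency = gfreq$freq2,
    stringsAsFactors = FALSE)
  ch <- ch_events_from_core(hc$cohort, gm, core)
  structure(list(
    variants = variants, variant_matrix = vmat,
    genes = genes, gene_matrix = core$copies,
    mechanism = core$mechanism, ambiguous = core$ambiguous,
    ch_events = ch, gene_class = classify_two_copy_mechanism(core),
    samples = hc$cohort$samples, phased = cohort$phased,
    cohort = hc$cohort, gene_map = gm
  ), class = "lof_result")
}

#' @export
print.lof_result <- function(x, ...) {
  cat("LoF call set:", length(unique(x$variants$variant_id)),
      "HC LoF variants in", nrow(x$genes), "genes across",
      length(x$samples), "samples\n")
  cat("  phased:", if (x$phased) "yes" else "no",
      "| compound-het events:", nrow(x$ch_events), "\n")
  if (nrow(x$gene_class) > 0) {
    tab <- table(factor(x$gene_class$class,
                        levels = c("hom_only", "ch_only", "both")))
    cat("  two-copy genes:", sum(tab),
        sprintf("(hom_only %d, ch_only %d, both %d)\n",
                tab[1], tab[2], tab[3]))
  }
  invisible(x)
}
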