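# Trio-based validation of compound-heterozygote transmission and pairwise
# comparison of LoF call sets.

#' Read a PED-like pedigree file
#'
#' Tab- or space-delimited with columns family, individual, father, mother,
#' sex, phenotype; unknown parents coded `0`. Extra columns are ignored.
#'
#' @param path Pedigree file path.
#' @return `data.frame` with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `phenotype` (parent ids `NA` when
#'   unknown).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) fail("pedigree file not found: ", path)
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) < 4) fail("pedigree file needs at least 4 columns")
  out <- data.frame(
    family_id = ped[[1]], individual_id = ped[[2]],
    father_id = ifelse(ped[[3]] == "0", NA_character_, ped[[3]]),
    mother_id = ifelse(ped[[4]] == "0", NA_character_, ped[[4]]),
    sex = if (ncol(ped) >= 5) ped[[5]] else NA_character_,
    phenotype = if (ncol(ped) >= 6) ped[[6]] else NA_character_,
    stringsAsFactors = FALSE)
  out
}

#' Extract complete trios from a pedigree
#'
#' @param ped A [read_pedigree()] result.
#' @param cohort Optional [lof_cohort()]; trios with members absent from the
#'   cohort are dropped with a log message.
#' @return `data.frame` with columns `proband_id`, `father_id`, `mother_id`.
#' @export
trios_from_pedigree <- function(ped, cohort = NULL) {
  tr <- ped[!is.na(ped$father_id) & !is.na(ped$mother_id), , drop = FALSE]
  out <- data.frame(proband_id = tr$individual_id,
                    father_id = tr$father_id, mother_id = tr$mother_id,
                    stringsAsFactors = FALSE)
  bad <- out$proband_id == out$father_id | out$proband_id == out$mother_id |
         out$father_id == out$mother_id
  if (any(bad)) fail("trio with non-distinct member ids: proband ",
                     out$proband_id[which(bad)[1]])
  if (!is.null(cohort)) {
    present <- out$proband_id %in% cohort$samples &
               out$father_id %in% cohort$samples &
               out$mother_id %in% cohort$samples
    if (any(!present)) {
      lof_log(sum(!present), " trio(s) dropped: member(s) not in cohort")
    }
    out <- out[present, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Validate compound-heterozygote transmission in trios
#'
#' For each proband compound-het event, checks the defining transmission
#' pattern: one variant of the pair carried (>= 1 alternate allele, phase not
#' required) by the father and the other by the mother, in either
#' assignment. Events failing that are false transmissions; an event whose
#' two variants are both absent from both parents is additionally flagged
#' `de_novo`, and an event where a parent is missing genotypes at both
#' variants is flagged `missing_data` (counted false, never dropped).
#'
#' @param trios `data.frame` with `proband_id`, `father_id`, `mother_id`
#'   (see [trios_from_pedigree()]).
#' @param ch_events Proband compound-het events (see [detect_ch_events()]).
#' @param cohort The [lof_cohort()] holding proband and parental genotypes.
#' @return An object of class `lof_transmission`: list with `results` (one
#'   row per event: carrier status per parent per variant, `verdict`,
#'   `de_novo`, `missing_data`) and `rates` (counts plus the
#'   true-transmission fraction, both over all events and excluding
#'   missing-data events).
#' @export
validate_ch_transmission <- function(trios, ch_events, cohort) {
  stopifnot(inherits(cohort, "lof_cohort"))
  ev <- merge(ch_events, trios, by.x = "sample_id", by.y = "proband_id",
              sort = FALSE)
  zyg <- zygosity_matrix(cohort)
  carrier <- function(variant, sample) {
    z <- zyg[cbind(match(variant, cohort$variants$id),
                   match(sample, cohort$samples))]
    z  # NA if missing call
  }
  n <- nrow(ev)
  res <- data.frame(
    sample_id = ev$sample_id, gene_id = ev$gene_id,
    variant1 = ev$variant1, variant2 = ev$variant2,
    father_id = ev$father_id, mother_id = ev$mother_id,
    stringsAsFactors = FALSE)
  if (n > 0) {
    f1 <- carrier(ev$variant1, ev$father_id)
    f2 <- carrier(ev$variant2, ev$father_id)
    m1 <- carrier(ev$variant1, ev$mother_id)
    m2 <- carrier(ev$variant2, ev$mother_id)
    has <- function(z) !is.na(z) & z >= 1L
    true_tx <- (has(f1) & has(m2)) | (has(f2) & has(m1))
    res$father_carries_variant1 <- has(f1)
    res$father_carries_variant2 <- has(f2)
    res$mother_carries_variant1 <- has(m1)
    res$mother_carries_variant2 <- has(m2)
    res$verdict <- ifelse(true_tx, "true_transmission", "false_transmission")
    res$missing_data <- (is.na(f1) & is.na(f2)) | (is.na(m1) & is.na(m2))
    res$de_novo <- (!has(f1) & !has(m1) & !is.na(f1) & !is.na(m1)) |
                   (!has(f2) & !has(m2) & !is.na(f2) & !is.na(m2))
  } else {
    res$father_carries_variant1 <- res$father_carries_variant2 <-
      res$mother_carries_variant1 <- res$mother_carries_variant2 <- logical(0)
    res$verdict <- character(0)
    res$missing_data <- res$de_novo <- logical(0)
  }
  n_true <- sum(res$verdict == "true_transmission")
  excl <- !res$missing_data
  rates <- list(
    n_events = n,
    n_true = n_true,
    n_false = n - n_true,
    rate_inclusive = if (n > 0) n_true / n else NA_real_,
    n_events_complete = sum(excl),
    n_true_complete = sum(res$verdict[excl] == "true_transmission"),
    rate_excluding_missing = if (sum(excl) > 0)
      sum(res$verdict[excl] == "true_transmission") / sum(excl)
      else NA_real_)
  structure(list(results = res, rates = rates), class = "lof_transmission")
}

#' @export
print.lof_transmission <- function(x, ...) {
  r <- x$rates
  cat("Compound-het transmission validation:", r$n_events, "events\n")
  cat(sprintf("  true transmissions: %d (%.1f%%)",
              r$n_true, 100 * (r$rate_inclusive %||% NA)), "\n")
  cat(sprintf("  excluding parental missing data: %d/%d (%.1f%%)\n",
              r$n_true_complete, r$n_events_complete,
              100 * (r$rate_excluding_missing %||% NA)))
  invisible(x)
}

#' Compare two LoF call sets sample by sample
#'
#' Treats `truth` as the reference (e.g. exome-sequencing calls) and `test`
#' as the evaluated set (e.g. calls from imputed genotypes). For every shared
#' sample, a variant is "called" when the sample carries >= 1 alternate
#' allele of an HC LoF variant (with `two_copy_only = TRUE`, when it carries
#' 2). False negatives are variants called in `truth` but not `test`; false
#' positives the converse. Variants are keyed by `chrom_pos_ref_alt` id
#' only, so annotation differences between the sets do not matter.
#'
#' @param truth,test [lof_cohort()]s or [lof_call()] results.
#' @param two_copy_only Compare homozygous/two-copy calls only?
#' @return List with `per_sample` (`data.frame`: `sample_id`, `fp`, `fn`)
#'   and the cohort averages `fp_mean`, `fn_mean`.
#' @export
compare_callsets <- function(truth, test, two_copy_only = FALSE) {
  vm <- function(x) {
    if (inherits(x, "lof_cohort")) x <- lof_call(x)
    if (!inherits(x, "lof_result")) fail("expected lof_cohort or lof_result")
    m <- x$variant_matrix
    m[!duplicated(rownames(m)), , drop = FALSE]
  }
  mt <- vm(truth)
  ms <- vm(test)
  shared <- intersect(colnames(mt), colnames(ms))
  if (length(shared) == 0) fail("no shared samples between call sets")
  lo <- if (two_copy_only) 2L else 1L
  per <- data.frame(sample_id = shared, fp = 0L, fn = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(shared)) {
    s <- shared[i]
    in_truth <- rownames(mt)[!is.na(mt[, s]) & mt[, s] >= lo]
    in_test  <- rownames(ms)[!is.na(ms[, s]) & ms[, s] >= lo]
    per$fn[i] <- length(setdiff(in_truth, in_test))
    per$fp[i] <- length(setdiff(in_test, in_truth))
  }
  list(per_sample = per,
       fp_mean = mean(per$fp), fn_mean = mean(per$fn),
       n_samples = length(shared))
}
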