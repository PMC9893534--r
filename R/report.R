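# Descriptive statistics over the call matrices and the plain-text ".info"
# cohort report.

#' Cohort summary of LoF variants and knockout genes
#'
#' Computes the descriptive statistics reported for a call set: totals of
#' distinct LoF variants (and how many are seen heterozygous / homozygous in
#' at least one sample), compound-het events, and distinct LoF genes (and
#' how many are seen with one / two copies lost — a gene may count in both
#' classes across samples); plus per-sample distributions (mean, median,
#' min, max) of carried LoF variants, het and hom variants, and one- and
#' two-copy genes, over non-missing entries.
#'
#' @param variant_matrix Integer (variant, gene)-row x sample matrix of
#'   zygosity codes, row names = variant ids (rows may repeat a variant that
#'   hits several genes; it is counted once).
#' @param gene_matrix Integer gene x sample matrix of copies lost.
#' @param ch_events Compound-het event `data.frame` (see
#'   [detect_ch_events()]); only its row count enters the summary.
#' @return An object of class `lof_summary`: list with `totals` (named
#'   integer vector) and `per_sample` (`data.frame` of mean/median/min/max
#'   per metric).
#' @export
summarize_cohort <- function(variant_matrix, gene_matrix, ch_events) {
  if (!identical(colnames(variant_matrix), colnames(gene_matrix))) {
    fail("variant and gene matrices cover different sample sets")
  }
  vid <- rownames(variant_matrix) %||% character(0)
  uniq <- !duplicated(vid)
  vm <- variant_matrix[uniq, , drop = FALSE]
  gm <- gene_matrix

  any_state <- function(m, states) rowSums(matrix(m %in% states, nrow(m)),
                                           na.rm = TRUE) > 0
  totals <- c(
    n_lof_variants      = sum(any_state(vm, c(1L, 2L))),
    n_het_variants      = sum(any_state(vm, 1L)),
    n_hom_variants      = sum(any_state(vm, 2L)),
    n_ch_events         = nrow(ch_events),
    n_lof_genes         = sum(any_state(gm, c(1L, 2L))),
    n_one_copy_genes    = sum(any_state(gm, 1L)),
    n_two_copy_genes    = sum(any_state(gm, 2L))
  )
  per_sample_counts <- rbind(
    lof_variants  = colSums(vm == 1 | vm == 2, na.rm = TRUE),
    het_variants  = colSums(vm == 1, na.rm = TRUE),
    hom_variants  = colSums(vm == 2, na.rm = TRUE),
    one_copy_genes = colSums(gm == 1, na.rm = TRUE),
    two_copy_genes = colSums(gm == 2, na.rm = TRUE))
  if (ncol(per_sample_counts) == 0) {
    per_sample_counts <- matrix(0, nrow(per_sample_counts), 1)
  }
  per_sample <- data.frame(
    metric = rownames(per_sample_counts),
    mean   = unname(apply(per_sample_counts, 1, mean)),
    median = unname(apply(per_sample_counts, 1, stats::median)),
    min    = unname(apply(per_sample_counts, 1, min)),
    max    = unname(apply(per_sample_counts, 1, max)),
    stringsAsFactors = FALSE)
  structure(list(totals = totals, per_sample = per_sample),
            class = "lof_summary")
}

#' Summarize an LoF call set
#'
#' @param object An [lof_call()] result.
#' @param ... Unused.
#' @return An `lof_summary`; see [summarize_cohort()].
#' @export
summary.lof_result <- function(object, ...) {
  summarize_cohort(object$variant_matrix, object$gene_matrix,
                   object$ch_events)
}

#' @export
print.lof_summary <- function(x, ...) {
  t <- x$totals
  cat("LoF cohort summary\n")
  cat(sprintf("  Total LoF variants : %d (het %d, hom %d)\n",
              t[["n_lof_variants"]], t[["n_het_variants"]],
              t[["n_hom_variants"]]))
  cat(sprintf("  Total LoF genes    : %d (1-copy %d, 2-copy %d)\n",
              t[["n_lof_genes"]], t[["n_one_copy_genes"]],
              t[["n_two_copy_genes"]]))
  cat(sprintf("  Compound-het events: %d\n", t[["n_ch_events"]]))
  cat("  Per sample (mean / median / min / max):\n")
  for (i in seq_len(nrow(x$per_sample))) {
    r <- x$per_sample[i, ]
    cat(sprintf("    %-15s %.2f / %g / %g / %g\n",
                r$metric, r$mean, r$median, r$min, r$max))
  }
  invisible(x)
}

summary_keys <- function(s) {
  t <- s$totals
  keys <- c(
    total_lof_variants              = t[["n_lof_variants"]],
    total_heterozygous_lof_variants = t[["n_het_variants"]],
    total_homozygous_lof_variants   = t[["n_hom_variants"]],
    total_ch_events                 = t[["n_ch_events"]],
    total_lof_genes                 = t[["n_lof_genes"]],
    total_one_copy_lof_genes        = t[["n_one_copy_genes"]],
    total_two_copy_lof_genes        = t[["n_two_copy_genes"]])
  for (i in seq_len(nrow(s$per_sample))) {
    m <- s$per_sample$metric[i]
    for (stat in c("mean", "median", "min", "max")) {
      keys[paste0(stat, "_", m, "_per_individual")] <- s$per_sample[i, stat]
    }
  }
  keys
}

#' Write the plain-text ".info" cohort report
#'
#' Emits every summary field as a machine-parseable `key<TAB>value` line,
#' preceded by `#`-prefixed provenance comments (package version, timestamp
#' and any supplied inputs/thresholds). [read_info_report()] inverts it.
#'
#' @param summary An `lof_summary` (from [summary.lof_result()]).
#' @param path Output path; the conventional extension is `.info`.
#' @param provenance Named list of extra provenance to record as comments
#'   (input paths, thresholds, ...).
#' @return `path`, invisibly.
#' @export
write_info_report <- function(summary, path, provenance = list()) {
  stopifnot(inherits(summary, "lof_summary"))
  prov <- c(list(tool = paste0("lofcall ",
                               as.character(utils::packageVersion("lofcall"))),
                 date = format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
            provenance)
  head <- sprintf("# %s: %s", names(prov),
                  vapply(prov, function(v) paste(as.character(v),
                                                 collapse = " "), ""))
  keys <- summary_keys(summary)
  body <- sprintf("%s\t%.17g", names(keys), unname(keys))
  ok <- tryCatch({ writeLines(c(head, body), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) fail("cannot write info report to ", path)
  invisible(path)
}

#' Parse a ".info" report back into its summary
#'
#' @param path Path written by [write_info_report()].
#' @return An `lof_summary` equal (on all numeric fields) to the one written.
#' @export
read_info_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          vapply(kv, `[`, "", 1))
  totals <- c(
    n_lof_variants   = vals[["total_lof_variants"]],
    n_het_variants   = vals[["total_heterozygous_lof_variants"]],
    n_hom_variants   = vals[["total_homozygous_lof_variants"]],
    n_ch_events      = vals[["total_ch_events"]],
    n_lof_genes      = vals[["total_lof_genes"]],
    n_one_copy_genes = vals[["total_one_copy_lof_genes"]],
    n_two_copy_genes = vals[["total_two_copy_lof_genes"]])
  metrics <- c("lof_variants", "het_variants", "hom_variants",
               "one_copy_genes", "two_copy_genes")
  per_sample <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (stat in c("mean", "median", "min", "max")) {
    per_sample[[stat]] <- vapply(
      metrics, function(m) vals[[paste0(stat, "_", m, "_per_individual")]],
      0.0)
  }
  rownames(per_sample) <- NULL
  structure(list(totals = totals, per_sample = per_sample),
            class = "lof_summary")
}

#' Write the tabular outputs of a call set
#'
#' Writes the variant zygosity matrix (`<prefix>_lof_variants.tsv`: variant
#' id, gene, consequence, het/hom frequencies, then one column per sample),
#' the gene copy-loss matrix (`<prefix>_lof_genes.tsv`), the allele-frequency
#' listing (`<prefix>_allele_frequencies.tsv`), the compound-het events
#' (`<prefix>_ch_events.tsv`) and the `.info` report (`<prefix>.info`).
#'
#' @param result An [lof_call()] result.
#' @param dir Output directory (created if absent).
#' @param prefix File name prefix, default `"lof"`.
#' @param provenance Named list forwarded to [write_info_report()].
#' @return Named character vector of the paths written, invisibly.
#' @export
write_lof_result <- function(result, dir, prefix = "lof",
                             provenance = list()) {
  stopifnot(inherits(result, "lof_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  tsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  vtab <- cbind(
    data.frame(SNP_ID = result$variants$variant_id,
               gene_ID = result$variants$gene_id,
               Consequence = result$variants$consequence,
               heterozygous_LoF_frequency = result$variants$het_frequency,
               homozygous_LoF_frequency = result$variants$hom_frequency,
               stringsAsFactors = FALSE),
    as.data.frame(result$variant_matrix, optional = TRUE))
  gtab <- cbind(
    data.frame(gene_ID = result$genes$gene_id,
               gene_symbol = result$genes$gene_symbol,
               `1_copy_LoF_frequency` = result$genes$one_copy_frequency,
               `2_copy_LoF_frequency` = result$genes$two_copy_frequency,
               stringsAsFactors = FALSE, check.names = FALSE),
    as.data.frame(result$gene_matrix, optional = TRUE))
  afreq <- unique(data.frame(SNP_ID = result$variants$variant_id,
                             allele_frequency = result$variants$allele_frequency,
                             stringsAsFactors = FALSE))
  paths <- c(
    variants = tsv(vtab, p("_lof_variants.tsv")),
    genes = tsv(gtab, p("_lof_genes.tsv")),
    allele_frequencies = tsv(afreq, p("_allele_frequencies.tsv")),
    ch_events = tsv(result$ch_events, p("_ch_events.tsv")),
    info = write_info_report(summary(result), p(".info"), provenance))
  invisible(paths)
}
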