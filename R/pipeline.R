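# End-to-end workflow: optional IMPUTE2 preprocessing, HC LoF calling,
# matrices, descriptive report, and the optional trio / sample-pair
# analyses. The external VEP/LOFTEE annotation step is represented by a
# pluggable hook.

#' Assemble and validate a pipeline run configuration
#'
#' @param input_format `"vcf"` or `"impute2"`.
#' @param vcf Annotated VCF path (for `input_format = "vcf"`).
#' @param gen,haps,sample,info IMPUTE2 file set (for `"impute2"`).
#' @param out_dir Output directory.
#' @param prefix Output file prefix, default `"lof"`.
#' @param min_info,prob_cutoff Imputation-quality thresholds (see
#'   [filter_by_info()], [call_genotype()]).
#' @param transcript_policy,keep_flagged HC filtering options (see
#'   [filter_hc()]).
#' @param assume_unphased Treat all genotypes as unphased regardless of the
#'   `GT` separators?
#' @param pedigree Optional PED-like pedigree path; triggers trio
#'   transmission validation of the proband compound hets.
#' @param pairs Optional two-column (`sample_a`, `sample_b`) TSV path;
#'   triggers mismatched-gene comparison.
#' @param annotate Annotation hook for IMPUTE2 input: a function
#'   `function(vcf_path) -> annotated_vcf_path` that runs the external
#'   VEP + LOFTEE step (or injects prepared CSQ annotations). `NULL` leaves
#'   the converted VCF unannotated, which yields an empty (but valid) HC
#'   call set.
#' @param seed Integer seed recorded in the resolved configuration.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input_format = c("vcf", "impute2"), vcf = NULL,
                       gen = NULL, haps = NULL, sample = NULL, info = NULL,
                       out_dir = "lofcall_out", prefix = "lof",
                       min_info = 0.3, prob_cutoff = 0.05,
                       transcript_policy = c("any", "canonical"),
                       keep_flagged = TRUE, assume_unphased = FALSE,
                       pedigree = NULL, pairs = NULL, annotate = NULL,
                       seed = 1L) {
  input_format <- match.arg(input_format)
  transcript_policy <- match.arg(transcript_policy)
  stopifnot(min_info >= 0, min_info <= 1,
            prob_cutoff >= 0, prob_cutoff <= 1)
  required <- if (input_format == "vcf") c(vcf = vcf)
              else c(gen = gen, haps = haps, sample = sample, info = info)
  if (length(required) == 0 || any(vapply(required, is.null, TRUE))) {
    fail("input_format '", input_format, "' requires ",
         if (input_format == "vcf") "a 'vcf' path"
         else "'gen', 'haps', 'sample' and 'info' paths")
  }
  for (nm in names(required)) {
    if (!file.exists(required[[nm]])) {
      fail("input file for '", nm, "' not found: ", required[[nm]])
    }
  }
  for (p in c(pedigree, pairs)) {
    if (!is.null(p) && !file.exists(p)) fail("input file not found: ", p)
  }
  structure(as.list(environment())[c(
    "input_format", "vcf", "gen", "haps", "sample", "info", "out_dir",
    "prefix", "min_info", "prob_cutoff", "transcript_policy",
    "keep_flagged", "assume_unphased", "pedigree", "pairs", "annotate",
    "seed")], class = "run_config")
}

write_resolved_config <- function(config, path) {
  scalar <- function(v) {
    if (is.null(v)) "" else if (is.function(v)) "<function>"
    else paste(as.character(v), collapse = ",")
  }
  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, scalar, "")), path)
  invisible(path)
}

#' Run the full LoF-calling workflow
#'
#' Executes, with step-level logging: (1) IMPUTE2 quality filtering and
#' conversion to phased VCF plus the annotation hook, when the input is
#' IMPUTE2; (2) reading the annotated VCF and HC LoF filtering; (3) variant
#' zygosity and gene copy-loss matrices, compound-het events and mechanism
#' classification; (4) the descriptive `.info` report — then the optional
#' trio transmission validation and sample-pair mismatch analysis. All
#' inputs are validated before anything is written. The resolved
#' configuration is written next to the outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the [lof_call()] `result`, the
#'   [summary.lof_result()] `summary`, optional `transmission` and
#'   `mismatches`, and the named vector of output `paths`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(config = write_resolved_config(
    config, file.path(config$out_dir, paste0(config$prefix, "_config.txt"))))

  vcf <- config$vcf
  if (config$input_format == "impute2") {
    vcf <- file.path(config$out_dir, paste0(config$prefix, "_converted.vcf"))
    lof_log("step 1: filtering IMPUTE2 genotypes (info > ",
            config$min_info, ", probability cutoff ", config$prob_cutoff,
            ") and converting to VCF")
    convert_to_vcf(config$gen, config$haps, config$sample, config$info,
                   vcf, min_info = config$min_info,
                   prob_cutoff = config$prob_cutoff)
    paths["converted_vcf"] <- vcf
    if (!is.null(config$annotate)) {
      lof_log("step 2: running annotation hook")
      vcf <- config$annotate(vcf)
    } else {
      lof_log("step 2: no annotation hook supplied; ",
              "proceeding with the unannotated conversion")
    }
  }

  lof_log("reading annotated VCF: ", vcf)
  cohort <- read_annotated_vcf(vcf)
  if (config$assume_unphased) cohort <- strip_phase(cohort)
  lof_log("cohort: ", nrow(cohort$variants), " variants x ",
          length(cohort$samples), " samples (phased: ", cohort$phased, ")")

  lof_log("step 3: HC LoF filtering, matrices and compound-het detection")
  result <- lof_call(cohort, transcript_policy = config$transcript_policy,
                     keep_flagged = config$keep_flagged)
  lof_log("HC LoF variants: ", length(unique(result$variants$variant_id)),
          " in ", nrow(result$genes), " genes; CH events: ",
          nrow(result$ch_events))

  lof_log("step 4: descriptive statistics and outputs")
  prov <- list(input = vcf, min_info = config$min_info,
               prob_cutoff = config$prob_cutoff,
               transcript_policy = config$transcript_policy,
               seed = config$seed)
  paths <- c(paths, write_lof_result(result, config$out_dir,
                                     prefix = config$prefix,
                                     provenance = prov))
  hc_vcf <- file.path(config$out_dir, paste0(config$prefix, "_hc.vcf"))
  write_cohort_vcf(cohort, hc_vcf, hc_only = TRUE)
  paths["hc_vcf"] <- hc_vcf

  out <- list(result = result, summary = summary(result), paths = paths)

  if (!is.null(config$pedigree)) {
    lof_log("trio validation from pedigree: ", config$pedigree)
    ped <- read_pedigree(config$pedigree)
    trios <- trios_from_pedigree(ped, cohort)
    tx <- validate_ch_transmission(trios, result$ch_events, cohort)
    tx_path <- file.path(config$out_dir,
                         paste0(config$prefix, "_transmission.tsv"))
    utils::write.table(tx$results, tx_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["transmission"] <- tx_path
    out$transmission <- tx
  }
  if (!is.null(config$pairs)) {
    lof_log("mismatched-gene analysis from pairs: ", config$pairs)
    pr <- utils::read.table(config$pairs, header = TRUE,
                            stringsAsFactors = FALSE)
    names(pr)[1:2] <- c("sample_a", "sample_b")
    mm <- mismatch_genes(list(copies = result$gene_matrix,
                              genes = result$genes$gene_id), pr)
    mm_path <- file.path(config$out_dir,
                         paste0(config$prefix, "_mismatched_genes.tsv"))
    utils::write.table(mm, mm_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths["mismatches"] <- mm_path
    out$mismatches <- mm
  }
  out$paths <- paths
  invisible(out)
}

#' Inject prepared CSQ annotations into a VCF
#'
#' A ready-made [run_config()] annotation hook for workflows where the
#' VEP/LOFTEE consequences are available as a table (e.g. annotations
#' produced once for a variant panel): rewrites the VCF with
#' `CSQ=<entries>` INFO fields looked up by variant id.
#'
#' @param csq_table `data.frame` with columns `variant_id` and `csq` (the
#'   full CSQ string for that variant).
#' @param csq_format The pipe-separated CSQ sub-field list for the header.
#' @return A function `function(vcf_path) -> vcf_path` usable as the
#'   `annotate` hook.
#' @export
csq_table_annotator <- function(csq_table, csq_format = default_csq_format) {
  force(csq_table)
  function(vcf_path) {
    lines <- readLines(vcf_path)
    is_meta <- startsWith(lines, "##")
    hdr <- which(startsWith(lines, "#") & !is_meta)[1]
    body <- if (hdr < length(lines)) lines[(hdr + 1):length(lines)]
            else character(0)
    fields <- strsplit(body, "\t", fixed = TRUE)
    out_body <- vapply(fields, function(f) {
      id <- variant_id(f[1], f[2], f[4], f[5])
      hit <- match(id, csq_table$variant_id)
      if (!is.na(hit)) f[8] <- paste0("CSQ=", csq_table$csq[hit])
      paste(f, collapse = "\t")
    }, "")
    meta <- lines[is_meta]
    if (!any(grepl("^##INFO=<ID=CSQ", meta))) {
      meta <- append(meta, minimal_meta(csq_format)[2], after = 1)
    }
    out <- c(meta, lines[hdr], out_body)
    out_path <- sub("\\.vcf$", "_annotated.vcf", vcf_path)
    if (identical(out_path, vcf_path)) out_path <- paste0(vcf_path, ".ann")
    writeLines(out, out_path)
    out_path
  }
}
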