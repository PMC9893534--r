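# VCF input/output for VEP/LOFTEE-annotated, phased cohorts. Parsing of the
# VCF container is delegated to vcfR; this file owns the genotype-string
# semantics, multi-allelic normalization and the CSQ plumbing.

#' Read a VEP/LOFTEE-annotated VCF into a cohort
#'
#' Parses a VCF (plain or gzip-compressed) with per-sample `GT` genotypes and
#' VEP `CSQ` INFO annotations into an [lof_cohort()]. Genotypes separated by
#' `|` are phased, `/` unphased; `.` alleles make a call missing (a
#' half-missing call such as `./1` is treated as fully missing). Hemizygous
#' single-allele genotypes are treated as homozygous for copy-loss purposes
#' and counted in a log message. Multi-allelic records are split into one
#' biallelic variant per alternate allele (see [split_multiallelic()]).
#'
#' @param path Path to the VCF file.
#' @param schema Optional [parse_csq_schema()] result; by default the schema
#'   is derived from the file's own header.
#' @return An `lof_cohort` carrying the original header lines (`$meta`) and
#'   the CSQ `$schema`, so that [write_cohort_vcf()] can round-trip it.
#' @export
read_annotated_vcf <- function(path, schema = NULL) {
  if (!file.exists(path)) fail("input VCF not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE), error = function(e) e)
  if (inherits(v, "error")) {
    # vcfR rejects record-less files; a header-only VCF is still legal input
    con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
    lines <- readLines(con)
    close(con)
    header <- grep("^#", lines, value = TRUE)
    if (length(header) != length(lines) || length(header) == 0) stop(v)
    meta <- grep("^##", header, value = TRUE)
    cols <- strsplit(header[length(header)], "\t", fixed = TRUE)[[1]]
    samples <- if (length(cols) > 9) cols[-(1:9)] else character(0)
    if (is.null(schema)) schema <- parse_csq_schema(meta)
    return(empty_cohort(samples, schema, meta))
  }
  meta <- v@meta
  if (is.null(schema)) schema <- parse_csq_schema(meta)
  fix <- v@fix
  gt <- v@gt
  n_rec <- nrow(fix)
  samples <- colnames(gt)[-1]
  # data line numbers in the file, for record-level error messages
  line_no <- length(meta) + 1L + seq_len(max(n_rec, 0L))

  if (n_rec == 0) {
    return(empty_cohort(samples, schema, meta))
  }

  fmt_first <- sub(":.*$", "", gt[, 1])
  if (any(fmt_first != "GT")) {
    fail("FORMAT must begin with GT (line ",
         line_no[which(fmt_first != "GT")[1]], ")")
  }
  gt_only <- sub(":.*$", "", gt[, -1, drop = FALSE])
  gt_only[is.na(gt_only)] <- "./."
  parsed <- parse_gt_matrix(gt_only, line_no)

  info <- fix[, "INFO"]
  csq_raw <- extract_info_field(info, "CSQ")
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)

  rec_list <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec_list[[r]] <- split_multiallelic(list(
      chrom = fix[r, "CHROM"], pos = as.integer(fix[r, "POS"]),
      ref = fix[r, "REF"], alt = alts[[r]],
      allele_a = parsed$a[r, ], allele_b = parsed$b[r, ],
      phased = parsed$phased[r, ], csq = csq_raw[r],
      n_hemi = sum(parsed$hemi[r, ])
    ), schema, line = line_no[r])
  }
  assemble_cohort(rec_list, samples, schema, meta)
}

empty_cohort <- function(samples, schema, meta) {
  co <- lof_cohort(
    samples = samples,
    variants = data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          stringsAsFactors = FALSE),
    csq = cbind(empty_csq_table()[0, -1], variant = integer()),
    geno_a = matrix(integer(), 0, length(samples)),
    geno_b = matrix(integer(), 0, length(samples)),
    phased = matrix(logical(), 0, length(samples)))
  co$schema <- schema
  co$meta <- meta
  co
}

# Stack per-record split results into one lof_cohort.
assemble_cohort <- function(rec_list, samples, schema, meta) {
  recs <- unlist(rec_list, recursive = FALSE)
  if (length(recs) == 0) return(empty_cohort(samples, schema, meta))
  variants <- data.frame(
    chrom = vapply(recs, `[[`, "", "chrom"),
    pos   = vapply(recs, `[[`, 0L, "pos"),
    ref   = vapply(recs, `[[`, "", "ref"),
    alt   = vapply(recs, `[[`, "", "alt"),
    stringsAsFactors = FALSE)
  geno_a <- do.call(rbind, lapply(recs, `[[`, "allele_a"))
  geno_b <- do.call(rbind, lapply(recs, `[[`, "allele_b"))
  phased <- do.call(rbind, lapply(recs, `[[`, "phased"))
  csq_per <- lapply(recs, `[[`, "csq_table")
  n_per <- vapply(csq_per, nrow, 0L)
  csq <- do.call(rbind, csq_per)
  if (is.null(csq)) csq <- empty_csq_table()
  csq$variant <- rep.int(seq_along(recs), n_per)
  csq <- csq[, c("variant", setdiff(names(csq), c("variant", "record")))]
  n_hemi <- sum(vapply(recs, function(r) r$n_hemi, 0L))
  if (n_hemi > 0) {
    lof_log(n_hemi, " hemizygous single-allele genotype(s) treated as homozygous")
  }
  co <- lof_cohort(samples = samples, variants = variants, csq = csq,
                   geno_a = geno_a, geno_b = geno_b, phased = phased)
  co$schema <- schema
  co$meta <- meta
  co
}

# Vectorized GT parsing over a character matrix (records x samples).
# Returns integer allele matrices with *raw* (unremapped) indices, a phased
# flag matrix and a hemizygous-call indicator.
parse_gt_matrix <- function(g, line_no) {
  ok <- grepl("^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$", g)
  dim(ok) <- dim(g)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    fail("malformed GT '", g[bad[1], bad[2]], "' at line ", line_no[bad[1]],
         ", sample column ", bad[2])
  }
  has_sep <- grepl("[/|]", g)
  phased <- grepl("|", g, fixed = TRUE)
  a_chr <- sub("^([^/|]+).*$", "\\1", g)
  b_chr <- ifelse(has_sep, sub("^[^/|]+[/|](.*)$", "\\1", g), a_chr)
  a <- suppressWarnings(as.integer(a_chr))  # "." -> NA
  b <- suppressWarnings(as.integer(b_chr))
  miss <- is.na(a) | is.na(b)
  a[miss] <- NA_integer_
  b[miss] <- NA_integer_
  hemi <- !has_sep & !miss
  dim(a) <- dim(b) <- dim(phased) <- dim(hemi) <- dim(g)
  phased[hemi | miss] <- TRUE  # no phase ambiguity without two known alleles
  list(a = a, b = b, phased = phased, hemi = hemi)
}

extract_info_field <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]*)")
  m <- regmatches(info, regexpr(pat, info, perl = TRUE))
  out <- rep("", length(info))
  hit <- grepl(pat, info, perl = TRUE)
  out[hit] <- sub(pat, "\\1", m, perl = TRUE)
  out
}

#' Split a (possibly multi-allelic) record into biallelic variants
#'
#' Produces one normalized variant per alternate allele. For each focal
#' alternate, genotype allele indices are remapped so the focal allele is 1
#' and every other allele (reference or non-focal alternate) is 0 — a
#' non-focal alternate does not contribute loss of function for the focal
#' variant. CSQ entries are assigned to the matching alternate via the CSQ
#' `Allele` sub-field (exact match or VEP's minimal indel representation);
#' entries matching no alternate are dropped with a warning.
#'
#' @param record List with `chrom`, `pos` (1-based), `ref`, `alt` (character
#'   vector of alternates), `allele_a`/`allele_b` (integer raw allele indices
#'   per sample, `NA` = missing), `phased` (logical per sample) and `csq`
#'   (the raw CSQ string, possibly empty).
#' @param schema A [parse_csq_schema()] result.
#' @param line Optional source line number, used in error messages.
#' @return List of one record per alternate allele, each with remapped
#'   `allele_a`/`allele_b`, its `csq_table` of parsed consequences, and a
#'   hemizygous-call count `n_hemi`.
#' @export
split_multiallelic <- function(record, schema, line = NA) {
  n_alt <- length(record$alt)
  max_idx <- suppressWarnings(max(c(record$allele_a, record$allele_b),
                                  na.rm = TRUE))
  if (is.finite(max_idx) && max_idx > n_alt) {
    fail("GT allele index ", max_idx, " exceeds the ", n_alt,
         " alternate allele(s)", if (!is.na(line)) paste0(" at line ", line))
  }
  csq_tab <- if (nzchar(record$csq)) {
    parse_csq_strings(record$csq, schema)
  } else {
    empty_csq_table()
  }
  # which alternate does each CSQ entry describe?
  if (nrow(csq_tab) > 0 && !is.na(schema$index_of_allele)) {
    vep_alt <- vep_allele(rep(record$ref, n_alt), record$alt)
    alt_of <- match(csq_tab$allele, record$alt)
    alt_of[is.na(alt_of)] <- match(csq_tab$allele[is.na(alt_of)], vep_alt)
    if (anyNA(alt_of)) {
      warning("dropped ", sum(is.na(alt_of)),
              " CSQ entr(ies) whose Allele matches no alternate at ",
              record$chrom, ":", record$pos, call. = FALSE)
      csq_tab <- csq_tab[!is.na(alt_of), , drop = FALSE]
      alt_of <- alt_of[!is.na(alt_of)]
    }
  } else {
    alt_of <- rep(1L, nrow(csq_tab))
    if (n_alt > 1 && nrow(csq_tab) > 0) {
      warning("CSQ schema has no Allele sub-field; assigning all ",
              "consequences to every alternate of a multi-allelic record",
              call. = FALSE)
      alt_of <- NULL  # signal: assign to all alts
    }
  }
  lapply(seq_len(n_alt), function(k) {
    keep <- if (is.null(alt_of)) rep(TRUE, nrow(csq_tab)) else alt_of == k
    list(chrom = record$chrom, pos = record$pos, ref = record$ref,
         alt = record$alt[k],
         allele_a = ifelse(is.na(record$allele_a), NA_integer_,
                           as.integer(record$allele_a == k)),
         allele_b = ifelse(is.na(record$allele_b), NA_integer_,
                           as.integer(record$allele_b == k)),
         phased = record$phased,
         csq_table = csq_tab[keep, , drop = FALSE],
         n_hemi = sum(record$n_hemi %||% 0L))
  })
}

default_csq_format <- "Allele|Consequence|SYMBOL|Gene|Feature|LoF|LoF_flags"

minimal_meta <- function(csq_format = default_csq_format) {
  c("##fileformat=VCFv4.2",
    paste0('##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence ',
           'annotations from Ensembl VEP. Format: ', csq_format, '">'),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
}

#' Write a cohort to a VCF file
#'
#' Serializes an [lof_cohort()] back to a VCF with phased `GT` genotypes and
#' the verbatim CSQ annotation strings, preserving the original header (plus
#' one provenance line) when the cohort was read from a file. With
#' `hc_only = TRUE` only variants carrying at least one high-confidence LoF
#' annotation are written.
#'
#' @param cohort An `lof_cohort`.
#' @param path Output path (`.vcf`; plain text).
#' @param hc_only Restrict output to HC LoF variants?
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, hc_only = FALSE) {
  stopifnot(inherits(cohort, "lof_cohort"))
  if (hc_only) {
    keep <- sort(unique(cohort$csq$variant[cohort$csq$lof_class == "HC"]))
    cohort <- subset_cohort(cohort, variants = keep)
  }
  meta <- cohort$meta %||% minimal_meta()
  meta <- c(meta, paste0("##lofcall_provenance=written by lofcall ",
                         as.character(utils::packageVersion("lofcall"))))
  n_var <- nrow(cohort$variants)
  csq_str <- rep(".", n_var)
  if (nrow(cohort$csq) > 0) {
    agg <- vapply(split(cohort$csq$raw, cohort$csq$variant),
                  paste, "", collapse = ",")
    idx <- as.integer(names(agg))
    csq_str[idx] <- paste0("CSQ=", agg)
  }
  sep <- ifelse(cohort$phased_call, "|", "/")
  gt <- matrix(paste0(cohort$geno_a, sep, cohort$geno_b),
               n_var, length(cohort$samples))
  gt[is.na(cohort$geno_a)] <- "./."
  body <- if (n_var > 0) {
    b <- paste(cohort$variants$chrom, cohort$variants$pos,
               cohort$variants$id, cohort$variants$ref,
               cohort$variants$alt, ".", "PASS", csq_str, "GT",
               sep = "\t")
    if (length(cohort$samples) > 0) {
      b <- paste(b, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    }
    b
  } else character(0)
  header_line <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", cohort$samples),
                       collapse = "\t")
  writeLines(c(meta, header_line, body), path)
  invisible(path)
}
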