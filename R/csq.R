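# Parsing of the VEP-style CSQ INFO annotation: the contract boundary with
# the external annotation step (VEP + LOFTEE). The CSQ field packs one
# pipe-separated sub-annotation per transcript; LOFTEE adds the `LoF`
# (HC/LC) and `LoF_flags` sub-fields.

#' Parse the CSQ annotation schema from a VCF header
#'
#' Reads the `##INFO=<ID=CSQ,...>` definition and derives the ordered list of
#' pipe-separated sub-field names from its `Format:` description, resolving
#' the positions of the sub-fields this package consumes (gene, symbol,
#' consequence, LoF confidence class, LoF flags).
#'
#' @param header_text VCF header as a character vector of lines (or one
#'   string with embedded newlines).
#' @return An object of class `csq_schema`: a list with `field_names` and
#'   integer 1-based indices `index_of_allele`, `index_of_gene`,
#'   `index_of_symbol`, `index_of_consequence`, `index_of_feature`,
#'   `index_of_lof`, `index_of_lof_flags` (`index_of_allele` and
#'   `index_of_feature` are `NA` when absent; the others are required).
#' @examples
#' hdr <- '##INFO=<ID=CSQ,Number=.,Type=String,Description="Consequence
#'   annotations. Format: Allele|Consequence|SYMBOL|Gene|LoF|LoF_flags">'
#' sch <- parse_csq_schema(gsub("\n\\s*", " ", hdr))
#' sch$index_of_lof
#' @export
parse_csq_schema <- function(header_text) {
  lines <- unlist(strsplit(header_text, "\n", fixed = TRUE))
  csq_line <- grep("^##INFO=<ID=CSQ[,>]", lines, value = TRUE)
  if (length(csq_line) == 0) {
    fail("no CSQ INFO definition found in VCF header; ",
         "the input must be annotated by VEP/LOFTEE first")
  }
  m <- regmatches(csq_line[1],
                  regexpr("Format:\\s*[^\">]+", csq_line[1]))
  if (length(m) == 0) {
    fail("CSQ INFO definition lacks a 'Format:' sub-field list")
  }
  fmt <- sub("^Format:\\s*", "", m)
  fmt <- sub("\\s+$", "", fmt)
  fields <- strsplit(fmt, "|", fixed = TRUE)[[1]]
  if (anyDuplicated(fields)) {
    fail("duplicate CSQ sub-field names in header: ",
         paste(unique(fields[duplicated(fields)]), collapse = ", "))
  }
  idx <- function(name, required = TRUE) {
    i <- match(name, fields)
    if (required && is.na(i)) {
      fail("CSQ schema is missing the required sub-field '", name, "'")
    }
    i
  }
  structure(list(
    field_names          = fields,
    index_of_allele      = idx("Allele", required = FALSE),
    index_of_consequence = idx("Consequence"),
    index_of_symbol      = idx("SYMBOL"),
    index_of_gene        = idx("Gene"),
    index_of_feature     = idx("Feature", required = FALSE),
    index_of_lof         = idx("LoF"),
    index_of_lof_flags   = idx("LoF_flags")
  ), class = "csq_schema")
}

#' @export
print.csq_schema <- function(x, ...) {
  cat("CSQ schema:", length(x$field_names), "sub-fields\n")
  cat("  ", paste(x$field_names, collapse = "|"), "\n", sep = "")
  cat("  LoF at position", x$index_of_lof,
      "| gene at position", x$index_of_gene, "\n")
  invisible(x)
}

# Parse CSQ strings (one per record, comma-separated transcript entries) into
# one long data.frame of transcript consequences. `record` indexes the input.
parse_csq_strings <- function(csq, schema) {
  entries <- strsplit(csq, ",", fixed = TRUE)
  n_per <- lengths(entries)
  flat <- unlist(entries, use.names = FALSE)
  record <- rep.int(seq_along(csq), n_per)
  if (length(flat) == 0) {
    return(empty_csq_table())
  }
  parts <- strsplit(flat, "|", fixed = TRUE)
  n_fields <- length(schema$field_names)
  arity <- lengths(parts)
  # trailing empty sub-fields are dropped by strsplit; pad them back
  bad <- arity > n_fields
  if (any(bad)) {
    fail("CSQ entry with ", arity[which(bad)[1]], " sub-fields where schema has ",
         n_fields, " (record ", record[which(bad)[1]], ")")
  }
  mat <- matrix("", nrow = length(parts), ncol = n_fields)
  idx_rows <- rep.int(seq_along(parts), arity)
  idx_cols <- unlist(lapply(arity, seq_len), use.names = FALSE)
  mat[cbind(idx_rows, idx_cols)] <- unlist(parts, use.names = FALSE)

  pick <- function(i) if (is.na(i)) rep("", nrow(mat)) else mat[, i]
  lof_raw <- pick(schema$index_of_lof)
  lof_class <- ifelse(lof_raw == "", "NONE",
                      ifelse(lof_raw %in% c("HC", "LC"), lof_raw, "NONE"))
  unknown <- lof_raw != "" & !(lof_raw %in% c("HC", "LC"))
  if (any(unknown)) {
    warning("unrecognized LoF class token(s) treated as NONE: ",
            paste(unique(lof_raw[unknown]), collapse = ", "), call. = FALSE)
  }
  data.frame(
    record        = record,
    allele        = pick(schema$index_of_allele),
    consequence   = pick(schema$index_of_consequence),
    gene_symbol   = pick(schema$index_of_symbol),
    gene_id       = pick(schema$index_of_gene),
    transcript_id = pick(schema$index_of_feature),
    lof_class     = lof_class,
    lof_flags     = pick(schema$index_of_lof_flags),
    raw           = flat,
    stringsAsFactors = FALSE
  )
}

empty_csq_table <- function() {
  data.frame(record = integer(), allele = character(),
             consequence = character(), gene_symbol = character(),
             gene_id = character(), transcript_id = character(),
             lof_class = character(), lof_flags = character(),
             raw = character(), stringsAsFactors = FALSE)
}

# VEP's minimal allele representation for indels: when REF and ALT share a
# leading base, VEP reports the ALT with that base stripped ("-" if empty).
vep_allele <- function(ref, alt) {
  same_first <- nchar(ref) > 1 | nchar(alt) > 1
  out <- alt
  shared <- same_first & substr(ref, 1, 1) == substr(alt, 1, 1)
  trimmed <- substring(alt, 2)
  trimmed[trimmed == ""] <- "-"
  out[shared] <- trimmed[shared]
  out
}
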