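# Shared internal helpers: identifiers, ordering, small parsers.

#' Canonical variant identifier
#'
#' Builds the underscore-joined `chrom_pos_ref_alt` key used throughout the
#' package (and in all tabular outputs) to identify a normalized biallelic
#' variant, e.g. `"chr19_52300416_CT_C"`.
#'
#' @param chrom Chromosome name (kept verbatim, including any `chr` prefix).
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate allele strings.
#' @return Character vector of variant identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = "_")
}

# Numeric-aware chromosome rank so "chr2" sorts before "chr10".
chrom_rank <- function(chrom) {
  core <- sub("^chr", "", chrom, ignore.case = TRUE)
  num <- suppressWarnings(as.integer(core))
  special <- match(toupper(core), c("X", "Y", "MT", "M"))
  rank <- ifelse(!is.na(num), num, ifelse(!is.na(special), 100L + special, NA))
  # unknown contigs go last, alphabetically
  ifelse(is.na(rank), 1000L + as.integer(factor(core, levels = sort(unique(core)))), rank)
}

# Deterministic variant ordering: (chrom, pos, ref, alt).
variant_order <- function(chrom, pos, ref, alt) {
  order(chrom_rank(chrom), as.integer(pos), ref, alt, method = "radix")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

lof_log <- function(..., verbose = getOption("lofcall.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[lofcall] ", ...)
}

# stop() without the call, consistently across the package
fail <- function(...) stop(..., call. = FALSE)
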