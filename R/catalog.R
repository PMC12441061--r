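#' Construct a repeat-motif catalog
#'
#' A motif catalog is the alphabet of the VNTR locus: a set of canonical
#' 60-nt repeat units, each identified by a short label. The MUC1-type
#' coding VNTR is built from GC-rich 60-bp units; every allele handled by
#' this package is an ordered array of catalog units.
#'
#' @param motif_id Character vector of unique motif labels.
#' @param sequence Character vector of 60-nt sequences over A/C/G/T,
#'   parallel to `motif_id`.
#' @param source Provenance string recorded on the catalog (e.g. the file
#'   it was read from, or `"synthetic"`).
#'
#' @return An object of class `motif_catalog`: a data frame with columns
#'   `motif_id`, `sequence` and the derived `gc_fraction`, plus a
#'   `source` attribute.
#' @export
#' @examples
#' motif_catalog("u1", strrep("ACGGGC", 10))
motif_catalog <- function(motif_id, sequence, source = "constructed") {
  motif_id <- as.character(motif_id)
  sequence <- toupper(as.character(sequence))
  if (length(motif_id) != length(sequence)) {
    stop("motif_id and sequence must have the same length", call. = FALSE)
  }
  if (anyDuplicated(motif_id)) {
    stop("motif_id values must be unique", call. = FALSE)
  }
  bad_len <- nchar(sequence) != 60L
  if (any(bad_len)) {
    stop("repeat-unit sequences must be exactly 60 nt (offending: ",
         paste(motif_id[bad_len], collapse = ", "), ")", call. = FALSE)
  }
  if (any(grepl("[^ACGT]", sequence))) {
    stop("repeat-unit sequences may only contain A, C, G, T", call. = FALSE)
  }
  cat <- data.frame(
    motif_id = motif_id,
    sequence = sequence,
    gc_fraction = gc_fraction(sequence),
    stringsAsFactors = FALSE
  )
  attr(cat, "source") <- source
  class(cat) <- c("motif_catalog", "data.frame")
  cat
}

#' GC fraction of a nucleotide string
#'
#' @param x Character vector of sequences.
#' @return Numeric vector in `[0, 1]`.
#' @export
gc_fraction <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n > 0L, gc / n, NA_real_)
}

#' Read a motif catalog from a TSV file
#'
#' Expected format: tab-separated columns `motif_id` and `sequence`
#' (header optional), `#` comment lines skipped.
#'
#' @param path Path to the TSV file.
#' @return A [motif_catalog()].
#' @export
read_motif_catalog <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty motif catalog: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("each catalog line needs two tab-separated fields", call. = FALSE)
  }
  ids <- vapply(fields, `[[`, "", 1L)
  seqs <- vapply(fields, `[[`, "", 2L)
  if (identical(tolower(ids[1L]), "motif_id")) {
    ids <- ids[-1L]; seqs <- seqs[-1L]
  }
  motif_catalog(ids, seqs, source = path)
}

#' Write a motif catalog to TSV
#'
#' @param catalog A [motif_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_motif_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "motif_catalog"))
  writeLines(
    c("motif_id\tsequence",
      paste(catalog$motif_id, catalog$sequence, sep = "\t")),
    path
  )
  invisible(path)
}

#' The packaged synthetic motif catalog
#'
#' Five synthetic GC-rich 60-nt repeat units shipped with the package
#' (`inst/extdata/synthetic_motifs.tsv`). These are not real MUC1 repeat
#' units (no published motif inventory exists); they emulate its unit
#' length and GC content so that simulations and the detector can be
#' exercised end to end.
#'
#' @return A [motif_catalog()].
#' @export
synthetic_catalog <- function() {
  read_motif_catalog(
    system.file("extdata", "synthetic_motifs.tsv", package = "vntrscreen",
                mustWork = TRUE)
  )
}

catalog_sequence <- function(catalog, motif_id) {
  i <- match(motif_id, catalog$motif_id)
  if (anyNA(i)) {
    stop("unknown motif_id: ",
         paste(unique(motif_id[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  catalog$sequence[i]
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat("Motif catalog (", nrow(x), " units, source: ",
      attr(x, "source"), ")\n", sep = "")
  NextMethod()
  invisible(x)
}
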