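#' Specify an insertion inside a VNTR allele
#'
#' Coordinates are 0-based and half-open throughout the package: the
#' insertion is placed *before* the base at position `offset` of the
#' repeat unit at (0-based) `repeat_index`. `offset = 0` inserts at the
#' unit's 5' edge; `offset = 60` at its 3' edge. The canonical pathogenic
#' lesion of the MUC1 VNTR is a single cytosine insertion causing a
#' frameshift, so the default `inserted_sequence` is `"C"`.
#'
#' @param repeat_index 0-based index of the repeat unit carrying the
#'   insertion.
#' @param offset 0-based position within the 60-nt unit, in `[0, 60]`.
#' @param inserted_sequence Non-empty A/C/G/T string.
#' @return An object of class `insertion_spec`.
#' @export
insertion_spec <- function(repeat_index, offset, inserted_sequence = "C") {
  repeat_index <- as.integer(repeat_index)
  offset <- as.integer(offset)
  inserted_sequence <- toupper(as.character(inserted_sequence))
  if (length(repeat_index) != 1L || is.na(repeat_index) || repeat_index < 0L) {
    stop("repeat_index must be a single non-negative integer", call. = FALSE)
  }
  if (length(offset) != 1L || is.na(offset) || offset < 0L || offset > 60L) {
    stop("offset must be in [0, 60]", call. = FALSE)
  }
  if (length(inserted_sequence) != 1L || nchar(inserted_sequence) == 0L ||
      grepl("[^ACGT]", inserted_sequence)) {
    stop("inserted_sequence must be a non-empty A/C/G/T string",
         call. = FALSE)
  }
  structure(
    list(repeat_index = repeat_index, offset = offset,
         inserted_sequence = inserted_sequence),
    class = "insertion_spec"
  )
}

#' Construct a VNTR allele
#'
#' An allele is an ordered array of repeat-unit labels, an optional
#' [insertion_spec()], and 5'/3' flanking anchor sequences. Real alleles
#' of the locus carry between 20 and 125 units; the constructor itself
#' does not enforce that range (the simulator's defaults do) so that
#' tiny alleles can be built for testing.
#'
#' @param repeat_units Character vector of motif_ids, in order.
#' @param insertion Optional [insertion_spec()].
#' @param flank_5p,flank_3p Non-repetitive anchor sequences (may be `""`).
#' @return An object of class `vntr_allele`.
#' @export
vntr_allele <- function(repeat_units, insertion = NULL,
                        flank_5p = "", flank_3p = "") {
  repeat_units <- as.character(repeat_units)
  if (length(repeat_units) == 0L) {
    stop("an allele needs at least one repeat unit", call. = FALSE)
  }
  if (!is.null(insertion) && !inherits(insertion, "insertion_spec")) {
    stop("insertion must be an insertion_spec or NULL", call. = FALSE)
  }
  if (!is.null(insertion) &&
      insertion$repeat_index >= length(repeat_units)) {
    stop("insertion repeat_index (", insertion$repeat_index,
         ") outside the allele's ", length(repeat_units), " repeat units",
         call. = FALSE)
  }
  structure(
    list(repeat_units = repeat_units, insertion = insertion,
         flank_5p = toupper(flank_5p), flank_3p = toupper(flank_3p)),
    class = "vntr_allele"
  )
}

#' Render an allele to its nucleotide sequence
#'
#' Concatenates `flank_5p`, the repeat units in order with the insertion
#' (if any) spliced in at its 0-based (repeat_index, offset) coordinate,
#' and `flank_3p`. The rendered length is
#' `60 * n_units + nchar(inserted_sequence) + nchar(flanks)`.
#'
#' @param allele A [vntr_allele()].
#' @param catalog A [motif_catalog()] resolving every motif_id used.
#' @return A single nucleotide string.
#' @export
#' @examples
#' cat <- motif_catalog("u1", strrep("ACGGGC", 10))
#' al <- vntr_allele(rep("u1", 3), insertion_spec(1, 5, "C"))
#' nchar(render_allele(al, cat))  # 3 * 60 + 1
render_allele <- function(allele, catalog) {
  stopifnot(inherits(allele, "vntr_allele"), inherits(catalog, "motif_catalog"))
  units <- catalog_sequence(catalog, allele$repeat_units)
  body <- paste(units, collapse = "")
  ins <- allele$insertion
  if (!is.null(ins)) {
    if (ins$repeat_index >= length(units)) {
      stop("insertion repeat_index out of bounds", call. = FALSE)
    }
    pos <- 60L * ins$repeat_index + ins$offset  # bases to the left
    body <- paste0(substr(body, 1L, pos), ins$inserted_sequence,
                   substr(body, pos + 1L, nchar(body)))
  }
  paste0(allele$flank_5p, body, allele$flank_3p)
}

#' VNTR portion of a rendered allele (flanks stripped)
#' @noRd
render_vntr <- function(allele, catalog) {
  s <- render_allele(allele, catalog)
  substr(s, nchar(allele$flank_5p) + 1L,
         nchar(s) - nchar(allele$flank_3p))
}

#' Left-normalise an insertion point within a sequence
#'
#' An insertion of `ins` before 0-based position `pos` of `ref` can be
#' equivalent to insertions at neighbouring positions (e.g. adding a C
#' anywhere inside a C homopolymer). This shifts the representation to
#' the leftmost equivalent `(pos, ins)` pair, the same normalisation used
#' for VCF indels, so that call coordinates can be compared.
#'
#' @param ref The insertion-free sequence (no flanks).
#' @param pos 0-based insertion point (insertion goes before `ref[pos]`).
#' @param ins Inserted sequence.
#' @return List with left-normalised `pos` and `ins`.
#' @export
normalize_insertion_point <- function(ref, pos, ins) {
  pos <- as.integer(pos)
  L <- nchar(ins)
  # shifting left by one is valid iff the last inserted base equals the
  # reference base immediately left of the insertion point
  while (pos > 0L &&
         substr(ins, L, L) == substr(ref, pos, pos)) {
    ins <- paste0(substr(ref, pos, pos), substr(ins, 1L, L - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, ins = ins)
}

#' @export
print.vntr_allele <- function(x, ...) {
  cat("VNTR allele: ", length(x$repeat_units), " units",
      if (!is.null(x$insertion)) {
        sprintf(" + insertion '%s' at unit %d offset %d",
                x$insertion$inserted_sequence, x$insertion$repeat_index,
                x$insertion$offset)
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' Serialise / deserialise alleles as JSON
#'
#' @param allele A [vntr_allele()].
#' @param path File path.
#' @return `write_allele_json` returns `path` invisibly;
#'   `read_allele_json` returns a [vntr_allele()].
#' @export
write_allele_json <- function(allele, path) {
  stopifnot(inherits(allele, "vntr_allele"))
  x <- list(repeat_units = allele$repeat_units,
            insertion = if (!is.null(allele$insertion)) {
              allele$insertion[c("repeat_index", "offset",
                                 "inserted_sequence")]
            },
            flank_5p = allele$flank_5p, flank_3p = allele$flank_3p)
  jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_allele_json
#' @export
read_allele_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ins <- if (!is.null(x$insertion)) {
    insertion_spec(x$insertion$repeat_index, x$insertion$offset,
                   x$insertion$inserted_sequence)
  }
  vntr_allele(x$repeat_units, ins,
              flank_5p = x$flank_5p %||% "",
              flank_3p = x$flank_3p %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
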