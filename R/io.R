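#' Write reads to FASTQ / FASTA
#'
#' @param reads Character vector of sequences, or a `short_read_set` /
#'   `long_read_set` (in which case `names`/`qualities` are taken from
#'   the object).
#' @param path Output path.
#' @param names Read names; defaults to `read<i>`.
#' @param qualities Quality strings for FASTQ; default constant Q30.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, names = NULL, qualities = NULL) {
  if (inherits(reads, c("short_read_set", "long_read_set"))) {
    names <- names %||% reads$names
    qualities <- qualities %||% reads$qualities
    reads <- reads$reads
  }
  names <- names %||% sprintf("read%06d", seq_along(reads))
  qualities <- qualities %||% strrep("?", nchar(reads))
  x <- Biostrings::DNAStringSet(stats::setNames(reads, names))
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(qualities))
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_fasta <- function(reads, path, names = NULL) {
  if (inherits(reads, c("short_read_set", "long_read_set"))) {
    names <- names %||% reads$names
    reads <- reads$reads
  }
  names <- names %||% sprintf("read%06d", seq_along(reads))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(stats::setNames(reads, names)), path)
  invisible(path)
}

#' Read sequences from FASTQ, FASTA, SAM or BAM
#'
#' Only the nucleotide sequences are extracted; for SAM/BAM no alignment
#' information is used, so downstream detection stays mapping-free by
#' construction. SAM/BAM support requires the Rsamtools package.
#'
#' @param path One or more input files. Format is inferred from the
#'   extension (`.fastq/.fq[.gz]`, `.fasta/.fa[.gz]`, `.sam`, `.bam`).
#' @return Character vector of read sequences.
#' @export
read_reads <- function(path) {
  out <- lapply(path, function(p) {
    base <- sub("\\.gz$", "", p)
    ext <- tolower(sub(".*\\.", "", base))
    if (ext %in% c("fastq", "fq")) {
      as.character(Biostrings::readDNAStringSet(p, format = "fastq"))
    } else if (ext %in% c("fasta", "fa", "fna")) {
      as.character(Biostrings::readDNAStringSet(p, format = "fasta"))
    } else if (ext %in% c("sam", "bam")) {
      if (!requireNamespace("Rsamtools", quietly = TRUE)) {
        stop("SAM/BAM input requires the Rsamtools package", call. = FALSE)
      }
      bam <- p
      if (ext == "sam") {
        bam <- Rsamtools::asBam(p, tempfile(), overwrite = TRUE,
                                indexDestination = FALSE)
      }
      res <- Rsamtools::scanBam(
        bam, param = Rsamtools::ScanBamParam(what = "seq"))
      as.character(res[[1L]]$seq)
    } else {
      stop("unrecognised read file extension: ", p, call. = FALSE)
    }
  })
  unname(unlist(out))
}
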