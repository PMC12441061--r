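#' Extract the VNTR segment of a long amplicon read
#'
#' Locates approximate matches (substitutions only, at most
#' `max_mismatch_frac` of the flank length) of the 5' and 3' flank
#' anchors in the read, trying the given orientation first and then the
#' reverse complement, and returns the enclosed segment in coding
#' orientation. `NA` signals a read that does not span both anchors.
#'
#' @param read A single read sequence.
#' @param flank_5p,flank_3p Flank anchor sequences, at least 15 nt.
#' @param max_mismatch_frac Mismatch tolerance per flank (default 0.1).
#' @return The VNTR substring, or `NA_character_`.
#' @export
extract_vntr <- function(read, flank_5p, flank_3p,
                         max_mismatch_frac = 0.1) {
  if (nchar(flank_5p) < 15L || nchar(flank_3p) < 15L) {
    stop("flank anchors must be at least 15 nt", call. = FALSE)
  }
  mm5 <- floor(max_mismatch_frac * nchar(flank_5p))
  mm3 <- floor(max_mismatch_frac * nchar(flank_3p))
  try_orient <- function(s) {
    subj <- Biostrings::DNAString(s)
    m5 <- Biostrings::matchPattern(flank_5p, subj, max.mismatch = mm5)
    m3 <- Biostrings::matchPattern(flank_3p, subj, max.mismatch = mm3)
    if (length(m5) == 0L || length(m3) == 0L) return(NA_character_)
    e5 <- BiocGenerics::end(m5)[1L]
    s3 <- BiocGenerics::start(m3)[length(m3)]
    if (s3 <= e5) return(NA_character_)
    substr(s, e5 + 1L, s3 - 1L)
  }
  v <- try_orient(read)
  if (is.na(v)) v <- try_orient(revcomp(read))
  v
}

#' @rdname extract_vntr
#' @param reads Character vector of reads (or a `long_read_set`).
#' @export
extract_vntr_set <- function(reads, flank_5p, flank_3p,
                             max_mismatch_frac = 0.1) {
  if (inherits(reads, "long_read_set")) reads <- reads$reads
  vapply(reads, extract_vntr, "", flank_5p, flank_3p, max_mismatch_frac,
         USE.NAMES = FALSE)
}

#' Cluster extracted VNTR segments into alleles by length
#'
#' Alleles of this locus differ primarily in repeat count, i.e. in steps
#' of 60 nt, so one-dimensional 2-means on segment length separates
#' heterozygous genotypes; clusters whose centroids differ by less than
#' half a unit (30 nt) are merged, which covers homozygous-length
#' genotypes and the 1-bp carrier case (resolved downstream at consensus
#' stage, not here). Errors are substitution-only in this model, so
#' lengths are exact.
#'
#' @param vntrs Character vector of extracted VNTR segments.
#' @param merge_below Centroid distance (nt) under which the two
#'   clusters are merged (default 30).
#' @return List of integer index vectors (one per cluster, ascending
#'   centroid length).
#' @export
cluster_reads_into_alleles <- function(vntrs, merge_below = 30) {
  if (length(vntrs) == 0L) stop("no VNTR segments to cluster", call. = FALSE)
  len <- nchar(vntrs)
  if (diff(range(len)) < merge_below) return(list(seq_along(vntrs)))
  km <- stats::kmeans(matrix(len, ncol = 1L),
                      centers = matrix(range(len), ncol = 1L))
  if (abs(diff(km$centers[, 1L])) < merge_below) {
    return(list(seq_along(vntrs)))
  }
  ord <- order(km$centers[, 1L])
  lapply(ord, function(cl) which(km$cluster == cl))
}

# byte-level mismatch helpers for consensus decomposition
motif_bytes <- function(catalog) {
  t(vapply(catalog$sequence, function(s) as.integer(charToRaw(s)),
           integer(60L), USE.NAMES = FALSE))
}

best_unit_mismatch <- function(unit_mat, mb) {
  # unit_mat: n_cand x 60 integer matrix; mb: n_motif x 60
  mm <- vapply(seq_len(nrow(mb)), function(t) {
    rowSums(unit_mat != matrix(mb[t, ], nrow(unit_mat), 60L, byrow = TRUE))
  }, numeric(nrow(unit_mat)))
  if (is.null(dim(mm))) mm <- matrix(mm, nrow = 1L)
  apply(mm, 1L, min)
}

#' Decompose a read cluster into allele reconstructions
#'
#' Reads in the cluster are partitioned by exact segment length (the
#' substitution-only error model preserves length, so a 1-bp insertion
#' allele forms its own length class even inside a merged cluster). Each
#' length class yields a per-column majority consensus. A consensus whose
#' length is not a multiple of 60 carries an insertion: the insertion
#' point is localised by finding the removal position that makes the
#' remaining sequence tile best (fewest mismatches) into catalog units,
#' anchored at the 5' end, with leftmost tie-breaking, and the resulting
#' call is left-normalised. The reconstruction also carries a 60-bases-
#' per-line text layout in which the insertion line is longer.
#'
#' @param seqs Character vector: the VNTR segments of one cluster.
#' @param catalog A [motif_catalog()] used to phase the unit tiling.
#' @return List of `allele_reconstruction` objects (one per length class
#'   observed), each with fields `consensus_sequence`, `repeat_count`,
#'   `read_count`, `allele_frequency` (filled by the caller),
#'   `insertion_call` (NULL or list with 0-based `repeat_index`,
#'   `offset`, `inserted_sequence`, `normalized_pos`), `layout_text`.
#' @export
decompose_and_call <- function(seqs, catalog) {
  if (length(seqs) == 0L) stop("empty read cluster", call. = FALSE)
  stopifnot(inherits(catalog, "motif_catalog"))
  by_len <- split(seqs, nchar(seqs))
  lapply(by_len, function(grp) {
    cons <- majority_consensus(grp)
    rec <- call_from_consensus(cons, catalog)
    rec$read_count <- length(grp)
    rec
  })
}

majority_consensus <- function(seqs) {
  if (length(seqs) == 1L) return(seqs)
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  cm <- cm[c("A", "C", "G", "T"), , drop = FALSE]
  paste(rownames(cm)[apply(cm, 2L, which.max)], collapse = "")
}

call_from_consensus <- function(cons, catalog) {
  len <- nchar(cons)
  n <- len %/% 60L
  r <- len %% 60L
  if (n == 0L) stop("consensus shorter than one repeat unit", call. = FALSE)
  ins_call <- NULL
  if (r > 0L) {
    p <- locate_insertion(cons, catalog, n, r)
    ins <- substr(cons, p + 1L, p + r)
    ref <- paste0(substr(cons, 1L, p), substr(cons, p + r + 1L, len))
    nrm <- normalize_insertion_point(ref, p, ins)
    repeat_index <- min(nrm$pos %/% 60L, n - 1L)
    ins_call <- list(repeat_index = repeat_index,
                     offset = nrm$pos - 60L * repeat_index,
                     inserted_sequence = nrm$ins,
                     normalized_pos = nrm$pos)
  }
  structure(
    list(consensus_sequence = cons,
         repeat_count = n,
         read_count = NA_integer_,
         allele_frequency = NA_real_,
         insertion_call = ins_call,
         layout_text = layout_60(cons, n, ins_call)),
    class = "allele_reconstruction"
  )
}

# minimal-mismatch removal position p in [0, 60n] for an off-phase
# consensus of length 60n + r; leftmost tie-break
locate_insertion <- function(cons, catalog, n, r) {
  cb <- as.integer(charToRaw(cons))
  mb <- motif_bytes(catalog)
  # in-phase (prefix) and r-shifted (suffix) unit scores
  pre_mat <- t(vapply(seq_len(n), function(i) {
    cb[(60L * (i - 1L) + 1L):(60L * i)]
  }, integer(60L)))
  suf_mat <- t(vapply(seq_len(n), function(i) {
    cb[(60L * (i - 1L) + r + 1L):(60L * i + r)]
  }, integer(60L)))
  s0 <- best_unit_mismatch(pre_mat, mb)
  s1 <- best_unit_mismatch(suf_mat, mb)
  pre_cum <- c(0, cumsum(s0))        # pre_cum[j] = sum s0[1..j-1]
  suf_cum <- c(rev(cumsum(rev(s1))), 0)  # suf_cum[j] = sum s1[j..n]
  # candidate-unit index template: row o+1 keeps all but the r removed
  # bases at offset o of the (60 + r)-wide mixed unit
  offsets <- 0:59
  idx <- t(vapply(offsets, function(o) {
    c(seq_len(o), (o + r + 1L):(60L + r))[seq_len(60L)]
  }, integer(60L)))
  best_p <- -1L; best_score <- Inf
  for (j in seq_len(n)) {
    b <- cb[(60L * (j - 1L) + 1L):(60L * j + r)]
    offs <- if (j == n) 0:60 else offsets
    unit_mat <- matrix(b[t(idx)], ncol = 60L, byrow = TRUE)
    if (j == n) unit_mat <- rbind(unit_mat, b[seq_len(60L)])
    mixed <- best_unit_mismatch(unit_mat, mb)
    score <- pre_cum[j] + mixed + suf_cum[j + 1L]
    o_best <- which.min(score)  # leftmost minimum within the unit
    if (score[o_best] < best_score) {
      best_score <- score[o_best]
      best_p <- 60L * (j - 1L) + offs[o_best]
    }
  }
  best_p
}

layout_60 <- function(cons, n, ins_call) {
  w <- rep(60L, n)
  if (!is.null(ins_call)) {
    w[ins_call$repeat_index + 1L] <- w[ins_call$repeat_index + 1L] +
      nchar(ins_call$inserted_sequence)
  }
  ends <- cumsum(w)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  substring(cons, starts, ends)
}

#' Reconstruct alleles from long amplicon reads
#'
#' Full oracle path: extract the VNTR segment of every spanning read,
#' cluster segments into alleles by length, decompose each cluster into
#' consensus reconstructions, and attach read counts and allele
#' frequencies (fractions of all spanning reads).
#'
#' @param reads A `long_read_set` or character vector of read sequences.
#' @param catalog A [motif_catalog()].
#' @param flank_5p,flank_3p Flank anchors (defaults from
#'   [default_flanks()]).
#' @param max_mismatch_frac Flank matching tolerance.
#' @return An object of class `vntr_reconstruction`: list with `alleles`
#'   (list of `allele_reconstruction`), `n_reads`, `n_spanning`, and a
#'   summary data frame `table` (consensus length, repeat count, read
#'   count, allele frequency, insertion call).
#' @export
reconstruct_alleles <- function(reads, catalog,
                                flank_5p = default_flanks()$flank_5p,
                                flank_3p = default_flanks()$flank_3p,
                                max_mismatch_frac = 0.1) {
  if (inherits(reads, "long_read_set")) reads <- reads$reads
  vn <- extract_vntr_set(reads, flank_5p, flank_3p, max_mismatch_frac)
  spanning <- vn[!is.na(vn)]
  if (length(spanning) == 0L) {
    stop("no read spans both flank anchors", call. = FALSE)
  }
  clusters <- cluster_reads_into_alleles(spanning)
  recs <- unlist(lapply(clusters, function(ix) {
    decompose_and_call(spanning[ix], catalog)
  }), recursive = FALSE)
  for (i in seq_along(recs)) {
    recs[[i]]$allele_frequency <- recs[[i]]$read_count / length(spanning)
  }
  tab <- data.frame(
    consensus_length = vapply(recs, function(x) nchar(x$consensus_sequence),
                              0L),
    repeat_count = vapply(recs, `[[`, 0L, "repeat_count"),
    read_count = vapply(recs, `[[`, 0L, "read_count"),
    allele_frequency = vapply(recs, `[[`, 0, "allele_frequency"),
    insertion = vapply(recs, function(x) {
      if (is.null(x$insertion_call)) "" else
        sprintf("%s@%d:%d", x$insertion_call$inserted_sequence,
                x$insertion_call$repeat_index, x$insertion_call$offset)
    }, ""),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(alleles = unname(recs), n_reads = length(vn),
                 n_spanning = length(spanning), table = tab),
            class = "vntr_reconstruction")
}

#' @export
print.vntr_reconstruction <- function(x, ...) {
  cat("Long-read VNTR reconstruction: ", x$n_spanning, "/", x$n_reads,
      " spanning reads, ", length(x$alleles), " allele(s)\n", sep = "")
  print(x$table, ...)
  invisible(x)
}

#' Write a reconstruction to TSV + 60-column layout text
#'
#' @param x A `vntr_reconstruction`.
#' @param prefix Output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>_layout.txt`.
#' @return The two paths, invisibly.
#' @export
write_reconstruction <- function(x, prefix) {
  stopifnot(inherits(x, "vntr_reconstruction"))
  tsv <- paste0(prefix, ".tsv")
  lay <- paste0(prefix, "_layout.txt")
  utils::write.table(x$table, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- unlist(lapply(seq_along(x$alleles), function(i) {
    c(sprintf(">allele_%d repeats=%d reads=%d", i,
              x$alleles[[i]]$repeat_count, x$alleles[[i]]$read_count),
      x$alleles[[i]]$layout_text)
  }))
  writeLines(lines, lay)
  invisible(c(tsv, lay))
}
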