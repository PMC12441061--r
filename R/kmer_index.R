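#' All k-length windows of a string
#' @noRd
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, seq_len(n - k + 1L), k:n)
}

#' Reverse complement
#'
#' @param x Character vector of A/C/G/T sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Build the reference k-mer index of a motif catalog
#'
#' The reference k-mer space is every k-mer occurring in any tandem
#' concatenation of two catalog units, over all ordered pairs (including
#' a unit with itself). Self-concatenation captures the rotational k-mer
#' content of a unit repeated in tandem; cross pairs capture every
#' possible unit-unit junction, since the true unit order of an allele is
#' unknown from short reads. Only the forward (coding) orientation is
#' stored; read matching considers both strands.
#'
#' When flank anchors are supplied, the k-mers of the flank-unit
#' junctions (5' flank followed by any unit; any unit followed by the 3'
#' flank) are included as well, so the insertion-free sequence space of
#' a capture region is covered end to end.
#'
#' @param catalog A [motif_catalog()].
#' @param k K-mer length, `1 <= k <= 60` (k-mers must fit the single-unit
#'   tandem model). Default 25.
#' @param flank_5p,flank_3p Optional flank anchor sequences; `NULL` for
#'   a pure unit-junction index.
#' @return An object of class `kmer_index`: list with elements `k`,
#'   `kmer` (character vector), `label` (parallel, all `"reference"`),
#'   `built_from`.
#' @export
build_reference_kmer_index <- function(catalog, k = 25L,
                                       flank_5p = NULL, flank_3p = NULL) {
  stopifnot(inherits(catalog, "motif_catalog"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 60L) {
    stop("k must be an integer in [1, 60]", call. = FALSE)
  }
  if (nrow(catalog) == 0L) stop("empty motif catalog", call. = FALSE)
  seqs <- catalog$sequence
  pairs <- expand.grid(a = seq_along(seqs), b = seq_along(seqs))
  ctx <- lapply(seq_len(nrow(pairs)), function(i) {
    paste0(seqs[pairs$a[i]], seqs[pairs$b[i]])
  })
  if (!is.null(flank_5p) && nzchar(flank_5p)) {
    f5 <- substr(flank_5p, max(1L, nchar(flank_5p) - k + 2L),
                 nchar(flank_5p))
    ctx <- c(ctx, lapply(seqs, function(s) paste0(f5, s)))
  }
  if (!is.null(flank_3p) && nzchar(flank_3p)) {
    f3 <- substr(flank_3p, 1L, k - 1L)
    ctx <- c(ctx, lapply(seqs, function(s) paste0(s, f3)))
  }
  kmers <- unique(unlist(lapply(ctx, seq_kmers, k = k), use.names = FALSE))
  structure(
    list(k = k, kmer = kmers, label = rep("reference", length(kmers)),
         built_from = attr(catalog, "source") %||% "unknown"),
    class = "kmer_index"
  )
}

#' A candidate insertion within a repeat unit
#'
#' Describes an insertion hypothesis tested by the detector: sequence
#' `inserted_sequence` placed before 0-based `offset` of the unit
#' `motif_id`, in a tandem context of that unit.
#'
#' @param motif_id Catalog unit receiving the insertion.
#' @param offset 0-based position within the unit, `[0, 60]`.
#' @param inserted_sequence Non-empty A/C/G/T string.
#' @return An object of class `variant_candidate`.
#' @export
variant_candidate <- function(motif_id, offset, inserted_sequence) {
  spec <- insertion_spec(0L, offset, inserted_sequence)  # reuse validation
  structure(
    list(motif_id = as.character(motif_id), offset = spec$offset,
         inserted_sequence = spec$inserted_sequence),
    class = "variant_candidate"
  )
}

#' Enumerate variant-diagnostic k-mers for a candidate insertion
#'
#' Builds a mutated context (`left_context` + the candidate's unit with
#' the insertion spliced in + `right_context`; both contexts default to
#' the candidate's own unit, i.e. a homogeneous tandem), takes every
#' k-length window overlapping at least one inserted base, and removes
#' any window already present in the reference index. The surviving
#' k-mers are diagnostic: observing one in a read evidences the
#' insertion, because no insertion-free tandem arrangement of catalog
#' units contains it. At most `k + nchar(inserted_sequence) - 1` k-mers
#' are returned per context.
#'
#' @param catalog A [motif_catalog()].
#' @param candidate A [variant_candidate()].
#' @param k K-mer length; must equal `ref_index$k`.
#' @param ref_index Reference index from [build_reference_kmer_index()],
#'   built from the same catalog and k.
#' @param left_context,right_context Sequences assumed to neighbour the
#'   mutated unit (default: the unit itself). [candidate_insertions()]
#'   unions enumerations over all catalog units and the flank anchors,
#'   since the true neighbours of an insertion are unknown.
#' @return Character vector of diagnostic k-mers (possibly empty, e.g.
#'   when the insertion duplicates its context).
#' @export
enumerate_variant_kmers <- function(catalog, candidate, k, ref_index,
                                    left_context = NULL,
                                    right_context = NULL) {
  stopifnot(inherits(catalog, "motif_catalog"),
            inherits(candidate, "variant_candidate"),
            inherits(ref_index, "kmer_index"))
  k <- as.integer(k)
  if (k != ref_index$k) {
    stop("k (", k, ") disagrees with the reference index (",
         ref_index$k, ")", call. = FALSE)
  }
  unit <- catalog_sequence(catalog, candidate$motif_id)
  left <- left_context %||% unit
  right <- right_context %||% unit
  o <- candidate$offset
  ins <- candidate$inserted_sequence
  L <- nchar(ins)
  nl <- nchar(left)
  ctx <- paste0(left,
                substr(unit, 1L, o), ins, substr(unit, o + 1L, 60L),
                right)
  # inserted bases occupy 1-based positions (nl+o+1) .. (nl+o+L)
  first <- max(1L, nl + o + 2L - k)
  last <- min(nl + o + L, nchar(ctx) - k + 1L)
  if (last < first) return(character())
  win <- unique(substring(ctx, first:last, (first:last) + k - 1L))
  win <- win[nchar(win) == k]
  setdiff(win, ref_index$kmer)
}

#' Expand and merge candidate insertions over a catalog
#'
#' Generates one [variant_candidate()] per (unit, offset 0..59) for each
#' insertion sequence and enumerates its diagnostic k-mers as the union
#' over every neighbour context: each catalog unit on either side, plus
#' the flank anchors when supplied (the true neighbours of an insertion
#' are unknown from short reads, so all hypotheses are indexed; for a
#' real insertion, the `k + len - 1` windows of its actual context are
#' the co-occurring subset). Candidates whose k-mer sets are identical
#' are merged (indistinguishable insertions, e.g. a C placed anywhere
#' within a C homopolymer run) and reported under their leftmost
#' context; k-mers claimed by more than one merged group are then
#' excluded from all groups, so groups are pairwise disjoint and a
#' diagnostic hit identifies its candidate unambiguously. Candidates
#' left without diagnostic k-mers are dropped.
#'
#' @param catalog A [motif_catalog()].
#' @param sequences Character vector of insertion sequences to test
#'   (default the canonical single `"C"`).
#' @param k K-mer length.
#' @param ref_index Optional pre-built reference index (built with the
#'   same flanks).
#' @param flank_5p,flank_3p Optional flank anchors used as additional
#'   neighbour contexts.
#' @return A list of class `candidate_set`: `table` (data frame with
#'   columns `candidate_id`, `motif_id`, `offset`, `inserted_sequence`,
#'   `n_kmers`, `n_core` = `k + len - 1` windows co-occurring in any one
#'   context, `n_merged`) and `kmers` (named list of diagnostic k-mer
#'   character vectors, parallel to `table`).
#' @export
candidate_insertions <- function(catalog, sequences = "C", k = 25L,
                                 ref_index = NULL,
                                 flank_5p = NULL, flank_3p = NULL) {
  if (is.null(ref_index)) {
    ref_index <- build_reference_kmer_index(catalog, k, flank_5p, flank_3p)
  }
  lefts <- c(as.list(catalog$sequence),
             if (!is.null(flank_5p) && nzchar(flank_5p)) {
               list(substr(flank_5p, max(1L, nchar(flank_5p) - 59L),
                           nchar(flank_5p)))
             })
  rights <- c(as.list(catalog$sequence),
              if (!is.null(flank_3p) && nzchar(flank_3p)) {
                list(substr(flank_3p, 1L, 60L))
              })
  cands <- list(); kmers <- list(); n <- 0L
  for (s in sequences) {
    for (m in catalog$motif_id) {
      for (o in 0:59) {
        cand <- variant_candidate(m, o, s)
        dk <- unique(unlist(
          lapply(lefts, function(lc) {
            unlist(lapply(rights, function(rc) {
              enumerate_variant_kmers(catalog, cand, k, ref_index,
                                      left_context = lc,
                                      right_context = rc)
            }), use.names = FALSE)
          }), use.names = FALSE))
        if (length(dk) == 0L) next
        n <- n + 1L
        cands[[n]] <- list(motif_id = m, offset = o, inserted_sequence = s)
        kmers[[n]] <- sort(dk)
      }
    }
  }
  empty <- function() structure(list(
    table = data.frame(candidate_id = character(), motif_id = character(),
                       offset = integer(), inserted_sequence = character(),
                       n_kmers = integer(), n_core = integer(),
                       n_merged = integer(), stringsAsFactors = FALSE),
    kmers = list(), k = ref_index$k), class = "candidate_set")
  if (n == 0L) return(empty())
  # candidates sharing a k-mer describe the same physical variant under
  # different labels (a C inserted in a homopolymer run, or at a unit
  # boundary where it can be written as the end of one unit or the start
  # of the next): merge them into one group by connected components,
  # represented by the leftmost member. A k-mer shared across groups
  # with *different* inserted sequences identifies neither and is
  # dropped from all.
  ins_of <- vapply(cands, `[[`, "", "inserted_sequence")
  owner <- split(rep(seq_along(kmers), lengths(kmers)),
                 unlist(kmers, use.names = FALSE))
  parent <- seq_along(kmers)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  shared <- owner[lengths(owner) > 1L]
  mixed <- vapply(shared, function(gs) length(unique(ins_of[gs])) > 1L,
                  TRUE)
  drop_k <- names(shared)[mixed]
  for (gs in shared[!mixed]) {
    roots <- unique(vapply(gs, find, 0L))
    for (r in roots[-1L]) parent[r] <- roots[1L]
  }
  root <- vapply(seq_along(kmers), find, 0L)
  comp <- split(seq_along(kmers), root)
  comp <- comp[order(vapply(comp, min, 0L))]
  cands <- lapply(comp, function(m) cands[[min(m)]])
  n_merged <- vapply(comp, length, 0L)
  kmers <- lapply(comp, function(m) {
    setdiff(sort(unique(unlist(kmers[m], use.names = FALSE))), drop_k)
  })
  nz <- lengths(kmers) > 0L
  cands <- cands[nz]; kmers <- kmers[nz]; n_merged <- n_merged[nz]
  if (length(cands) == 0L) return(empty())
  tab <- data.frame(
    motif_id = vapply(cands, `[[`, "", "motif_id"),
    offset = vapply(cands, function(x) as.integer(x$offset), 0L),
    inserted_sequence = vapply(cands, `[[`, "", "inserted_sequence"),
    n_kmers = lengths(kmers),
    n_merged = n_merged,
    stringsAsFactors = FALSE
  )
  tab$n_core <- pmin(ref_index$k + nchar(tab$inserted_sequence) - 1L,
                     tab$n_kmers)
  tab$candidate_id <- sprintf("%s:%d:%s", tab$motif_id, tab$offset,
                              tab$inserted_sequence)
  tab <- tab[, c("candidate_id", "motif_id", "offset",
                 "inserted_sequence", "n_kmers", "n_core", "n_merged")]
  structure(list(table = tab,
                 kmers = stats::setNames(kmers, tab$candidate_id),
                 k = ref_index$k),
            class = "candidate_set")
}

#' Combine reference and variant k-mers into one index
#'
#' K-mers claimed by both sides (possible only across candidate sets,
#' since enumeration already subtracts reference k-mers) are excluded
#' from the variant side.
#' @noRd
combine_index <- function(ref_index, candidates) {
  var_kmer <- unlist(candidates$kmers, use.names = FALSE)
  var_label <- rep(paste0("variant:", names(candidates$kmers)),
                   lengths(candidates$kmers))
  clash <- var_kmer %in% ref_index$kmer
  structure(
    list(k = ref_index$k,
         kmer = c(ref_index$kmer, var_kmer[!clash]),
         label = c(ref_index$label, var_label[!clash]),
         built_from = ref_index$built_from),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer index: k=", x$k, ", ", length(x$kmer), " k-mers (",
      sum(x$label == "reference"), " reference), built from ",
      x$built_from, "\n", sep = "")
  invisible(x)
}
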