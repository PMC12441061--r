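#' Detector configuration
#'
#' Tunables of the mapping-free insertion caller. The confidence rule is
#' the published two-tier classification of the upstream k-mer caller: a
#' call is High confidence iff its depth score is at least 0.00515 AND
#' its estimated alternate depth is strictly greater than 20; everything
#' else is Low confidence. The artifact rule flags Low-confidence calls
#' whose insertion is longer than `artifact_max_insertion_len` (multi-base
#' insertions such as "GGCT" with weak support behave as pipeline
#' artifacts in practice).
#'
#' @param k K-mer length (default 25; must stay below the 60-nt unit so
#'   k-mers are informative within one repeat while fitting short reads).
#' @param min_shared_kmers_to_screen Minimum k-mers (either strand) a
#'   read must share with the index to be retained (default 3).
#' @param high_conf_depth_score Depth-score floor for High confidence
#'   (inclusive; default 0.00515).
#' @param high_conf_alt_depth Alternate-depth threshold for High
#'   confidence (strict; default 20).
#' @param artifact_max_insertion_len Insertions longer than this are
#'   artifact candidates (default 1).
#' @param candidate_insertions Insertion sequences to test at every unit
#'   offset (default `"C"`; add e.g. `"GGCT"` to also track the known
#'   artifact motif).
#' @param flank_5p,flank_3p Flank anchor sequences of the locus (known
#'   from the assay design), used as neighbour contexts for reference
#'   and variant k-mer enumeration; `NULL` to index units only.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(k = 25L,
                            min_shared_kmers_to_screen = 3L,
                            high_conf_depth_score = 0.00515,
                            high_conf_alt_depth = 20,
                            artifact_max_insertion_len = 1L,
                            candidate_insertions = "C",
                            flank_5p = default_flanks()$flank_5p,
                            flank_3p = default_flanks()$flank_3p) {
  if (high_conf_depth_score <= 0 || high_conf_alt_depth <= 0) {
    stop("confidence thresholds must be positive", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 60L) {
    stop("k must be in [1, 60]", call. = FALSE)
  }
  structure(
    list(k = k,
         min_shared_kmers_to_screen = as.integer(min_shared_kmers_to_screen),
         high_conf_depth_score = high_conf_depth_score,
         high_conf_alt_depth = high_conf_alt_depth,
         artifact_max_insertion_len = as.integer(artifact_max_insertion_len),
         candidate_insertions = toupper(candidate_insertions),
         flank_5p = flank_5p, flank_3p = flank_3p),
    class = "detector_config"
  )
}

# count occurrences of index k-mers in reads, both orientations;
# collapse = 1 -> per k-mer totals, collapse = 2 -> per read totals.
# Reads and their reverse complements are concatenated with N separators
# into one subject so the Aho-Corasick scan runs once (windows spanning
# a separator contain N and can never match an A/C/G/T k-mer).
kmer_hits <- function(kmers, reads, collapse) {
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(reads)))
  big <- Biostrings::DNAString(paste(c(reads, rc), collapse = "N"))
  pd <- Biostrings::PDict(kmers)
  if (collapse == 1L) {
    return(Biostrings::countPDict(pd, big))
  }
  mi <- Biostrings::matchPDict(pd, big)
  st <- unlist(Biostrings::startIndex(mi), use.names = FALSE)
  n <- length(reads)
  if (length(st) == 0L) return(integer(n))
  seg_len <- rep(nchar(reads), 2L)
  offs <- cumsum(c(0L, seg_len + 1L))
  ri <- findInterval(st, offs)
  ri[ri > n] <- ri[ri > n] - n
  tabulate(ri, nbins = n)
}

#' Screen reads by shared k-mers
#'
#' Retains exactly the reads sharing at least
#' `config$min_shared_kmers_to_screen` k-mers with the index, in either
#' orientation, preserving input order. This is the read-recruitment
#' step: panel data contain mostly off-target reads and only recruited
#' reads enter the counting stage.
#'
#' @param reads Character vector of read sequences.
#' @param index A `kmer_index` (reference, or reference plus variant).
#' @param config A [detector_config()]; `config$k` must equal `index$k`.
#' @return The retained subset of `reads`.
#' @export
screen_reads <- function(reads, index, config = detector_config()) {
  stopifnot(inherits(index, "kmer_index"))
  if (length(index$kmer) == 0L) {
    stop("cannot screen against an empty k-mer index", call. = FALSE)
  }
  if (config$k != index$k) {
    stop("config k (", config$k, ") != index k (", index$k, ")",
         call. = FALSE)
  }
  if (length(reads) == 0L) return(character())
  keep <- nchar(reads) >= index$k
  shared <- integer(length(reads))
  if (any(keep)) {
    shared[keep] <- as.integer(kmer_hits(index$kmer, reads[keep],
                                         collapse = 2L))
  }
  reads[shared >= config$min_shared_kmers_to_screen]
}

#' Count reference and variant-diagnostic k-mer depths
#'
#' Counts, over both read orientations, the occurrences of every indexed
#' k-mer in the screened reads, then aggregates: the alternate depth of
#' a candidate is the mean over the `n_core = k + len - 1` largest counts
#' in its diagnostic k-mer group (a true insertion produces exactly that
#' many co-occurring windows; the group's remaining k-mers belong to
#' neighbour hypotheses that did not materialise); the total depth is
#' the mean count over reference k-mers.
#'
#' @param reads Screened read sequences.
#' @param ref_index Reference `kmer_index`.
#' @param candidates A `candidate_set` from [candidate_insertions()].
#' @return List with `kmer_counts` (named integer vector),
#'   `alt_depth` (named by candidate_id), `supporting_kmers` (number of
#'   diagnostic k-mers with nonzero count, per candidate) and
#'   `total_depth` (scalar).
#' @export
count_kmer_depths <- function(reads, ref_index, candidates) {
  stopifnot(inherits(ref_index, "kmer_index"),
            inherits(candidates, "candidate_set"))
  if (length(candidates$kmers) > 0L && candidates$k != ref_index$k) {
    stop("candidate set k disagrees with reference index", call. = FALSE)
  }
  all_kmers <- unique(c(ref_index$kmer,
                        unlist(candidates$kmers, use.names = FALSE)))
  counts <- stats::setNames(integer(length(all_kmers)), all_kmers)
  reads <- reads[nchar(reads) >= ref_index$k]
  if (length(reads) > 0L) {
    counts[] <- as.integer(kmer_hits(all_kmers, reads, collapse = 1L))
  }
  n_core <- candidates$table$n_core
  alt <- vapply(seq_along(candidates$kmers), function(i) {
    cnt <- counts[candidates$kmers[[i]]]
    mean(sort(cnt, decreasing = TRUE)[seq_len(n_core[i])])
  }, 0)
  names(alt) <- names(candidates$kmers)
  supp <- vapply(candidates$kmers,
                 function(ks) sum(counts[ks] > 0L), 0L)
  list(kmer_counts = counts,
       alt_depth = alt,
       supporting_kmers = supp,
       total_depth = mean(counts[ref_index$kmer]))
}

#' Depth score of a call
#'
#' The fraction of informative k-mer depth supporting the alternate
#' allele: `alt_depth / (alt_depth + total_depth)`, defined as 0 when
#' both depths are 0. The published threshold (0.00515) is a floor on
#' this scalar; the upstream tool does not publish its exact formula, so
#' this quantity is kept isolated behind this function.
#'
#' @param alt_depth,total_depth Non-negative depths (vectorised).
#' @return Numeric depth scores in `[0, 1]`.
#' @export
depth_score <- function(alt_depth, total_depth) {
  if (any(alt_depth < 0) || any(total_depth < 0)) {
    stop("depths must be non-negative", call. = FALSE)
  }
  den <- alt_depth + total_depth
  ifelse(den > 0, alt_depth / den, 0)
}

#' Classify call confidence
#'
#' High confidence iff `depth_score >= high_conf_depth_score` (inclusive,
#' "at least") AND `alt_depth > high_conf_alt_depth` (strict, "greater
#' than"); otherwise Low.
#'
#' @param depth_score,alt_depth Numeric vectors.
#' @param config A [detector_config()].
#' @return Character vector, `"High"` or `"Low"`.
#' @export
classify_confidence <- function(depth_score, alt_depth,
                                config = detector_config()) {
  stopifnot(is.finite(depth_score), is.finite(alt_depth))
  ifelse(depth_score >= config$high_conf_depth_score &
           alt_depth > config$high_conf_alt_depth,
         "High", "Low")
}

#' Flag probable artifact calls
#'
#' Sets `artifact_flag = TRUE` for calls that are both Low confidence and
#' carry an insertion longer than `config$artifact_max_insertion_len`.
#' Flagged calls are retained in the output, only marked. A
#' High-confidence multi-base call is *not* flagged: the rule is a
#' conjunction.
#'
#' @param calls A call data frame (from [detect()]), with columns
#'   `inserted_sequence` and `confidence`.
#' @param config A [detector_config()].
#' @return `calls` with `artifact_flag` set.
#' @export
filter_artifacts <- function(calls, config = detector_config()) {
  calls$artifact_flag <-
    nchar(calls$inserted_sequence) > config$artifact_max_insertion_len &
    calls$confidence == "Low"
  calls
}

#' Detect VNTR insertions in short reads (mapping-free)
#'
#' End-to-end caller: build the reference k-mer index, enumerate
#' diagnostic k-mers for every configured candidate insertion, screen the
#' reads, count k-mer depths, and emit one call per candidate with at
#' least one observed diagnostic k-mer, with depth score, High/Low
#' confidence and artifact flag.
#'
#' @param reads Character vector of read sequences (see [read_reads()]
#'   for file input).
#' @param catalog A [motif_catalog()].
#' @param config A [detector_config()].
#' @param ref_index,candidates Optional pre-built reference index and
#'   `candidate_set` (they only depend on catalog and config, so batch
#'   callers reuse them across samples).
#' @return An object of class `vntr_calls`: list with `calls` (data
#'   frame: `inserted_sequence`, `context` = "motif:offset" of the
#'   left-normalised candidate, `alt_depth`, `total_depth`,
#'   `depth_score`, `confidence`, `artifact_flag`, `supporting_kmers`)
#'   and `report` (input/screened read counts, median and mean reference
#'   k-mer count, k, candidate count).
#' @export
detect <- function(reads, catalog, config = detector_config(),
                   ref_index = NULL, candidates = NULL) {
  stopifnot(inherits(catalog, "motif_catalog"),
            inherits(config, "detector_config"))
  if (is.null(ref_index)) {
    ref_index <- build_reference_kmer_index(catalog, config$k,
                                            config$flank_5p, config$flank_3p)
  }
  cands <- candidates %||%
    candidate_insertions(catalog, config$candidate_insertions,
                         config$k, ref_index,
                         flank_5p = config$flank_5p,
                         flank_3p = config$flank_3p)
  full_index <- combine_index(ref_index, cands)
  screened <- screen_reads(reads, full_index, config)
  depths <- count_kmer_depths(screened, ref_index, cands)

  hit <- depths$supporting_kmers > 0L
  tab <- cands$table[hit, , drop = FALSE]
  calls <- data.frame(
    inserted_sequence = tab$inserted_sequence,
    context = sprintf("%s:%d", tab$motif_id, tab$offset),
    alt_depth = unname(depths$alt_depth[hit]),
    total_depth = rep(depths$total_depth, sum(hit)),
    depth_score = depth_score(unname(depths$alt_depth[hit]),
                              rep(depths$total_depth, sum(hit))),
    supporting_kmers = unname(depths$supporting_kmers[hit]),
    stringsAsFactors = FALSE
  )
  calls$confidence <- classify_confidence(calls$depth_score,
                                          calls$alt_depth, config)
  calls <- filter_artifacts(calls, config)
  calls <- calls[order(-calls$depth_score), , drop = FALSE]
  rownames(calls) <- NULL
  structure(
    list(calls = calls,
         report = list(
           n_reads_input = length(reads),
           n_reads_screened = length(screened),
           median_ref_kmer_count = stats::median(
             depths$kmer_counts[ref_index$kmer]),
           mean_ref_kmer_depth = depths$total_depth,
           k = config$k,
           n_reference_kmers = length(ref_index$kmer),
           n_candidates = nrow(cands$table))),
    class = "vntr_calls"
  )
}

#' @export
#' @param n Maximum number of call rows to display.
print.vntr_calls <- function(x, n = 5L, ...) {
  r <- x$report
  cat("VNTR insertion screen: ", r$n_reads_screened, "/", r$n_reads_input,
      " reads recruited, k=", r$k, ", ", r$n_candidates,
      " candidate insertions\n", sep = "")
  calls <- x$calls
  if (nrow(calls) == 0L) {
    cat("No insertion calls.\n")
    return(invisible(x))
  }
  n_high <- sum(calls$confidence == "High")
  n_art <- sum(calls$artifact_flag)
  cat(nrow(calls), " call(s): ", n_high, " High confidence, ",
      nrow(calls) - n_high, " Low (", n_art, " flagged as artifacts)\n",
      sep = "")
  print(utils::head(calls, n), ...)
  if (nrow(calls) > n) {
    cat("... and", nrow(calls) - n, "further low-support rows\n")
  }
  invisible(x)
}

#' Write calls as a TSV table
#'
#' @param x A `vntr_calls` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(x, path) {
  stopifnot(inherits(x, "vntr_calls"))
  utils::write.table(x$calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
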