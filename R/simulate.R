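#' Default amplicon flank anchors
#'
#' Fixed synthetic 150-nt non-repetitive, AT-leaning anchor sequences
#' used as the 5' and 3' flanks of simulated alleles. They share no
#' 25-mer with the packaged catalog's reference k-mer space and stand in
#' for the primer-anchored unique sequence flanking the real locus.
#'
#' @return Named list with elements `flank_5p` and `flank_3p`.
#' @export
default_flanks <- function() {
  list(
    flank_5p = paste0(
      "CAACAAAATTTAAACCTAAAATGTGTCGCATGACACATTATTCTTAAATTCTCTTAATTA",
      "TCGTAGCATTTCATATAAAATCACAATTTATTAAACAAAATTTTAGGACATAAAGTGCAT",
      "GTACATATAATGAGAATACGCAGACCGAAT"),
    flank_3p = paste0(
      "TTTCATGTGTTACATACTAAAACAAATAACCGGTTGGAGTCATACGTAATAAAAAAAGTA",
      "TTTCCGAGTAAATTTTAGGAAAATGAATATGTCGTTTTATTCGGTTAGTTATTTCGATGT",
      "ACTACCTATCCAATTAAAACGAGAAAGGGC")
  )
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The two named
#' coverage presets mirror the median VNTR coverages of the two targeted
#' panels studied with this locus: `"broad_panel"` (344x, a ~180-gene
#' kidney panel) and `"adtkd_panel"` (2424x, a disease-specific panel).
#'
#' @param seed Integer seed; every simulator output is a pure function of
#'   `(seed, inputs)`.
#' @param repeat_count_range Integer pair; allele repeat counts are drawn
#'   uniformly from this range. Default `c(20, 125)`, the documented
#'   copy-number range of the locus.
#' @param read_length Short-read length (default 150).
#' @param paired Paired-end reads? Default `TRUE` (fragment length
#'   Normal(350, 50), truncated below at `read_length`).
#' @param mean_coverage Target mean depth over the VNTR region, summed
#'   over both alleles.
#' @param per_base_error_rate Substitution error rate of short reads.
#' @param gc_bias_strength Scalar `>= 0`; fragments are retained with
#'   probability `min(1, exp(-gc_bias_strength * (gc - 0.5)))`, so GC-rich
#'   fragments drop out when positive and coverage is uniform at 0.
#' @param long_read_error_rate Substitution error rate of long amplicon
#'   reads.
#' @param long_read_count Number of long amplicon reads.
#' @param flank_5p,flank_3p Allele flank anchors (defaults from
#'   [default_flanks()]).
#' @return An object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(seed = 1L,
                              repeat_count_range = c(20L, 125L),
                              read_length = 150L,
                              paired = TRUE,
                              mean_coverage = 344,
                              per_base_error_rate = 0.001,
                              gc_bias_strength = 0,
                              long_read_error_rate = 0.002,
                              long_read_count = 60L,
                              flank_5p = default_flanks()$flank_5p,
                              flank_3p = default_flanks()$flank_3p) {
  repeat_count_range <- as.integer(repeat_count_range)
  stopifnot(length(repeat_count_range) == 2L)
  if (repeat_count_range[1L] > repeat_count_range[2L] ||
      repeat_count_range[1L] <= 1L || repeat_count_range[2L] >= 1000L) {
    stop("repeat_count_range must satisfy 1 < low <= high < 1000",
         call. = FALSE)
  }
  if (!is.finite(mean_coverage) || mean_coverage <= 0) {
    stop("mean_coverage must be positive", call. = FALSE)
  }
  if (per_base_error_rate < 0 || per_base_error_rate >= 1 ||
      long_read_error_rate < 0 || long_read_error_rate >= 1) {
    stop("error rates must lie in [0, 1)", call. = FALSE)
  }
  if (gc_bias_strength < 0) stop("gc_bias_strength must be >= 0",
                                 call. = FALSE)
  if (read_length <= 0L) stop("read_length must be positive", call. = FALSE)
  structure(
    list(seed = as.integer(seed),
         repeat_count_range = repeat_count_range,
         read_length = as.integer(read_length),
         paired = isTRUE(paired),
         mean_coverage = mean_coverage,
         per_base_error_rate = per_base_error_rate,
         gc_bias_strength = gc_bias_strength,
         long_read_error_rate = long_read_error_rate,
         long_read_count = as.integer(long_read_count),
         flank_5p = toupper(flank_5p),
         flank_3p = toupper(flank_3p)),
    class = "simulation_config"
  )
}

#' Named coverage presets
#'
#' @param preset `"broad_panel"` (344x) or `"adtkd_panel"` (2424x).
#' @param ... Further arguments to [simulation_config()].
#' @return A [simulation_config()] with `mean_coverage` set.
#' @export
coverage_preset <- function(preset = c("broad_panel", "adtkd_panel"), ...) {
  preset <- match.arg(preset)
  cov <- c(broad_panel = 344, adtkd_panel = 2424)[[preset]]
  simulation_config(mean_coverage = cov, ...)
}

# deterministic sub-seed per (seed, operation); stays below 2^31 - 1
derive_seed <- function(seed, op) {
  s <- (as.double(seed) %% 2147483647) * 69621 + as.double(op)
  s <- s %% 2147483647
  as.integer(if (s == 0) 1 else s)
}

#' Simulate a diploid VNTR genotype
#'
#' Repeat counts are drawn uniformly and independently per allele from
#' `config$repeat_count_range`; unit identities are drawn uniformly from
#' the catalog. A carrier is heterozygous (autosomal-dominant model):
#' exactly one allele, chosen at random, receives the insertion.
#'
#' @param config A [simulation_config()].
#' @param catalog A [motif_catalog()].
#' @param carrier Does the genotype carry the insertion?
#' @param insertion An [insertion_spec()] for carriers; if `NULL`, a
#'   single-C insertion at a uniformly drawn unit and offset is used.
#'   Its `repeat_index` must fall inside the drawn repeat count.
#' @return An object of class `diploid_genotype`: list with `allele_a`,
#'   `allele_b` ([vntr_allele()]s) and logical `carrier`.
#' @export
simulate_genotype <- function(config, catalog, carrier = FALSE,
                              insertion = NULL) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(catalog, "motif_catalog"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    rng <- config$repeat_count_range
    counts <- sample(rng[1L]:rng[2L], 2L, replace = TRUE)
    units <- lapply(counts, function(n) {
      sample(catalog$motif_id, n, replace = TRUE)
    })
    ins_allele <- if (carrier) sample(1:2, 1L) else 0L
    alleles <- lapply(1:2, function(i) {
      ins <- NULL
      if (carrier && i == ins_allele) {
        ins <- insertion
        if (is.null(ins)) {
          ins <- insertion_spec(sample.int(counts[i], 1L) - 1L,
                                sample(0:59, 1L), "C")
        }
        if (ins$repeat_index >= counts[i]) {
          stop("insertion repeat_index (", ins$repeat_index,
               ") >= drawn repeat count (", counts[i], ")", call. = FALSE)
        }
      }
      vntr_allele(units[[i]], ins,
                  flank_5p = config$flank_5p, flank_3p = config$flank_3p)
    })
    structure(list(allele_a = alleles[[1L]], allele_b = alleles[[2L]],
                   carrier = isTRUE(carrier)),
              class = "diploid_genotype")
  })
}

# substitute random bases at `rate`, vectorised over a read set
inject_substitutions <- function(reads, rate, bases = c("A", "C", "G", "T")) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  len <- nchar(reads)
  total <- sum(len)
  n_err <- stats::rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  idx <- sample.int(total, n_err)
  ends <- cumsum(len)
  read_i <- findInterval(idx - 1L, ends) + 1L
  pos <- idx - c(0L, ends)[read_i]
  for (e in seq_len(n_err)) {
    i <- read_i[e]; p <- pos[e]
    old <- substr(reads[i], p, p)
    substr(reads[i], p, p) <- sample(setdiff(bases, old), 1L)
  }
  reads
}

#' Simulate short panel reads over a diploid genotype
#'
#' Fragments are drawn uniformly over each rendered allele, in equal
#' expectation from the two alleles; a fragment is retained with
#' probability `min(1, exp(-gc_bias_strength * (gc - 0.5)))`, emulating
#' GC dropout in the GC-rich repeat; substitution errors are applied at
#' `per_base_error_rate`; qualities are constant Q30. The fragment count
#' is calibrated so the interior of the region reaches
#' `config$mean_coverage` in expectation when `gc_bias_strength = 0`.
#'
#' @param genotype A `diploid_genotype` from [simulate_genotype()].
#' @param catalog A [motif_catalog()].
#' @param config A [simulation_config()].
#' @return An object of class `short_read_set`: list with `reads`
#'   (character), `names`, `qualities`, and a `meta` data frame recording
#'   each read's source allele and interval (simulator bookkeeping used
#'   for coverage accounting, never given to the detector).
#' @export
simulate_short_reads <- function(genotype, catalog, config) {
  stopifnot(inherits(genotype, "diploid_genotype"),
            inherits(config, "simulation_config"))
  rl <- config$read_length
  withr::with_seed(derive_seed(config$seed, 2L), {
    out_reads <- character(); out_meta <- list()
    for (ai in 1:2) {
      allele <- genotype[[c("allele_a", "allele_b")[ai]]]
      aseq <- render_allele(allele, catalog)
      L <- nchar(aseq)
      if (L <= rl) stop("rendered allele shorter than read_length",
                        call. = FALSE)
      frag_bases <- if (config$paired) 2L * rl else rl
      # interior depth is n_frag * frag_bases / n_start_positions, so
      # calibrate against the expected start-position count
      exp_flen <- if (config$paired) min(350, L) else rl
      n_frag <- round((config$mean_coverage / 2) *
                        (L - exp_flen + 1L) / frag_bases)
      if (n_frag == 0L) next
      flen <- if (config$paired) {
        pmax(rl, pmin(L, round(stats::rnorm(n_frag, 350, 50))))
      } else rep(rl, n_frag)
      start <- floor(stats::runif(n_frag, 1, L - flen + 2))
      frag <- substring(aseq, start, start + flen - 1L)
      if (config$gc_bias_strength > 0) {
        gc <- gc_fraction(frag)
        keep_p <- pmin(1, exp(-config$gc_bias_strength * (gc - 0.5)))
        keep <- stats::runif(n_frag) < keep_p
        frag <- frag[keep]; start <- start[keep]; flen <- flen[keep]
      }
      if (length(frag) == 0L) next
      if (config$paired) {
        r1 <- substr(frag, 1L, rl)
        r2 <- revcomp(substring(frag, flen - rl + 1L, flen))
        out_reads <- c(out_reads, r1, r2)
        out_meta[[ai]] <- data.frame(
          allele = ai,
          start = c(start, start + flen - rl),
          end = c(start + rl - 1L, start + flen - 1L))
      } else {
        out_reads <- c(out_reads, frag)
        out_meta[[ai]] <- data.frame(allele = ai, start = start,
                                     end = start + rl - 1L)
      }
    }
    reads <- inject_substitutions(out_reads, config$per_base_error_rate)
    meta <- do.call(rbind, out_meta)
    structure(
      list(reads = reads,
           names = sprintf("sr%06d", seq_along(reads)),
           qualities = rep(strrep("?", rl), length(reads)),  # Q30
           meta = meta,
           read_length = rl, paired = config$paired),
      class = "short_read_set"
    )
  })
}

#' Simulate long amplicon reads spanning the whole VNTR
#'
#' Each read covers one allele flank-to-flank (primer-anchored amplicon
#' model), with the allele chosen with equal probability, a uniformly
#' random strand, and substitution errors at `long_read_error_rate`
#' (indel errors are out of the model, so read lengths are exact).
#'
#' @inheritParams simulate_short_reads
#' @return An object of class `long_read_set`: list with `reads`,
#'   `names`, and truth vectors `allele` (1/2) and `strand` (`"+"`/`"-"`).
#' @export
simulate_long_reads <- function(genotype, catalog, config) {
  stopifnot(inherits(genotype, "diploid_genotype"),
            inherits(config, "simulation_config"))
  if (!nzchar(config$flank_5p) || !nzchar(config$flank_3p)) {
    stop("long-read simulation needs non-empty flank anchors", call. = FALSE)
  }
  withr::with_seed(derive_seed(config$seed, 3L), {
    n <- config$long_read_count
    aseq <- c(render_allele(genotype$allele_a, catalog),
              render_allele(genotype$allele_b, catalog))
    allele <- sample(1:2, n, replace = TRUE)
    reads <- inject_substitutions(aseq[allele], config$long_read_error_rate)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    reads[strand == "-"] <- revcomp(reads[strand == "-"])
    structure(
      list(reads = reads, names = sprintf("lr%04d", seq_len(n)),
           allele = allele, strand = strand),
      class = "long_read_set"
    )
  })
}

#' Realized coverage over the VNTR region of a simulation
#'
#' Uses the simulator's own fragment bookkeeping (not alignment) to
#' compute the per-position read depth over the VNTR portion of each
#' allele, pooled across alleles.
#'
#' @param sim A `short_read_set`.
#' @param genotype The `diploid_genotype` it was simulated from.
#' @param catalog The [motif_catalog()].
#' @return List with `median` and `mean` pooled VNTR depth.
#' @export
realized_vntr_coverage <- function(sim, genotype, catalog) {
  stopifnot(inherits(sim, "short_read_set"))
  prof <- list()
  for (ai in 1:2) {
    allele <- genotype[[c("allele_a", "allele_b")[ai]]]
    L <- nchar(render_allele(allele, catalog))
    v0 <- nchar(allele$flank_5p) + 1L
    v1 <- L - nchar(allele$flank_3p)
    m <- sim$meta[sim$meta$allele == ai, , drop = FALSE]
    cov <- IRanges::coverage(IRanges::IRanges(m$start, m$end), width = L)
    prof[[ai]] <- as.integer(cov)[v0:v1]
  }
  n <- min(lengths(prof))
  pooled <- prof[[1L]][seq_len(n)] + prof[[2L]][seq_len(n)]
  list(median = stats::median(pooled), mean = mean(pooled))
}

#' Genotype truth sidecar
#'
#' Serialisable ground truth of a simulated genotype, for harness
#' scoring: repeat counts, VNTR lengths, and the insertion (if any) both
#' in its original coordinates and left-normalised against the rendered
#' insertion-free VNTR.
#'
#' @param genotype A `diploid_genotype`.
#' @param catalog A [motif_catalog()].
#' @return A list; write with [write_truth()].
#' @export
genotype_truth <- function(genotype, catalog) {
  per_allele <- lapply(c("allele_a", "allele_b"), function(nm) {
    al <- genotype[[nm]]
    ref_vntr <- render_vntr(
      vntr_allele(al$repeat_units, NULL, al$flank_5p, al$flank_3p), catalog)
    ins <- NULL
    if (!is.null(al$insertion)) {
      g <- 60L * al$insertion$repeat_index + al$insertion$offset
      nrm <- normalize_insertion_point(ref_vntr, g,
                                       al$insertion$inserted_sequence)
      ins <- list(repeat_index = al$insertion$repeat_index,
                  offset = al$insertion$offset,
                  inserted_sequence = al$insertion$inserted_sequence,
                  normalized_pos = nrm$pos,
                  normalized_sequence = nrm$ins)
    }
    list(repeat_count = length(al$repeat_units),
         vntr_length = nchar(ref_vntr) +
           if (is.null(al$insertion)) 0L else
             nchar(al$insertion$inserted_sequence),
         insertion = ins)
  })
  list(carrier = genotype$carrier,
       allele_a = per_allele[[1L]], allele_b = per_allele[[2L]])
}

#' @rdname genotype_truth
#' @param truth A truth list from [genotype_truth()].
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' @rdname genotype_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
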