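# Fixtures are generated in code. Sequences here are drawn with local
# seeds so helpers are deterministic and never disturb a test's RNG.

random_dna <- function(n, gc = 0.5, seed = NULL) {
  draw <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# a random catalog of GC-rich 60-nt units
random_catalog <- function(n_motifs = 3, gc = 0.7, seed = 1) {
  withr::with_seed(seed, {
    motif_catalog(sprintf("m%d", seq_len(n_motifs)),
                  replicate(n_motifs, random_dna(60, gc)),
                  source = "test")
  })
}

# brute-force k-mer enumeration, independent of the package internals
brute_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character())
  unique(vapply(seq_len(n - k + 1L),
                function(i) substr(s, i, i + k - 1L), ""))
}

# small, fast simulation settings (repeat counts far below the clinical
# range, for unit tests that only need structure, not realism)
quick_config <- function(seed = 1, mean_coverage = 120, ...) {
  simulation_config(seed = seed, repeat_count_range = c(20, 30),
                    mean_coverage = mean_coverage, ...)
}

# brute-force product-limit estimator with events-before-censorings at
# ties; returns survival at each distinct event time
brute_km <- function(time, event) {
  tt <- sort(unique(time[event]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])  # censored at t still at risk at t
    d <- sum(time == tt[i] & event)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = tt, surv = out)
}
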