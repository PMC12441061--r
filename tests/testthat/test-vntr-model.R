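test_that("catalog construction validates unit length, alphabet, unique ids", {
  expect_s3_class(motif_catalog("u1", strrep("ACGGGC", 10)), "motif_catalog")
  expect_error(motif_catalog("u1", strrep("AC", 10)), "60 nt")
  expect_error(motif_catalog("u1", paste0(strrep("AC", 29), "NN")), "A, C, G, T")
  expect_error(motif_catalog(c("u1", "u1"), rep(strrep("ACGGGC", 10), 2)),
               "unique")
  cat <- motif_catalog("u1", strrep("GCGCAT", 10))
  expect_equal(cat$gc_fraction, 4 / 6)
})

test_that("catalog TSV round-trips and skips comments", {
  cat <- random_catalog(3, seed = 11)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_catalog(cat, path)
  back <- read_motif_catalog(path)
  expect_equal(back$motif_id, cat$motif_id)
  expect_equal(back$sequence, cat$sequence)
  writeLines(c("# a comment", readLines(path)), path)
  expect_equal(read_motif_catalog(path)$sequence, cat$sequence)
})

test_that("render_allele splices insertions and obeys the length formula", {
  cat <- random_catalog(2, seed = 3)
  # identity: one unit, no insertion, no flanks
  al1 <- vntr_allele("m1")
  expect_identical(render_allele(al1, cat), cat$sequence[1])

  # 20 identical units + single C: 20 * 60 + 1
  al2 <- vntr_allele(rep("m1", 20), insertion_spec(0, 5, "C"))
  s2 <- render_allele(al2, cat)
  expect_equal(nchar(s2), 1201L)
  expect_identical(substr(s2, 6, 6), "C")
  expect_identical(substr(s2, 7, 7), substr(cat$sequence[1], 6, 6))

  # 125 units, no insertion, with flanks
  al3 <- vntr_allele(rep(c("m1", "m2"), length.out = 125),
                     flank_5p = "ACGTACGTACGT", flank_3p = "TTTT")
  expect_equal(nchar(render_allele(al3, cat)), 125L * 60L + 12L + 4L)

  # fuzz: length formula for random alleles
  withr::with_seed(42, {
    for (i in 1:25) {
      n <- sample(2:40, 1)
      ins <- if (runif(1) < 0.5) {
        insertion_spec(sample(0:(n - 1), 1), sample(0:60, 1),
                       random_dna(sample(1:6, 1)))
      }
      fl5 <- random_dna(sample(0:30, 1)); fl3 <- random_dna(sample(0:30, 1))
      al <- vntr_allele(sample(cat$motif_id, n, replace = TRUE), ins,
                        fl5, fl3)
      expect_equal(nchar(render_allele(al, cat)),
                   60L * n + nchar(fl5) + nchar(fl3) +
                     if (is.null(ins)) 0L else nchar(ins$inserted_sequence))
    }
  })
})

test_that("render_allele rejects unknown units and out-of-bounds insertions", {
  cat <- random_catalog(1, seed = 5)
  expect_error(render_allele(vntr_allele("nope"), cat), "unknown motif_id")
  expect_error(vntr_allele(rep("m1", 3), insertion_spec(3, 0, "C")),
               "outside")
  expect_error(insertion_spec(0, 61, "C"), "offset")
  expect_error(insertion_spec(0, 5, ""), "inserted_sequence")
})

test_that("reference index equals brute-force k-mers of pairwise tandems", {
  cat1 <- random_catalog(1, seed = 7)
  k <- 25
  idx <- build_reference_kmer_index(cat1, k)
  oracle <- brute_kmers(paste0(cat1$sequence, cat1$sequence), k)
  expect_setequal(idx$kmer, oracle)
  # all rotations distinct for this unit: exactly 60 k-mers
  expect_length(idx$kmer, 60L)

  # k = 60: the 60 rotations of the unit
  idx60 <- build_reference_kmer_index(cat1, 60)
  expect_length(idx60$kmer, 60L)
  expect_true(all(nchar(idx60$kmer) == 60L))

  # multi-unit catalog: union over all ordered pair concatenations
  cat3 <- random_catalog(3, seed = 8)
  idx3 <- build_reference_kmer_index(cat3, k)
  oracle3 <- unique(unlist(lapply(cat3$sequence, function(a) {
    lapply(cat3$sequence, function(b) brute_kmers(paste0(a, b), k))
  })))
  expect_setequal(idx3$kmer, oracle3)

  expect_error(build_reference_kmer_index(cat1, 61), "\\[1, 60\\]")
  expect_error(
    build_reference_kmer_index(cat1[0, , drop = FALSE], 25),
    "empty")
})

test_that("flank-aware index covers flank-unit junction k-mers", {
  cat <- random_catalog(2, seed = 9)
  f5 <- random_dna(80, seed = 10); f3 <- random_dna(80, seed = 12)
  k <- 25
  idx <- build_reference_kmer_index(cat, k, f5, f3)
  junction <- brute_kmers(
    paste0(substr(f5, 80 - k + 2, 80), cat$sequence[1]), k)
  expect_true(all(junction %in% idx$kmer))
  # pure flank-interior k-mers are not part of the repeat space
  expect_false(substr(f5, 1, k) %in% idx$kmer)
})

test_that("diagnostic k-mers never occur in insertion-free renderings", {
  k <- 25
  withr::with_seed(99, {
    for (rep_i in 1:20) {
      cat <- random_catalog(sample(1:4, 1), gc = runif(1, 0.4, 0.8),
                            seed = sample.int(1e6, 1))
      idx <- build_reference_kmer_index(cat, k)
      cand <- variant_candidate(sample(cat$motif_id, 1), sample(0:59, 1),
                                random_dna(sample(c(1, 1, 4), 1)))
      dk <- enumerate_variant_kmers(cat, cand, k, idx)
      expect_lte(length(dk),
                 k + nchar(cand$inserted_sequence) - 1L)
      # brute-force substring scan over insertion-free alleles
      al <- vntr_allele(sample(cat$motif_id, 30, replace = TRUE))
      ref <- render_allele(al, cat)
      for (d in dk) expect_false(grepl(d, ref, fixed = TRUE))
    }
  })
})

test_that("single-C and GGCT candidates obey the per-context size bound", {
  cat <- random_catalog(2, seed = 21)
  idx <- build_reference_kmer_index(cat, 25)
  dk_c <- enumerate_variant_kmers(cat, variant_candidate("m1", 30, "C"),
                                  25, idx)
  expect_lte(length(dk_c), 25L)
  expect_true(all(nchar(dk_c) == 25L))
  dk_g <- enumerate_variant_kmers(cat, variant_candidate("m1", 30, "GGCT"),
                                  25, idx)
  expect_lte(length(dk_g), 28L)
})

test_that("insertions equivalent under homopolymer shift merge into one candidate", {
  # unit with a CCCCC run at offsets 10..14: inserting C anywhere in the
  # run (offsets 10..15) yields the same mutated sequence
  withr::with_seed(31, {
    repeat {
      u <- paste0(random_dna(10, gc = 0.5), "CCCCC",
                  random_dna(45, gc = 0.5))
      if (substr(u, 10, 10) != "C" && substr(u, 16, 16) != "C") break
    }
  })
  cat <- motif_catalog("hp", u)
  idx <- build_reference_kmer_index(cat, 25)
  sets <- lapply(10:15, function(o) {
    sort(enumerate_variant_kmers(cat, variant_candidate("hp", o, "C"),
                                 25, idx))
  })
  for (i in 2:6) expect_identical(sets[[i]], sets[[1]])
  # and candidate_insertions reports them as one merged group
  cs <- candidate_insertions(cat, "C", 25, idx)
  row <- cs$table[cs$table$offset == 10, ]
  expect_equal(nrow(row), 1L)
  expect_gte(row$n_merged, 6L)
  expect_false(any(cs$table$offset %in% 11:15))
})

test_that("merged candidate groups are pairwise disjoint and non-empty", {
  catl <- synthetic_catalog()
  fl <- default_flanks()
  idx <- build_reference_kmer_index(catl, 25, fl$flank_5p, fl$flank_3p)
  cs <- candidate_insertions(catl, c("C", "GGCT"), 25, idx,
                             fl$flank_5p, fl$flank_3p)
  all_k <- unlist(cs$kmers, use.names = FALSE)
  expect_false(any(duplicated(all_k)))
  expect_true(all(cs$table$n_kmers > 0L))
  expect_true(all(cs$table$n_core <= cs$table$n_kmers))
})

test_that("insertion left-normalisation finds the leftmost equivalent point", {
  ref <- "AATTCCCCGG"
  # inserting C anywhere inside the C run is equivalent to pos 4
  for (p in 4:8) {
    nrm <- normalize_insertion_point(ref, p, "C")
    expect_equal(nrm$pos, 4L)
    expect_equal(nrm$ins, "C")
  }
  # non-equivalent point stays put
  expect_equal(normalize_insertion_point(ref, 2, "G")$pos, 2L)
})

test_that("allele JSON round-trips", {
  al <- vntr_allele(c("m1", "m2", "m1"), insertion_spec(1, 7, "GGCT"),
                    flank_5p = "ACGT", flank_3p = "GGTT")
  path <- withr::local_tempfile(fileext = ".json")
  write_allele_json(al, path)
  back <- read_allele_json(path)
  expect_equal(back$repeat_units, al$repeat_units)
  expect_equal(back$insertion$offset, 7L)
  expect_equal(back$flank_3p, "GGTT")
})
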