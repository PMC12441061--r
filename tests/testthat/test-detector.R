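test_that("depth score is the alternate fraction of informative depth", {
  expect_equal(depth_score(0, 0), 0)
  expect_equal(depth_score(0, 1234), 0)
  expect_equal(depth_score(20, 3980), 0.005)
  for (x in c(0.5, 1, 7, 1e6)) expect_equal(depth_score(x, x), 0.5)
  expect_error(depth_score(-1, 5), "non-negative")
  # monotone in alt at fixed total, decreasing in total at fixed alt
  alt <- seq(0, 100, by = 5)
  expect_false(is.unsorted(depth_score(alt, 1000)))
  expect_false(is.unsorted(rev(depth_score(50, alt + 1))))
})

test_that("confidence boundaries are inclusive on score, strict on depth", {
  cfg <- detector_config()
  expect_equal(classify_confidence(0.00515, 21, cfg), "High")
  expect_equal(classify_confidence(0.9, 20, cfg), "Low")
  expect_equal(classify_confidence(0.00514, 1000, cfg), "Low")
  expect_equal(classify_confidence(0.00515, 20.0001, cfg), "High")
  # monotone: once High, staying High as either argument grows
  grid <- expand.grid(ds = seq(0, 0.02, by = 0.001), ad = seq(0, 60, by = 5))
  conf <- classify_confidence(grid$ds, grid$ad, cfg)
  for (i in which(conf == "High")) {
    expect_equal(classify_confidence(grid$ds[i] + 0.01, grid$ad[i], cfg),
                 "High")
    expect_equal(classify_confidence(grid$ds[i], grid$ad[i] + 10, cfg),
                 "High")
  }
})

test_that("artifact rule flags only Low-confidence multi-base insertions", {
  cfg <- detector_config()
  calls <- data.frame(
    inserted_sequence = c("GGCT", "C", "GGCT", "C"),
    confidence = c("Low", "High", "High", "Low"),
    stringsAsFactors = FALSE)
  out <- filter_artifacts(calls, cfg)
  expect_identical(out$artifact_flag, c(TRUE, FALSE, FALSE, FALSE))
  # all calls are retained, only marked
  expect_equal(nrow(out), 4L)
})

test_that("screening keeps repeat reads in both orientations, drops junk", {
  cat <- random_catalog(2, seed = 23)
  idx <- build_reference_kmer_index(cat, 25)
  cfg <- detector_config(flank_5p = NULL, flank_3p = NULL)
  al <- vntr_allele(sample(cat$motif_id, 25, replace = TRUE))
  ref <- render_allele(al, cat)
  vread <- substr(ref, 101, 250)
  junk <- random_dna(150, seed = 77)
  short_v <- substr(ref, 11, 11 + 26)  # length k + 2: three windows
  reads <- c(junk, vread, revcomp(vread), short_v)
  kept <- screen_reads(reads, idx, cfg)
  expect_identical(kept, c(vread, revcomp(vread), short_v))
  expect_error(screen_reads(reads, structure(list(k = 25, kmer = character()),
                                             class = "kmer_index"), cfg),
               "empty")
  expect_error(screen_reads(reads, idx, detector_config(k = 21)), "k")
})

test_that("k-mer depth counting matches a brute-force window count", {
  cat <- random_catalog(1, seed = 25)
  idx <- build_reference_kmer_index(cat, 25)
  cands <- candidate_insertions(cat, "C", 25, idx)
  al <- vntr_allele(rep("m1", 5))
  ref <- render_allele(al, cat)
  reads <- c(substr(ref, 1, 100), substr(ref, 50, 180),
             revcomp(substr(ref, 90, 200)))
  d <- count_kmer_depths(reads, idx, cands)
  # brute force: count windows of reads and their reverse complements
  wins <- table(factor(unlist(lapply(c(reads, revcomp(reads)), function(r) {
    n <- nchar(r); substring(r, 1:(n - 24), 25:n)
  })), levels = names(d$kmer_counts)))
  expect_equal(unname(d$kmer_counts), as.integer(wins))
  expect_equal(d$total_depth, mean(d$kmer_counts[idx$kmer]))
  # no variant support in insertion-free reads
  expect_true(all(d$alt_depth == 0))
  # zero reads: zero everywhere
  d0 <- count_kmer_depths(character(), idx, cands)
  expect_true(all(d0$kmer_counts == 0L))
  expect_equal(d0$total_depth, 0)
})

test_that("detect finds a heterozygous C insertion and nothing in wild type", {
  catl <- synthetic_catalog()
  cfg <- quick_config(seed = 41, per_base_error_rate = 0,
                      mean_coverage = 400)
  dcfg <- detector_config()
  g <- simulate_genotype(cfg, catl, carrier = TRUE)
  sim <- simulate_short_reads(g, catl, cfg)
  res <- detect(sim$reads, catl, dcfg)
  expect_equal(nrow(res$calls), 1L)
  expect_equal(res$calls$inserted_sequence, "C")
  expect_equal(res$calls$confidence, "High")
  expect_false(res$calls$artifact_flag)
  expect_equal(res$calls$depth_score,
               with(res$calls, alt_depth / (alt_depth + total_depth)))

  # the called context matches the simulated insertion after
  # left-normalisation of both representations
  carrier <- if (!is.null(g$allele_a$insertion)) g$allele_a else g$allele_b
  truth <- genotype_truth(g, catl)
  truth_ins <- c(truth$allele_a$insertion, truth$allele_b$insertion)
  ctx <- strsplit(res$calls$context, ":")[[1]]
  called_unit <- ctx[1]; called_off <- as.integer(ctx[2])
  # the candidate's unit at the truth position must agree
  expect_equal(called_unit,
               carrier$repeat_units[truth_ins$repeat_index + 1L])

  g0 <- simulate_genotype(cfg, catl, carrier = FALSE)
  sim0 <- simulate_short_reads(g0, catl, cfg)
  res0 <- detect(sim0$reads, catl, dcfg)
  expect_equal(nrow(res0$calls), 0L)
  expect_gt(res0$report$n_reads_screened, 0)
})

test_that("detect output equals the composed screen/count stages", {
  catl <- synthetic_catalog()
  fl <- default_flanks()
  cfg <- quick_config(seed = 43, mean_coverage = 150)
  dcfg <- detector_config()
  g <- simulate_genotype(cfg, catl, carrier = TRUE)
  sim <- simulate_short_reads(g, catl, cfg)
  res <- detect(sim$reads, catl, dcfg)

  idx <- build_reference_kmer_index(catl, 25, fl$flank_5p, fl$flank_3p)
  cands <- candidate_insertions(catl, "C", 25, idx, fl$flank_5p,
                                fl$flank_3p)
  full <- vntrscreen:::combine_index(idx, cands)
  screened <- screen_reads(sim$reads, full, dcfg)
  expect_equal(res$report$n_reads_screened, length(screened))
  d <- count_kmer_depths(screened, idx, cands)
  expect_equal(res$report$mean_ref_kmer_depth, d$total_depth)
  hit <- names(d$alt_depth)[d$supporting_kmers > 0]
  expect_setequal(
    res$calls$context,
    sub(":[ACGT]+$", "", hit))
})

test_that("adding alternate-supporting reads never lowers the call", {
  catl <- synthetic_catalog()
  cfg <- quick_config(seed = 47, per_base_error_rate = 0,
                      mean_coverage = 60)
  g <- simulate_genotype(cfg, catl, carrier = TRUE)
  sim <- simulate_short_reads(g, catl, cfg)
  dcfg <- detector_config()
  res1 <- detect(sim$reads, catl, dcfg)
  # duplicate reads overlapping the insertion (alt support grows,
  # reference depth fixed by construction of the added reads)
  carrier <- if (!is.null(g$allele_a$insertion)) g$allele_a else g$allele_b
  truth <- genotype_truth(g, catl)
  tri <- c(truth$allele_a$insertion, truth$allele_b$insertion)
  aseq <- render_allele(carrier, catl)
  pos <- nchar(carrier$flank_5p) + 60 * tri$repeat_index + tri$offset
  alt_read <- substr(aseq, pos - 74, pos + 75)
  res2 <- detect(c(sim$reads, rep(alt_read, 40)), catl, dcfg)
  i1 <- which(res1$calls$inserted_sequence == "C")[1]
  i2 <- which(res2$calls$inserted_sequence == "C")[1]
  expect_gt(res2$calls$alt_depth[i2], res1$calls$alt_depth[i1])
  expect_gt(res2$calls$depth_score[i2], res1$calls$depth_score[i1])
})

test_that("reads can enter the detector from SAM without alignment use", {
  skip_if_not_installed("Rsamtools")
  cat <- random_catalog(1, seed = 51)
  al <- vntr_allele(rep("m1", 3))
  ref <- render_allele(al, cat)
  reads <- c(substr(ref, 1, 60), substr(ref, 61, 120))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:chr1\tLN:1000",
    sprintf("r%d\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", seq_along(reads),
            reads, strrep("I", nchar(reads)))), sam)
  expect_identical(read_reads(sam), reads)
})
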