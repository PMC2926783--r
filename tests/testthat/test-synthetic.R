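small_cfg <- function(...) {
  sim_config(n_coding = 10L, n_lncrna = 10L, chrom_length = 1e6, ...)
}

test_that("generators are deterministic under (seed, config)", {
  cfg <- small_cfg(seed = 7L)
  a1 <- sim_annotation(cfg)
  a2 <- sim_annotation(cfg)
  expect_identical(write_bed12(a1$lncrna, header = FALSE),
                   write_bed12(a2$lncrna, header = FALSE))
  expect_identical(a1$truth, a2$truth)
  t1 <- sim_score_track(cfg, a1$lncrna)
  t2 <- sim_score_track(cfg, a2$lncrna)
  expect_identical(t1$track, t2$track)
  expect_identical(sim_alignment(cfg)$blocks, sim_alignment(cfg)$blocks)
  expect_identical(sim_ortholog_pair(cfg)$subject, sim_ortholog_pair(cfg)$subject)
  # a different seed changes the outputs
  b <- sim_annotation(small_cfg(seed = 8L))
  expect_false(identical(write_bed12(a1$lncrna, header = FALSE),
                         write_bed12(b$lncrna, header = FALSE)))
})

test_that("empty lncRNA request yields an empty cohort", {
  ann <- sim_annotation(sim_config(n_lncrna = 0L, n_coding = 5L,
                                   chrom_length = 1e6))
  expect_equal(nrow(ann$lncrna), 0L)
  expect_equal(nrow(ann$coding), 5L)
})

test_that("a genome too small for the requested loci is an error", {
  expect_error(sim_annotation(sim_config(n_lncrna = 100L, n_coding = 100L,
                                         chrom_length = 1e5)),
               "increase chrom_length")
})

test_that("planted gaps straddling the proximity threshold label exactly one locus", {
  cfg <- sim_config(n_lncrna = 2L, n_coding = 2L, chrom_length = 1e6,
                    frac_overlapping = 0, frac_proximal = 0.5,
                    proximal_gap_range = c(4999L, 4999L),
                    kept_gap_range = c(5001L, 5001L))
  ann <- sim_annotation(cfg)
  expect_equal(sort(ann$truth$class), c("kept", "within_proximity"))
  expect_setequal(ann$truth$nearest_coding_distance, c(4999L, 5001L))
  # labels agree with the exhaustive pairwise oracle
  expect_equal(ann$truth$class, o_filter(ann$lncrna, ann$coding, 5000L)$reason)
})

test_that("ground-truth labels match the pairwise oracle on a random cohort", {
  ann <- sim_annotation(small_cfg(seed = 3L))
  oracle <- o_filter(ann$lncrna, ann$coding, 5000L)
  expect_equal(ann$truth$class, oracle$reason)
  expect_equal(ann$truth$nearest_coding_distance, oracle$nearest_coding_distance)
})

test_that("track argmax near a planted locus sits at the planted promoter offset", {
  cfg <- small_cfg(seed = 5L, noise_halfwidth = 0.02)
  ann <- sim_annotation(cfg)
  trk <- sim_score_track(cfg, ann$lncrna)
  for (i in 1:4) {
    tx <- ann$lncrna[i, ]
    if (tx$strand == "+") {
      pos <- seq.int(tx$start - 200L, tx$start - 1L)
      offsets <- pos - tx$start
    } else {
      pos <- seq.int(tx$end, tx$end + 199L)
      offsets <- tx$end - 1L - pos
    }
    sc <- track_scores(trk$track, tx$chrom, pos)
    expect_lte(abs(offsets[which.max(sc)] - (-43)), 10)
  }
})

test_that("flat planted track stays flat", {
  cfg <- small_cfg(seed = 2L, promoter_peak_height = 0.05,
                   splice_peak_height = 0.05, background_score_mean = 0.05,
                   noise_halfwidth = 0, element_exonic_coverage = 0)
  ann <- sim_annotation(cfg)
  trk <- sim_score_track(cfg, ann$lncrna)
  expect_equal(unique(trk$track$score), 0.05)
})

test_that("element coverage hits its target and zero coverage is empty", {
  cfg <- small_cfg(seed = 4L)
  ann <- sim_annotation(cfg)
  trk <- sim_score_track(cfg, ann$lncrna)
  ov <- overlap_fraction(ann$lncrna, trk$elements)
  expect_lt(abs(mean(ov$exonic_fraction) - cfg$element_exonic_coverage), 0.05)
  trk0 <- sim_score_track(small_cfg(seed = 4L, element_exonic_coverage = 0),
                          ann$lncrna)
  expect_equal(nrow(trk0$elements), 0L)
})

test_that("perfect-identity alignment matches at every column", {
  cfg <- small_cfg(background_identity = 1, gap_rate = 0,
                   ecr_specs = tibble::tibble(start = integer(),
                                              length = integer(),
                                              identity = numeric()))
  aln <- sim_alignment(cfg)
  expect_true(all(column_identity(aln$blocks)))
})

test_that("planted alignment segments carry their configured identity", {
  cfg <- small_cfg(seed = 9L, aln_length = 2000L,
                   ecr_specs = tibble::tibble(start = 500L, length = 400L,
                                              identity = 0.95))
  aln <- sim_alignment(cfg)
  flags <- column_identity(aln$blocks)
  # reference is ungapped so reference base i = column i
  planted <- flags[501:900]
  expect_gt(mean(planted), 0.90)
  expect_lt(mean(flags[-(501:900)]), 0.60)
})

test_that("full-identity ortholog pair is an identical sequence copy", {
  cfg <- small_cfg(ortholog_identity = 1, add_polya = FALSE)
  pair <- sim_ortholog_pair(cfg)
  expect_identical(pair$query$seq, pair$subject$seq)
  expect_equal(pair$truth$identical_fraction, 1)
})

test_that("requested poly(A) signal lands 30 bp from the 3' end", {
  for (seed in 1:5) {
    pair <- sim_ortholog_pair(small_cfg(seed = seed, ortholog_identity = 0.5))
    L <- nchar(pair$query$seq)
    # independent string search: last ATAAA occurrence
    hits <- o_iupac_positions(pair$query$seq, "ATAAA")
    expect_equal(max(hits), L - 30L)
    expect_equal(substr(pair$query$seq, L - 29L, L - 25L), "ATAAA")
  }
})

test_that("planted identical fraction tracks the configured value", {
  for (f in c(0.3, 0.6)) {
    pair <- sim_ortholog_pair(small_cfg(seed = 12L, ortholog_identity = f))
    expect_lt(abs(pair$truth$identical_fraction - f), 0.02)
  }
})

test_that("synthetic genome plants canonical splice sites", {
  ann <- sim_annotation(small_cfg(seed = 6L))
  genome <- sim_genome_seq(ann$lncrna, seed = 6L)
  rep <- splice_consensus_report(ann$lncrna, genome)
  scored <- rep[!rep$too_short, ]
  expect_gt(nrow(scored), 0L)
  expect_true(all(scored$gt_ag))
  expect_true(all(scored$donor_consensus))
})
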