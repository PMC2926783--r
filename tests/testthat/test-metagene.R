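# A track whose score encodes its own position (score = pos / 1e4) lets the
# sampling tests read back exactly which bases were sampled.
position_track <- function(lo, hi, chrom = "chr1") {
  pos <- seq.int(lo, hi - 1L)
  score_track(chrom, pos, pos + 1L, pos / 1e4)
}

three_exon_tx <- function(strand = "+") {
  transcript_tbl("t3", "chr1", 1000L, 2000L, strand,
                 list(tibble::tibble(start = c(1000L, 1400L, 1920L),
                                     end = c(1100L, 1450L, 2000L))))
}

test_that("two-exon locus has one intron and no middle exons", {
  tx <- transcript_tbl("t2", "chr1", 500L, 900L, "+",
                       list(tibble::tibble(start = c(500L, 800L),
                                           end = c(600L, 900L))))
  parts <- partition_locus(tx)
  expect_equal(nrow(parts[parts$region == "middle_exons", ]), 0L)
  introns <- parts[parts$region == "introns", ]
  expect_equal(introns$start, 600L)
  expect_equal(introns$end, 800L)
  expect_equal(parts[parts$region == "upstream200", ]$start, 300L)
})

test_that("exon order follows transcription on either strand", {
  plus <- partition_locus(three_exon_tx("+"))
  expect_equal(plus[plus$region == "first_exon", ]$start, 1000L)
  expect_equal(plus[plus$region == "middle_exons", ]$start, 1400L)
  expect_equal(plus[plus$region == "last_exon", ]$end, 2000L)

  minus <- partition_locus(three_exon_tx("-"))
  expect_equal(minus[minus$region == "first_exon", ]$start, 1920L)
  expect_equal(minus[minus$region == "last_exon", ]$start, 1000L)
  # upstream flank of a minus-strand locus lies at higher coordinates
  up <- minus[minus$region == "upstream200", ]
  expect_equal(c(up$start, up$end), c(2000L, 2200L))
})

test_that("single-exon transcripts are rejected from the metagene partition", {
  tx <- transcript_tbl("t1", "chr1", 0L, 100L, "+")
  expect_error(partition_locus(tx), "single-exon")
})

test_that("sampling an L == k region returns the raw per-base scores", {
  trk <- position_track(0, 500)
  iv <- tibble::tibble(region = "x", feature = 1L, chrom = "chr1",
                       start = 100L, end = 300L, strand = "+")
  v <- sample_region(trk, iv, k = 200L)
  expect_equal(v, (100:299) / 1e4)
})

test_that("short regions spread onto slots without interpolation", {
  trk <- score_track("chr1", 0:2, 1:3, c(0.1, 0.2, 0.3))
  iv <- tibble::tibble(region = "x", feature = 1L, chrom = "chr1",
                       start = 0L, end = 3L, strand = "+")
  v <- sample_region(trk, iv, k = 5L)
  expect_equal(v, c(0.1, NA, 0.2, NA, 0.3))
})

test_that("downsampling positions are strictly increasing and hit both ends", {
  trk <- position_track(0, 500)
  iv <- tibble::tibble(region = "x", feature = 1L, chrom = "chr1",
                       start = 0L, end = 399L, strand = "+")
  v <- sample_region(trk, iv, k = 200L)
  pos <- v * 1e4
  expect_equal(pos[1], 0)
  expect_equal(pos[200], 398)
  expect_true(all(diff(pos) > 0))
})

test_that("minus-strand sampling walks the region 5' to 3'", {
  trk <- position_track(0, 500)
  iv <- tibble::tibble(region = "x", feature = 1L, chrom = "chr1",
                       start = 100L, end = 300L, strand = "-")
  v <- sample_region(trk, iv, k = 200L)
  expect_equal(v, (299:100) / 1e4)
})

test_that("a constant track yields a constant profile equal to one locus' vectors", {
  tx <- three_exon_tx("+")
  trk <- score_track("chr1", 700L, 2300L, 0.42)
  prof <- build_metagene(tx, trk)
  defined <- prof$mean[prof$count > 0]
  expect_true(all(abs(defined - 0.42) < 1e-12))
  # one locus: profile equals that locus' sampled vectors
  parts <- partition_locus(tx)
  up <- sample_region(trk, parts[parts$region == "upstream200", ], 200L)
  expect_equal(prof$mean[prof$region == "upstream200"], up)
})

test_that("profile values stay within the track's range and are locus-weighted", {
  cfg <- sim_config(seed = 30L, n_coding = 15L, n_lncrna = 15L, chrom_length = 2e6)
  ann <- sim_annotation(cfg)
  trk <- sim_score_track(cfg, ann$lncrna)
  prof <- build_metagene(ann$lncrna, trk$track)
  defined <- prof$mean[!is.na(prof$mean)]
  expect_gte(min(defined), min(trk$track$score))
  expect_lte(max(defined), max(trk$track$score))
  expect_equal(attr(prof, "n_loci"), 15L)

  # doubling one locus' intron length must not change its weight (count)
  counts_before <- prof$count[prof$region == "introns"]
  tx2 <- ann$lncrna
  ex <- tx2$exons[[1]]
  stretch <- 500L
  ex$start[-1] <- ex$start[-1] + stretch
  ex$end[-1] <- ex$end[-1] + stretch
  tx2$exons[[1]] <- ex
  tx2$end[1] <- ex$end[nrow(ex)]
  trk2 <- sim_score_track(cfg, tx2)
  prof2 <- build_metagene(tx2, trk2$track)
  expect_equal(prof2$count[prof2$region == "introns"], counts_before)
})

test_that("peak calling follows the argmax with anchor-proximal tie-breaks", {
  schema <- region_schema(samples_per_region = 10L, flank_length = 10L)
  mk_prof <- function(vals) {
    df <- tidyr::expand_grid(region = schema$regions, slot = 0:9)
    df$mean <- NA_real_
    df$count <- 0L
    df$mean[df$region == "upstream200"] <- vals
    df$count[df$region == "upstream200"] <- 1L
    structure(df, class = c("metagene_profile", class(df)), schema = schema,
              n_loci = 1L)
  }
  inc <- mk_prof(seq(0.01, 0.10, by = 0.01))
  expect_equal(call_peak(inc, "upstream200")$slot, 9L)
  flat <- mk_prof(rep(0.5, 10))
  # upstream region is TSS-anchored at its 3' end: ties go to the last slot
  expect_equal(call_peak(flat, "upstream200")$slot, 9L)
  expect_equal(call_peak(flat, "upstream200")$offset_bp, -1)
  expect_error(call_peak(mk_prof(rep(NA_real_, 10)), "first_exon"), "no defined")
})

test_that("planted promoter bump is recovered from a synthetic cohort", {
  cfg <- sim_config(seed = 101L, n_coding = 0L, n_lncrna = 100L,
                    chrom_length = 4e6, frac_overlapping = 0, frac_proximal = 0)
  ann <- sim_annotation(cfg)
  trk <- sim_score_track(cfg, ann$lncrna)
  prof <- build_metagene(ann$lncrna, trk$track)
  peak <- call_peak(prof, "upstream200")
  expect_lte(abs(peak$offset_bp - (-43)), 10)
  expect_lte(abs(peak$height - 0.19), 0.03)
  g <- glance(prof)
  expect_equal(g$promoter_peak_offset_bp, peak$offset_bp)
  p <- autoplot(prof)
  expect_s3_class(p, "ggplot")
})
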