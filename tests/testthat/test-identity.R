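test_that("identical sequences produce one full-length hit at 100%", {
  s <- rand_seq(50)
  hits <- local_align(s, s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identities, 50L)
  expect_equal(hits$aligned_len, 50L)
  expect_equal(overall_identity(s, s)$percent, 100)
})

test_that("a planted exact 40-mer is the top hit with 40 identities", {
  set.seed(5)
  core <- rand_seq(40)
  q_left <- rand_seq(30); q_right <- rand_seq(30)
  s_left <- rand_seq(80); s_right <- rand_seq(80)
  # force mismatches at both junctions so the optimum is exactly the core
  force_mismatch <- function(a, b) {
    if (substr(a, nchar(a), nchar(a)) == substr(b, nchar(b), nchar(b))) {
      substr(a, nchar(a), nchar(a)) <- setdiff(c("A","C","G","T"),
                                               substr(b, nchar(b), nchar(b)))[1]
    }
    a
  }
  q_left <- force_mismatch(q_left, s_left)
  q <- paste0(q_left, core, q_right)
  s <- paste0(s_left, core, s_right)
  if (substr(q_right, 1, 1) == substr(s_right, 1, 1)) {
    substr(q_right, 1, 1) <- setdiff(c("A","C","G","T"), substr(s_right, 1, 1))[1]
    q <- paste0(q_left, core, q_right)
  }
  hits <- local_align(q, s, min_score = 30)
  expect_equal(hits$identities[1], 40L)
  expect_equal(hits$query_start[1], 30L)
  expect_equal(hits$query_end[1], 70L)
})

test_that("best local score agrees with a full Smith-Waterman DP oracle", {
  set.seed(31)
  for (i in 1:30) {
    q <- rand_seq(sample(8:30, 1))
    s <- rand_seq(sample(8:30, 1))
    want <- o_sw_score(q, s)
    got <- local_align(q, s, min_score = 1)
    got_score <- if (nrow(got) > 0) max(got$score) else 0
    if (want < 1) {
      expect_lte(got_score, max(want, 0))
    } else {
      expect_equal(got_score, want)
    }
  }
})

test_that("masking keeps hits non-overlapping on the query and percent <= 100", {
  set.seed(8)
  pair <- sim_ortholog_pair(sim_config(seed = 8L, ortholog_identity = 0.5,
                                       ortholog_length = 1200L))
  hits <- local_align(pair$query, pair$subject)
  if (nrow(hits) > 1) {
    o <- order(hits$query_start)
    expect_true(all(hits$query_start[o][-1] >= hits$query_end[o][-nrow(hits)]))
  }
  summ <- overall_identity(pair$query, pair$subject)
  expect_lte(summ$percent, 100)
  expect_lte(summ$total_identities, summ$query_length)
})

test_that("zero accepted hits gives zero percent identity", {
  expect_equal(overall_identity("ACGTACGTACGT", "TTTTTTTTTTTT")$percent, 0)
})

test_that("overall identity is asymmetric in the query (denominator)", {
  set.seed(14)
  core <- rand_seq(300)
  short <- core
  long <- paste0(core, rand_seq(300))
  a <- overall_identity(short, long)$percent
  b <- overall_identity(long, short)$percent
  expect_gt(a, b)
  expect_gt(a, 90)
})

test_that("min_score must be positive", {
  expect_error(local_align("ACGT", "ACGT", min_score = 0), "min_score")
})

test_that("identity recovery is calibrated to the planted fraction", {
  for (f in c(0.4, 0.8)) {
    pair <- sim_ortholog_pair(sim_config(seed = 20L, ortholog_identity = f,
                                         ortholog_length = 2000L))
    pct <- overall_identity(pair$query, pair$subject)$percent
    expect_lt(abs(pct - 100 * f), 5)
  }
})

test_that("windowed identity matches direct window counting", {
  b <- tibble::tibble(
    block_id = 1L, species = c("mouse", "chicken"), src_chrom = "chr1",
    src_start = c(100L, 0L), src_size = c(40L, 40L), strand = "+",
    src_length = c(500L, 500L),
    text = c(rand_seq(40), NA))
  b$text[2] <- b$text[1]
  prof <- windowed_identity_profile(b, window = 10L, step = 5L)
  expect_true(all(prof$percent == 100))
  expect_equal(prof$window_start[1], 100L)

  # alternating match/mismatch -> 50%
  ref <- strsplit(rand_seq(40), "")[[1]]
  oth <- ref
  oth[seq(1, 40, 2)] <- vapply(ref[seq(1, 40, 2)],
                               function(x) setdiff(c("A","C","G","T"), x)[1], "")
  b2 <- b
  b2$text <- c(paste(ref, collapse = ""), paste(oth, collapse = ""))
  prof2 <- windowed_identity_profile(b2, window = 10L, step = 10L)
  expect_true(all(prof2$percent == 50))
  # step == window tiles the reference without overlap
  expect_equal(prof2$window_start, c(100L, 110L, 120L, 130L))
  expect_equal(prof2$window_end, c(110L, 120L, 130L, 140L))
})

test_that("windowed identity agrees with the oracle on gapped random rows", {
  set.seed(63)
  for (i in 1:10) {
    n <- sample(60:180, 1)
    ref <- strsplit(rand_seq(n), "")[[1]]
    oth <- ref
    flip <- which(runif(n) > 0.7)
    oth[flip] <- vapply(ref[flip], function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
    oth[runif(n) < 0.05] <- "-"
    ref[runif(n) < 0.03] <- "-"
    b <- tibble::tibble(
      block_id = 1L, species = c("m", "c"), src_chrom = "chr1",
      src_start = c(7L, 0L),
      src_size = c(sum(ref != "-"), sum(oth != "-")), strand = "+",
      src_length = 1000L,
      text = c(paste(ref, collapse = ""), paste(oth, collapse = "")))
    w <- 20L; st <- 7L
    got <- windowed_identity_profile(b, window = w, step = st)
    want <- o_windowed(b$text[1], b$text[2], 7L, w, st)
    expect_equal(got$window_start, want$window_start)
    expect_equal(got$window_end, want$window_end)
    expect_equal(got$percent, want$percent)
  }
})
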