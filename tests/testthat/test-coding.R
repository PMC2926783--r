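test_that("ORF detection handles absent, minimal and incomplete ORFs", {
  expect_true(is.na(find_longest_orf("CCCCCC")$nt_start))
  orf <- find_longest_orf("ATGAAATAG")
  expect_equal(orf$aa_length, 2L)  # ATG-AAA translated MK, stop excluded
  expect_true(orf$complete)
  expect_equal(orf$nt_end, 9L)
  # ATG without a downstream stop: incomplete, counted by current length
  inc <- find_longest_orf("CCATGAAAAAA")
  expect_false(inc$complete)
  expect_equal(inc$aa_length, 3L)
  expect_equal(inc$frame, 2L)
})

test_that("longest ORF wins; ties resolve 5'-most; N-containing ORFs skipped", {
  # frame 0: ATG AAA TAG (2 aa); frame offset later: ATG AAA AAA TAG (3 aa)
  seq <- paste0("ATGAAATAG", "ATGAAAAAATAG")
  orf <- find_longest_orf(seq)
  expect_equal(orf$aa_length, 3L)
  expect_equal(orf$nt_start, 9L)
  # equal-length candidates: the 5'-most start is reported
  seq2 <- paste0("ATGAAATAG", "ATGCCCTAG")
  expect_equal(find_longest_orf(seq2)$nt_start, 0L)
  # an N inside the ORF body disqualifies it
  expect_true(is.na(find_longest_orf("ATGANATAG")$nt_start))
})

test_that("the long-ORF flag is a strict >100 aa rule", {
  orf100 <- paste0("ATG", strrep("AAA", 99L), "TAG")   # 100 aa with Met
  orf101 <- paste0("ATG", strrep("AAA", 100L), "TAG")  # 101 aa
  expect_false(find_longest_orf(orf100)$long_orf)
  expect_true(find_longest_orf(orf101)$long_orf)
})

test_that("NG86 site counts match hand enumeration", {
  expect_equal(ng86_sites("TTT"), c(n = 8 / 3, s = 1 / 3))
  expect_equal(ng86_sites("GTT"), c(n = 2, s = 1))
  expect_equal(ng86_sites("ATG"), c(n = 3, s = 0))
  expect_error(ng86_sites("TAA"), "stop")
  expect_error(ng86_sites("AXG"), "ACGT")
})

test_that("site counts agree with the independent enumeration for all sense codons", {
  sense <- setdiff(names(Biostrings::GENETIC_CODE)[
    !grepl("U", names(Biostrings::GENETIC_CODE))], c("TAA", "TAG", "TGA"))
  for (codon in sense) {
    expect_equal(unname(ng86_sites(codon)), unname(o_sites(codon)),
                 tolerance = 1e-12)
  }
})

test_that("identical sequences give zero differences and an undefined ratio", {
  s <- rand_sense_codons(50)
  est <- ng86_dnds(s, s)
  expect_equal(est$Nd, 0)
  expect_equal(est$Sd, 0)
  expect_equal(est$dN, 0)
  expect_equal(est$dS, 0)
  expect_false(est$ratio_defined)
})

test_that("single synonymous difference saturates the correction", {
  est <- ng86_dnds("GTT", "GTA")
  expect_equal(est$S, 1)
  expect_equal(est$Sd, 1)
  expect_equal(est$Nd, 0)
  expect_equal(est$pS, 1)
  expect_false(est$dS_defined)
})

test_that("difference counting matches the path-enumeration oracle", {
  set.seed(19)
  for (i in 1:20) {
    n <- 40L
    a <- rand_sense_codons(n)
    bchars <- strsplit(a, "")[[1]]
    hit <- runif(length(bchars)) < 0.15
    bchars[hit] <- vapply(bchars[hit],
                          function(x) sample(setdiff(c("A","C","G","T"), x), 1), "")
    b <- paste(bchars, collapse = "")
    cods <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    internal_stop <- which(cods %in% c("TAA", "TAG", "TGA"))
    if (length(internal_stop) > 0) {
      cods[internal_stop] <- substring(a, 3 * internal_stop - 2, 3 * internal_stop)
    }
    b <- paste(cods, collapse = "")
    est <- ng86_dnds(a, b)
    want <- o_ng86(a, b)
    dropped <- est$n_stop_path_dropped
    expect_equal(est$N, want$N, tolerance = 1e-9)
    expect_equal(est$Nd, want$Nd, tolerance = 1e-9)
    expect_equal(est$Sd, want$Sd, tolerance = 1e-9)
    expect_equal(est$codons_compared + dropped, want$compared + dropped)
    # site conservation: N + S = 3 x codons compared
    expect_equal(est$N + est$S, 3 * est$codons_compared, tolerance = 1e-6)
  }
})

test_that("the estimate is symmetric in its arguments", {
  set.seed(23)
  pair <- sim_neutral_codon_pair(80L, 0.08, seed = 23L)
  ab <- glance(ng86_dnds(pair$a, pair$b))
  ba <- glance(ng86_dnds(pair$b, pair$a))
  expect_equal(ab, ba, tolerance = 1e-12)
})

test_that("gapped codons are dropped pairwise and internal stops are an error", {
  a <- "ATGGTTAAA"
  b <- "ATG---AAA"
  est <- ng86_dnds(a, b)
  expect_equal(est$n_gapped_dropped, 1L)
  expect_equal(est$codons_compared, 2L)
  expect_error(ng86_dnds("ATGTAAAAA", "ATGTAAAAA"), "codon 2")
})

test_that("Jukes-Cantor correction is monotone below saturation", {
  est <- function(p) -(3 / 4) * log(1 - 4 * p / 3)
  ps <- seq(0.01, 0.74, by = 0.01)
  expect_true(all(diff(vapply(ps, est, 1)) > 0))
  # dX > pX for p > 0 (multiple-hit correction inflates)
  expect_true(all(vapply(ps, est, 1) > ps))
})

test_that("neutral simulation is centred on dN/dS of one", {
  ratios <- vapply(1:10, function(s) {
    pair <- sim_neutral_codon_pair(300L, 0.05, seed = s)
    ng86_dnds(pair$a, pair$b)$ratio
  }, 1)
  expect_true(all(is.finite(ratios)))
  expect_gt(median(ratios), 0.75)
  expect_lt(median(ratios), 1.3)
})

test_that("tidy and glance expose the estimate fields", {
  pair <- sim_neutral_codon_pair(100L, 0.05, seed = 2L)
  est <- ng86_dnds(pair$a, pair$b)
  td <- tidy(est)
  expect_setequal(td$term, c("N", "S", "Nd", "Sd", "pN", "pS", "dN", "dS", "ratio"))
  g <- glance(est)
  expect_equal(g$ratio, est$ratio)
  expect_output(print(est), "Nei-Gojobori")
})
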