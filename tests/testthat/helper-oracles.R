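# Independent brute-force oracles. Each re-derives a quantity from first
# principles (per-base sets, exhaustive window/path enumeration, full DP)
# without sharing code with the implementation it checks.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rand_tx_tbl <- function(n, chrom_len = 10000L, max_exons = 4L, prefix = "tx",
                        biotype = "lncRNA") {
  recs <- lapply(seq_len(n), function(i) {
    k <- sample(1:max_exons, 1)
    sizes <- sample(20:120, k, TRUE)
    gaps <- if (k > 1) sample(30:200, k - 1, TRUE) else integer(0)
    span <- sum(sizes) + sum(gaps)
    at <- sample(0:(chrom_len - span), 1)
    starts <- at + cumsum(c(0L, sizes[-k] + gaps))
    tibble::tibble(start = as.integer(starts), end = as.integer(starts + sizes))
  })
  transcript_tbl(
    tx_id = sprintf("%s%03d", prefix, seq_len(n)),
    chrom = "chr1",
    start = vapply(recs, function(e) e$start[1], 1L),
    end = vapply(recs, function(e) e$end[nrow(e)], 1L),
    strand = sample(c("+", "-"), n, TRUE),
    exons = recs, biotype = biotype
  )
}

# --- locus filter -----------------------------------------------------------

o_filter <- function(lncrna, coding, min_distance = 5000L) {
  per_base <- function(ex) unlist(mapply(function(s, e) seq.int(s, e - 1L),
                                         ex$start, ex$end, SIMPLIFY = FALSE))
  purrr::map_dfr(seq_len(nrow(lncrna)), function(i) {
    same <- coding[coding$chrom == lncrna$chrom[i], , drop = FALSE]
    lb <- per_base(lncrna$exons[[i]])
    ov <- FALSE
    dist <- NA_integer_
    if (nrow(same) > 0) {
      for (j in seq_len(nrow(same))) {
        if (length(intersect(lb, per_base(same$exons[[j]]))) > 0) ov <- TRUE
      }
      gaps <- vapply(seq_len(nrow(same)), function(j) {
        if (same$start[j] >= lncrna$end[i]) same$start[j] - lncrna$end[i]
        else if (lncrna$start[i] >= same$end[j]) lncrna$start[i] - same$end[j]
        else 0L
      }, 1L)
      dist <- min(gaps)
    }
    reason <- if (ov) "overlaps_coding"
              else if (!is.na(dist) && dist < min_distance) "within_proximity"
              else "kept"
    tibble::tibble(tx_id = lncrna$tx_id[i], kept = reason == "kept",
                   reason = reason, nearest_coding_distance = dist)
  })
}

o_overlap <- function(tx, elements) {
  purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    el <- elements[elements$chrom == tx$chrom[i], , drop = FALSE]
    el_bases <- unique(unlist(mapply(function(s, e) seq.int(s, e - 1L),
                                     el$start, el$end, SIMPLIFY = FALSE)))
    ex <- tx$exons[[i]]
    ex_bases <- unlist(mapply(function(s, e) seq.int(s, e - 1L),
                              ex$start, ex$end, SIMPLIFY = FALSE))
    locus_bases <- seq.int(tx$start[i], tx$end[i] - 1L)
    tibble::tibble(
      tx_id = tx$tx_id[i],
      exonic_fraction = length(intersect(ex_bases, el_bases)) / length(ex_bases),
      genic_fraction = length(intersect(locus_bases, el_bases)) / length(locus_bases),
      has_constrained = length(intersect(locus_bases, el_bases)) > 0
    )
  })
}

# --- ECR --------------------------------------------------------------------

o_ecr_from_flags <- function(flags, w, min_identity, src_start = 0L) {
  n <- length(flags)
  if (n < w) return(tibble::tibble(start = integer(), end = integer(),
                                   identity = numeric(), n_windows = integer()))
  qual_start <- c()
  for (s in 1:(n - w + 1L)) {
    if (sum(flags[s:(s + w - 1L)]) / w >= min_identity - 1e-9) {
      qual_start <- c(qual_start, s)
    }
  }
  if (length(qual_start) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          identity = numeric(), n_windows = integer()))
  }
  covered <- rep(FALSE, n)
  for (s in qual_start) covered[s:(s + w - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  purrr::map_dfr(keep, function(k) {
    s <- starts[k]; e <- ends[k]
    tibble::tibble(start = src_start + s - 1L, end = src_start + e,
                   identity = 100 * sum(flags[s:e]) / (e - s + 1L),
                   n_windows = sum(qual_start >= s & qual_start + w - 1L <= e))
  })
}

o_column_flags <- function(ref, oth) {
  a <- strsplit(toupper(ref), "")[[1]]
  b <- strsplit(toupper(oth), "")[[1]]
  keep <- a != "-"
  (a == b & b != "-" & a != "N" & b != "N")[keep]
}

# --- windowed identity ------------------------------------------------------

o_windowed <- function(ref, oth, src_start, window, step) {
  a <- strsplit(toupper(ref), "")[[1]]
  b <- strsplit(toupper(oth), "")[[1]]
  n <- length(a)
  out <- list()
  for (cs in seq(1, n - window + 1L, by = step)) {
    cols <- cs:(cs + window - 1L)
    ref_cols <- cols[a[cols] != "-"]
    if (length(ref_cols) == 0L) next
    matches <- sum(a[cols] == b[cols] & a[cols] != "-" & b[cols] != "-" &
                     a[cols] != "N" & b[cols] != "N")
    ref_ord <- cumsum(a != "-")
    out[[length(out) + 1L]] <- tibble::tibble(
      window_start = src_start + ref_ord[ref_cols[1]] - 1L,
      window_end = src_start + ref_ord[ref_cols[length(ref_cols)]],
      percent = 100 * matches / window)
  }
  dplyr::bind_rows(out)
}

# --- IUPAC ------------------------------------------------------------------

o_iupac_tbl <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
                 H = "ACT", V = "ACG", N = "ACGT")

o_iupac_positions <- function(seq, pattern) {
  seq <- toupper(seq)
  pat <- toupper(gsub("|", "", pattern, fixed = TRUE))
  n <- nchar(seq)
  m <- nchar(pat)
  hits <- integer(0)
  if (n < m) return(hits)
  for (p in 0:(n - m)) {
    ok <- TRUE
    for (j in 1:m) {
      allowed <- strsplit(o_iupac_tbl[[substr(pat, j, j)]], "")[[1]]
      if (!substr(seq, p + j, p + j) %in% allowed) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# --- NG86 -------------------------------------------------------------------

o_translate <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

o_sites <- function(codon) {
  aa <- o_translate(codon)
  syn <- 0; tot <- 0
  for (p in 1:3) for (b in c("A", "C", "G", "T")) {
    if (b == substr(codon, p, p)) next
    mut <- codon
    substr(mut, p, p) <- b
    if (o_translate(mut) == "*") next
    tot <- tot + 1
    if (o_translate(mut) == aa) syn <- syn + 1
  }
  c(n = 3 - 3 * syn / tot, s = 3 * syn / tot)
}

# recursive path enumeration (vs the implementation's permutation loop)
o_paths <- function(cur, tgt) {
  pos <- which(strsplit(cur, "")[[1]] != strsplit(tgt, "")[[1]])
  if (length(pos) == 0L) return(list(c(nd = 0, sd = 0)))
  out <- list()
  for (p in pos) {
    nxt <- cur
    substr(nxt, p, p) <- substr(tgt, p, p)
    if (o_translate(nxt) == "*") next
    step <- if (o_translate(cur) == o_translate(nxt)) c(nd = 0, sd = 1) else c(nd = 1, sd = 0)
    for (rest in o_paths(nxt, tgt)) out[[length(out) + 1L]] <- step + rest
  }
  out
}

o_ng86 <- function(a, b) {
  n_codons <- nchar(a) %/% 3L
  N <- S <- Nd <- Sd <- 0
  compared <- 0L
  for (i in seq_len(n_codons)) {
    ca <- substr(a, 3 * i - 2, 3 * i)
    cb <- substr(b, 3 * i - 2, 3 * i)
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    if (o_translate(ca) == "*" || o_translate(cb) == "*") next
    paths <- o_paths(ca, cb)
    if (length(paths) == 0L) next
    d <- Reduce(`+`, paths) / length(paths)
    sa <- o_sites(ca); sb <- o_sites(cb)
    N <- N + (sa["n"] + sb["n"]) / 2
    S <- S + (sa["s"] + sb["s"]) / 2
    Nd <- Nd + d["nd"]; Sd <- Sd + d["sd"]
    compared <- compared + 1L
  }
  list(N = unname(N), S = unname(S), Nd = unname(Nd), Sd = unname(Sd),
       pN = unname(Nd / N), pS = unname(Sd / S), compared = compared)
}

rand_sense_codons <- function(n) {
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")), 1, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  paste(sample(sense, n, TRUE), collapse = "")
}

# --- Smith-Waterman local affine DP (score only) ---------------------------

o_sw_score <- function(q, s, match = 2, mismatch = -3, gap_open = 5, gap_extend = 2) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  H <- E <- F <- matrix(0, n + 1, m + 1)
  E[,] <- -Inf; F[,] <- -Inf
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - gap_open - gap_extend, F[i - 1, j] - gap_extend)
      sub <- if (qc[i - 1] == sc[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}
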