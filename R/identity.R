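# Ortholog percent identity. Overall identity between two cDNAs follows the
# summed-local-alignment convention: the best affine-gap local alignment is
# recorded, its query span masked, and the search repeated until no hit
# reaches min_score; percent identity is summed identical pairs over the
# query length. Scoring defaults mirror BLASTn nucleotide defaults
# (match +2, mismatch -3, gap open 5, gap extend 2).

dna_scoring_matrix <- function(match = 2, mismatch = -3) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch  # N never counts as a match
  m
}

as_seq <- function(x, what) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) abort(sprintf("`%s` must be a single record", what))
    return(list(id = x$id[1], seq = x$seq[1]))
  }
  if (is.character(x) && length(x) == 1L) {
    return(list(id = names(x) %||% what, seq = toupper(x)))
  }
  abort(sprintf("`%s` must be a one-row cDNA tibble or a single string", what))
}

best_local_hit <- function(qseq, sseq, mat, gap_open, gap_extend) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(qseq), subject = Biostrings::DNAString(sseq),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  list(score = Biostrings::score(aln),
       q_start = Biostrings::start(pat) - 1L,
       q_end = Biostrings::end(pat),
       s_start = Biostrings::start(sub) - 1L,
       s_end = Biostrings::end(sub),
       identities = Biostrings::nmatch(aln),
       aligned_len = nchar(as.character(pat)),
       pat_text = as.character(pat),
       sub_text = as.character(sub))
}

# Split an optimal local alignment into X-drop-delimited positive-scoring
# segments, the way seeded aligners report HSPs: an exact DP happily bridges
# long net-negative stretches whenever the anchor beyond them outweighs the
# bridge, which inflates summed identities with spurious gap-shifted matches.
# Walking the per-column scores and cutting wherever the running score falls
# `xdrop` below its running maximum removes those bridges deterministically.
decompose_hit <- function(h, mat, gap_open, gap_extend, min_score, xdrop) {
  qc <- strsplit(h$pat_text, "")[[1]]
  sc <- strsplit(h$sub_text, "")[[1]]
  n <- length(qc)
  col_score <- numeric(n)
  in_gap <- FALSE
  for (i in seq_len(n)) {
    if (qc[i] == "-" || sc[i] == "-") {
      col_score[i] <- -gap_extend - (if (in_gap) 0 else gap_open)
      in_gap <- TRUE
    } else {
      col_score[i] <- mat[qc[i], sc[i]]
      in_gap <- FALSE
    }
  }
  q_before <- cumsum(c(0L, head(as.integer(qc != "-"), -1L)))
  s_before <- cumsum(c(0L, head(as.integer(sc != "-"), -1L)))
  is_match <- qc == sc & qc != "-" & qc != "N" & sc != "N"
  segs <- list()
  cur_start <- 1L
  run <- 0
  best <- 0
  best_i <- 0L
  emit <- function(from, to, sc_val) {
    if (sc_val < min_score || to < from) return(NULL)
    tibble::tibble(
      q_start = h$q_start + q_before[from],
      q_end = h$q_start + q_before[to] + as.integer(qc[to] != "-"),
      s_start = h$s_start + s_before[from],
      s_end = h$s_start + s_before[to] + as.integer(sc[to] != "-"),
      score = sc_val,
      identities = as.integer(sum(is_match[from:to])),
      aligned_len = to - from + 1L)
  }
  for (i in seq_len(n)) {
    run <- run + col_score[i]
    if (run > best) {
      best <- run
      best_i <- i
    }
    if (best <= 0 && run < 0) {  # nothing positive yet: restart
      cur_start <- i + 1L
      run <- 0
      best <- 0
      best_i <- i
      next
    }
    if (run < best - xdrop) {  # fell too far below the running maximum: cut
      seg <- emit(cur_start, best_i, best)
      if (!is.null(seg)) segs[[length(segs) + 1L]] <- seg
      cur_start <- i + 1L
      run <- 0
      best <- 0
      best_i <- i
    }
  }
  seg <- emit(cur_start, best_i, best)
  if (!is.null(seg)) segs[[length(segs) + 1L]] <- seg
  dplyr::bind_rows(segs)
}

#' Iterated masked local alignments between two cDNAs
#'
#' Finds the best-scoring affine-gap local alignment, splits it into
#' X-drop-delimited positive segments (see below), records those, masks the
#' alignment's query span, and repeats until the best remaining score falls
#' below `min_score`. Ties between equal-scoring candidates resolve to the
#' smallest query start, then smallest subject start.
#'
#' Exact local DP will bridge a long low-identity stretch whenever the
#' conserved anchor beyond it outweighs the bridge cost; seeded aligners
#' (whose summed-HSP identity convention this function reproduces) do not,
#' because extension stops once the score drops `xdrop` below its running
#' maximum. Each optimal alignment is therefore decomposed by the same
#' rule, so reported identities exclude spurious matches inside bridged
#' low-identity stretches.
#'
#' @param query,subject one-row cDNA tibbles or single sequence strings.
#' @param match,mismatch,gap_open,gap_extend scoring (BLASTn nucleotide
#'   defaults; gap penalties are positive costs).
#' @param min_score minimum accepted segment score (> 0).
#' @param max_hits safety cap on the number of masking iterations.
#' @param xdrop score drop from the running maximum at which an alignment
#'   is split.
#' @return a tibble of hits sorted by score descending: `query_start`,
#'   `query_end`, `subject_start`, `subject_end` (0-based half-open),
#'   `score`, `identities`, `aligned_len`.
#' @export
local_align <- function(query, subject, match = 2, mismatch = -3,
                        gap_open = 5, gap_extend = 2, min_score = 30,
                        max_hits = 64L, xdrop = 50) {
  if (min_score <= 0) abort("`min_score` must be > 0 (risk of nontermination)")
  q <- as_seq(query, "query")
  s <- as_seq(subject, "subject")
  if (!nzchar(q$seq) || !nzchar(s$seq)) abort("sequences must be non-empty")
  mat <- dna_scoring_matrix(match, mismatch)
  # segments of the query still unmasked; per-segment best hit memoised
  segs <- list(list(off = 0L, seq = q$seq, best = NULL))
  hits <- list()
  while (length(hits) < max_hits) {
    for (i in seq_along(segs)) {
      if (is.null(segs[[i]]$best) && nchar(segs[[i]]$seq) >= 1L) {
        segs[[i]]$best <- best_local_hit(segs[[i]]$seq, s$seq, mat,
                                         gap_open, gap_extend)
      }
    }
    scores <- purrr::map_dbl(segs, ~ .x$best$score %||% -Inf)
    if (length(scores) == 0L || max(scores) < min_score) break
    qstarts <- purrr::map_dbl(segs, ~ if (is.null(.x$best)) Inf else .x$off + .x$best$q_start)
    sstarts <- purrr::map_dbl(segs, ~ if (is.null(.x$best)) Inf else .x$best$s_start)
    ord <- order(-scores, qstarts, sstarts)
    i <- ord[1]
    seg <- segs[[i]]
    h <- seg$best
    pieces <- decompose_hit(h, mat, gap_open, gap_extend, min_score, xdrop)
    if (nrow(pieces) > 0L) {
      hits[[length(hits) + 1L]] <- tibble::tibble(
        query_start = seg$off + pieces$q_start,
        query_end = seg$off + pieces$q_end,
        subject_start = pieces$s_start, subject_end = pieces$s_end,
        score = pieces$score, identities = pieces$identities,
        aligned_len = pieces$aligned_len)
    }
    left <- list(off = seg$off, seq = substr(seg$seq, 1L, h$q_start), best = NULL)
    right <- list(off = seg$off + h$q_end,
                  seq = substr(seg$seq, h$q_end + 1L, nchar(seg$seq)), best = NULL)
    segs[[i]] <- NULL
    if (nchar(left$seq) > 0L) segs[[length(segs) + 1L]] <- left
    if (nchar(right$seq) > 0L) segs[[length(segs) + 1L]] <- right
  }
  if (length(hits) == 0L) {
    return(tibble::tibble(query_start = integer(), query_end = integer(),
                          subject_start = integer(), subject_end = integer(),
                          score = numeric(), identities = integer(),
                          aligned_len = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(hits), dplyr::desc(.data$score),
                 .data$query_start, .data$subject_start)
}

#' Overall percent identity between ortholog cDNAs
#'
#' Percent identity is 100 x (identical aligned pairs summed over the
#' masked, non-overlapping local hits) / query length. The measure is not
#' symmetric: the denominator is the query (reference-species transcript)
#' length, so swapping the arguments changes the percentage when lengths
#' differ.
#'
#' @inheritParams local_align
#' @return a one-row tibble: `query_id`, `subject_id`, `n_hits`,
#'   `total_identities`, `query_length`, `percent`.
#' @export
overall_identity <- function(query, subject, match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2, min_score = 30,
                             xdrop = 50) {
  q <- as_seq(query, "query")
  s <- as_seq(subject, "subject")
  hits <- local_align(query, subject, match, mismatch, gap_open, gap_extend,
                      min_score, xdrop = xdrop)
  total <- sum(hits$identities)
  tibble::tibble(
    query_id = q$id, subject_id = s$id, n_hits = nrow(hits),
    total_identities = as.integer(total), query_length = nchar(q$seq),
    percent = 100 * total / nchar(q$seq)
  )
}

#' Windowed percent-identity profile along alignment blocks
#'
#' Identity of each window of `window` alignment columns (advanced by
#' `step`), per non-reference row, mapped to the reference coordinates of
#' the window's first and last reference bases. A column counts as a match
#' when both characters are non-gap, non-N and equal case-insensitively;
#' windows containing no reference base are skipped.
#'
#' @param blocks an alignment-block tibble.
#' @param window window size in alignment columns (>= 2).
#' @param step step in alignment columns.
#' @return a tibble: `block_id`, `species`, `window_start`, `window_end`
#'   (reference coordinates, half-open), `percent`.
#' @export
windowed_identity_profile <- function(blocks, window = 100L, step = 10L) {
  if (window < 2L) abort("`window` must be >= 2")
  if (step < 1L) abort("`step` must be >= 1")
  validate_maf_blocks(blocks)
  out <- list()
  for (b in unique(blocks$block_id)) {
    rows <- blocks[blocks$block_id == b, , drop = FALSE]
    ref <- strsplit(toupper(rows$text[1]), "")[[1]]
    ncol <- length(ref)
    if (ncol < window) next
    is_ref <- ref != "-"
    ref_idx <- cumsum(is_ref)  # 1-based ref base ordinal at each column
    starts <- seq.int(1L, ncol - window + 1L, by = step)
    for (j in seq_len(nrow(rows))[-1]) {
      oth <- strsplit(toupper(rows$text[j]), "")[[1]]
      m <- as.integer(ref == oth & is_ref & oth != "-" & ref != "N" & oth != "N")
      cm <- cumsum(c(0L, m))
      crb <- cumsum(c(0L, as.integer(is_ref)))
      for (cstart in starts) {
        cend <- cstart + window - 1L
        nref <- crb[cend + 1L] - crb[cstart]
        if (nref == 0L) next
        first_ref <- ref_idx[cstart] + if (is_ref[cstart]) 0L else 1L
        last_ref <- ref_idx[cend]
        matches <- cm[cend + 1L] - cm[cstart]
        out[[length(out) + 1L]] <- tibble::tibble(
          block_id = b, species = rows$species[j],
          window_start = rows$src_start[1] + first_ref - 1L,
          window_end = rows$src_start[1] + last_ref,
          percent = 100 * matches / window
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(block_id = integer(), species = character(),
                          window_start = integer(), window_end = integer(),
                          percent = numeric()))
  }
  dplyr::bind_rows(out)
}
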