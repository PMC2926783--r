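# Evolutionarily conserved regions: every window of exactly `min_length`
# consecutive reference bases whose match fraction reaches `min_identity`
# qualifies; overlapping/adjacent qualifying windows are merged into maximal
# intervals. Windows are measured in reference (ungapped) bases, stepped by
# one; an N or a gap in either row is a mismatch.

#' Per-reference-base match flags between two alignment rows
#'
#' @param blocks an alignment-block tibble.
#' @param block_id which block to score.
#' @param row_a,row_b row indices within the block (1-based; `row_a` is the
#'   reference).
#' @return a logical vector with one flag per non-gap reference base: `TRUE`
#'   where both characters are non-gap, non-N and equal case-insensitively.
#' @export
column_identity <- function(blocks, block_id = 1L, row_a = 1L, row_b = 2L) {
  rows <- blocks[blocks$block_id == block_id, , drop = FALSE]
  if (nrow(rows) == 0L) abort(sprintf("no block with id %s", block_id))
  if (row_a > nrow(rows) || row_b > nrow(rows) || row_a < 1L || row_b < 1L) {
    abort("row index out of range for block")
  }
  a <- strsplit(toupper(rows$text[row_a]), "")[[1]]
  b <- strsplit(toupper(rows$text[row_b]), "")[[1]]
  ref_bases <- a != "-"
  match <- a == b & a != "-" & b != "-" & a != "N" & b != "N"
  match[ref_bases]
}

#' Scan alignment blocks for evolutionarily conserved regions
#'
#' @param blocks an alignment-block tibble (>= 2 rows per block; the first
#'   row of each block is the reference).
#' @param min_length window length in reference bases (default 100).
#' @param min_identity minimum window match fraction (default 0.70).
#' @return a tibble of merged ECRs: `block_id`, `other_species`, `chrom`,
#'   `start`, `end` (reference genome coordinates, `src_start` applied),
#'   `identity` (percent, recomputed over the merged interval — it may fall
#'   below the window threshold), `n_windows` (qualifying windows merged).
#'   Non-reference rows are scanned independently against the reference.
#' @export
scan_ecrs <- function(blocks, min_length = 100L, min_identity = 0.70) {
  validate_maf_blocks(blocks)
  if (min_length < 1L) abort("`min_length` must be >= 1")
  assert_scalar_number(min_identity, "min_identity", 0, 1)
  out <- list()
  for (b in unique(blocks$block_id)) {
    rows <- blocks[blocks$block_id == b, , drop = FALSE]
    if (nrow(rows) < 2L) abort(sprintf("block %s has fewer than 2 rows", b))
    for (j in 2:nrow(rows)) {
      flags <- column_identity(blocks, b, 1L, j)
      n <- length(flags)
      if (n < min_length) next
      w <- min_length
      cs <- cumsum(c(0L, as.integer(flags)))
      wins <- cs[(w + 1L):(n + 1L)] - cs[1:(n - w + 1L)]  # matches per window
      qual <- which(wins >= min_identity * w - 1e-9)
      if (length(qual) == 0L) next
      merged <- merge_intervals(qual - 1L, qual - 1L + w)
      for (m in seq_len(nrow(merged))) {
        s <- merged$start[m]
        e <- merged$end[m]
        ident <- 100 * (cs[e + 1L] - cs[s + 1L]) / (e - s)
        nw <- sum(qual - 1L >= s & qual - 1L + w <= e)
        out[[length(out) + 1L]] <- tibble::tibble(
          block_id = b,
          other_species = rows$species[j],
          chrom = rows$src_chrom[1],
          start = rows$src_start[1] + s,
          end = rows$src_start[1] + e,
          identity = ident,
          n_windows = nw
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(block_id = integer(), other_species = character(),
                          chrom = character(), start = integer(), end = integer(),
                          identity = numeric(), n_windows = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$block_id, .data$other_species,
                 .data$start)
}

#' Write ECRs as BED6
#'
#' Name is the other species, score is `round(identity x 10)`.
#'
#' @param ecrs output of [scan_ecrs()].
#' @inheritParams write_bed12
#' @export
write_ecr_bed <- function(ecrs, path = NULL, header = !is.null(path)) {
  el <- element_tbl(chrom = ecrs$chrom, start = ecrs$start, end = ecrs$end,
                    name = ecrs$other_species,
                    score = pmin(1000L, pmax(1L, as.integer(round_half_up(ecrs$identity * 10)))),
                    strand = "+")
  write_bed6(el, path, header)
}
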