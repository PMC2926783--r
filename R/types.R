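# Tabular domain containers. Every container is an ordinary tibble so that the
# whole toolkit composes with dplyr; constructors only validate invariants.

#' Build a transcript table
#'
#' The central annotation container: one row per transcript, with the exon
#' block structure held in a list-column of `start`/`end` tibbles (0-based
#' half-open genome coordinates, BED12 semantics). The transcription start
#' site is the strand-aware 5' end: `start` on `+`, `end - 1` on `-`.
#'
#' @param tx_id character vector of transcript identifiers.
#' @param chrom chromosome names.
#' @param start,end locus bounds, 0-based half-open.
#' @param strand one of `"+"`, `"-"`, `"."` per transcript.
#' @param exons list of tibbles with integer columns `start`, `end`; exons
#'   must be disjoint, sorted, the first starting at `start` and the last
#'   ending at `end`.
#' @param biotype `"lncRNA"`, `"coding"` or `"other"`.
#' @return a tibble with columns `tx_id`, `chrom`, `start`, `end`, `strand`,
#'   `biotype`, `exons`.
#' @examples
#' transcript_tbl("tx1", "chr1", 100L, 300L, "+",
#'                list(tibble::tibble(start = c(100L, 150L), end = c(110L, 300L))))
#' @export
transcript_tbl <- function(tx_id, chrom, start, end, strand = "+",
                           exons = NULL, biotype = "lncRNA") {
  n <- length(tx_id)
  if (is.null(exons)) {
    exons <- purrr::map2(start, end, ~ tibble::tibble(start = as.integer(.x),
                                                      end = as.integer(.y)))
  }
  out <- tibble::tibble(
    tx_id = as.character(tx_id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    biotype = rep_len(as.character(biotype), n),
    exons = exons
  )
  validate_transcripts(out)
}

#' Validate a transcript table's invariants
#'
#' @param tx a tibble as produced by [transcript_tbl()] or [parse_bed12()].
#' @return `tx`, invisibly unchanged, or an error naming the first offending
#'   transcript.
#' @export
validate_transcripts <- function(tx) {
  required <- c("tx_id", "chrom", "start", "end", "strand", "biotype", "exons")
  missing <- setdiff(required, names(tx))
  if (length(missing) > 0) {
    abort(paste0("transcript table lacks columns: ", paste(missing, collapse = ", ")))
  }
  for (i in seq_len(nrow(tx))) {
    id <- tx$tx_id[i]
    if (!nzchar(tx$chrom[i])) abort(sprintf("transcript '%s': empty chrom", id))
    if (!(tx$start[i] >= 0 && tx$start[i] < tx$end[i])) {
      abort(sprintf("transcript '%s': need 0 <= start < end", id))
    }
    if (!tx$strand[i] %in% c("+", "-", ".")) {
      abort(sprintf("transcript '%s': bad strand '%s'", id, tx$strand[i]))
    }
    ex <- tx$exons[[i]]
    if (nrow(ex) < 1L) abort(sprintf("transcript '%s': needs >= 1 exon", id))
    if (any(ex$start >= ex$end)) abort(sprintf("transcript '%s': empty exon", id))
    if (is.unsorted(ex$start, strictly = TRUE) ||
        any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(sprintf("transcript '%s': exons must be sorted and non-overlapping", id))
    }
    if (ex$start[1] != tx$start[i] || ex$end[nrow(ex)] != tx$end[i]) {
      abort(sprintf("transcript '%s': exon span must equal locus bounds", id))
    }
  }
  tx
}

#' Build a conserved-element table
#'
#' Discrete conserved elements (phastCons-style most-conserved track rows):
#' BED6 semantics with an integer log-odds score in \[1, 1000\].
#'
#' @param chrom,start,end interval coordinates (0-based half-open).
#' @param name element names (recycled).
#' @param score integer log-odds scores in \[1, 1000\].
#' @param strand strand (recycled; elements are unstranded in practice).
#' @return a tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
element_tbl <- function(chrom, start, end, name = "el", score = 500L,
                        strand = ".") {
  n <- length(start)
  out <- tibble::tibble(
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    end = as.integer(end),
    name = rep_len(as.character(name), n),
    score = rep_len(as.integer(score), n),
    strand = rep_len(as.character(strand), n)
  )
  if (any(out$start >= out$end)) abort("element with start >= end")
  bad <- which(out$score < 1L | out$score > 1000L)
  if (length(bad) > 0) {
    abort(sprintf("element %d: score %d outside [1, 1000]", bad[1], out$score[bad[1]]))
  }
  out
}

#' Build a per-base conservation score track
#'
#' Run-length representation of a per-base track (bedGraph semantics): every
#' base in `[start, end)` carries `score`; bases not covered by any row are
#' undefined (phastCons tracks legitimately omit unalignable sequence).
#' Scores must lie in \[0, 1\] (posterior-probability scale).
#'
#' @param chrom,start,end run coordinates, 0-based half-open, non-overlapping
#'   per chromosome.
#' @param score numeric scores in \[0, 1\].
#' @return a tibble with columns `chrom`, `start`, `end`, `score`, sorted by
#'   chrom and start.
#' @export
score_track <- function(chrom, start, end, score) {
  out <- tibble::tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    score = as.numeric(score)
  )
  if (any(out$start >= out$end)) abort("track row with start >= end")
  bad <- which(out$score < 0 | out$score > 1)
  if (length(bad) > 0) {
    abort(sprintf("track row %d: score %g outside [0, 1]", bad[1], out$score[bad[1]]))
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  split_rows <- split(seq_len(nrow(out)), out$chrom)
  for (idx in split_rows) {
    if (length(idx) > 1L) {
      s <- out$start[idx]
      e <- out$end[idx]
      ov <- which(s[-1] < e[-length(e)])
      if (length(ov) > 0) {
        abort(sprintf("overlapping track rows on %s near position %d",
                      out$chrom[idx[1]], s[ov[1] + 1L]))
      }
    }
  }
  out
}

#' Pre-index a score track for repeated lookups
#'
#' Splits the run table into per-chromosome sorted vectors so that repeated
#' [track_scores()] calls (thousands per metagene build) skip the tibble
#' subsetting cost. Any function taking a track also accepts the index.
#'
#' @param track a tibble from [score_track()] / [parse_bedgraph()].
#' @return an object of class `score_track_index`.
#' @export
track_index <- function(track) {
  if (inherits(track, "score_track_index")) return(track)
  by_chrom <- split(seq_len(nrow(track)), track$chrom)
  idx <- lapply(by_chrom, function(i) {
    # doubles up front: findInterval would otherwise coerce on every call
    list(start = as.numeric(track$start[i]), end = as.numeric(track$end[i]),
         score = track$score[i])
  })
  structure(idx, class = "score_track_index")
}

#' Look up per-base scores in a track
#'
#' @param track a tibble from [score_track()] / [parse_bedgraph()], or a
#'   [track_index()].
#' @param chrom a single chromosome name.
#' @param pos integer vector of 0-based positions.
#' @return numeric vector of scores, `NA` where the track is undefined.
#' @export
track_scores <- function(track, chrom, pos) {
  sub <- if (inherits(track, "score_track_index")) track[[chrom]]
         else track_index(track)[[chrom]]
  out <- rep(NA_real_, length(pos))
  if (is.null(sub) || length(sub$start) == 0L || length(pos) == 0L) return(out)
  idx <- findInterval(pos, sub$start)
  hit <- idx >= 1L & pos < sub$end[pmax(idx, 1L)]
  out[hit] <- sub$score[idx[hit]]
  out
}

#' Build a cDNA sequence table
#'
#' @param id sequence identifiers.
#' @param seq nucleotide strings; lower case is accepted and normalised to
#'   upper case, `U` is normalised to `T`.
#' @param desc free-text descriptions.
#' @return a tibble with columns `id`, `seq`, `desc`.
#' @export
cdna_tbl <- function(id, seq, desc = "") {
  seq <- toupper(as.character(seq))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  n <- length(id)
  out <- tibble::tibble(id = as.character(id), seq = seq,
                        desc = rep_len(as.character(desc), n))
  for (i in seq_len(nrow(out))) {
    if (nchar(out$seq[i]) < 1L) abort(sprintf("record '%s': empty sequence", out$id[i]))
    bad <- regexpr("[^ACGTN]", out$seq[i])
    if (bad > 0) {
      abort(sprintf("record '%s': illegal character '%s' at position %d",
                    out$id[i], substr(out$seq[i], bad, bad), bad))
    }
  }
  out
}

#' Validate an alignment-block table
#'
#' Alignment blocks follow MAF semantics: one row per aligned sequence, rows
#' grouped by `block_id`, the first row of each block being the reference.
#' `src_start` is 0-based in the source sequence (counted from the start of
#' the reverse-complemented source for `-` strand rows).
#'
#' @param blocks a tibble with columns `block_id`, `species`, `src_chrom`,
#'   `src_start`, `src_size`, `strand`, `src_length`, `text`.
#' @return `blocks` invisibly, or an error naming the offending block.
#' @export
validate_maf_blocks <- function(blocks) {
  required <- c("block_id", "species", "src_chrom", "src_start", "src_size",
                "strand", "src_length", "text")
  missing <- setdiff(required, names(blocks))
  if (length(missing) > 0) {
    abort(paste0("alignment table lacks columns: ", paste(missing, collapse = ", ")))
  }
  for (b in unique(blocks$block_id)) {
    rows <- blocks[blocks$block_id == b, , drop = FALSE]
    widths <- nchar(rows$text)
    if (length(unique(widths)) != 1L) {
      abort(sprintf("block %s: row texts differ in length", b))
    }
    ungapped <- nchar(gsub("-", "", rows$text, fixed = TRUE))
    bad <- which(ungapped != rows$src_size)
    if (length(bad) > 0) {
      abort(sprintf("block %s, row '%s': src_size %d but %d non-gap characters",
                    b, rows$species[bad[1]], rows$src_size[bad[1]], ungapped[bad[1]]))
    }
    over <- which(rows$src_start + rows$src_size > rows$src_length)
    if (length(over) > 0) {
      abort(sprintf("block %s, row '%s': interval exceeds source length",
                    b, rows$species[over[1]]))
    }
  }
  blocks
}
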