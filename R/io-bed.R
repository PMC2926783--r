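# BED readers/writers. BED is the single annotation dialect in this package:
# transcript models are BED12, conserved elements and ECRs are BED6. Parsers
# reject invalid input outright, naming the offending line.

strip_comment_lines <- function(lines) {
  keep <- !grepl("^\\s*(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Parse BED12 transcript models
#'
#' @param lines character vector of BED12 lines (tab- or space-separated), or
#'   use [read_bed12()] for a file.
#' @param biotype biotype assigned to every parsed transcript.
#' @return a transcript tibble (see [transcript_tbl()]). `thickStart` and
#'   `thickEnd` are ignored; exons are reconstructed from
#'   `chromStart + blockStarts[i] .. + blockSizes[i]`.
#' @examples
#' parse_bed12("chr1\t100\t300\ttx1\t0\t+\t100\t300\t0\t2\t10,20\t0,50")
#' @export
parse_bed12 <- function(lines, biotype = "lncRNA") {
  kept <- strip_comment_lines(lines)
  if (length(kept$lines) == 0L) {
    return(transcript_tbl(character(), character(), integer(), integer(),
                          character(), list(), character()))
  }
  recs <- vector("list", length(kept$lines))
  for (i in seq_along(kept$lines)) {
    ln <- kept$lineno[i]
    f <- strsplit(trimws(kept$lines[i]), "[\t ]+")[[1]]
    if (length(f) < 12L) {
      abort(sprintf("line %d: BED12 needs >= 12 fields, found %d", ln, length(f)))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    n_blocks <- suppressWarnings(as.integer(f[10]))
    if (anyNA(c(start, end, n_blocks))) {
      abort(sprintf("line %d: non-integer coordinate or blockCount", ln))
    }
    sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
    offs <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
    if (length(sizes) != n_blocks || length(offs) != n_blocks || anyNA(sizes) || anyNA(offs)) {
      abort(sprintf("line %d: blockSizes/blockStarts must be %d comma-separated integers",
                    ln, n_blocks))
    }
    if (offs[1] != 0L) {
      abort(sprintf("line %d: blockStarts[1] must be 0, found %d", ln, offs[1]))
    }
    ex_start <- start + offs
    ex_end <- ex_start + sizes
    if (any(ex_end > end)) {
      abort(sprintf("line %d: block extends past chromEnd", ln))
    }
    # the locus interval is the exon span; a chromEnd beyond the last block
    # is tolerated on input but not preserved
    recs[[i]] <- list(tx_id = f[4], chrom = f[1], start = start,
                      end = ex_end[n_blocks], strand = f[6],
                      exons = tibble::tibble(start = ex_start, end = ex_end))
  }
  transcript_tbl(
    tx_id = purrr::map_chr(recs, "tx_id"),
    chrom = purrr::map_chr(recs, "chrom"),
    start = purrr::map_int(recs, "start"),
    end = purrr::map_int(recs, "end"),
    strand = purrr::map_chr(recs, "strand"),
    exons = purrr::map(recs, "exons"),
    biotype = biotype
  )
}

#' @rdname parse_bed12
#' @param path path to a BED12 file.
#' @export
read_bed12 <- function(path, biotype = "lncRNA") {
  parse_bed12(readLines(path), biotype = biotype)
}

#' Write transcript models as BED12
#'
#' @param tx a transcript tibble.
#' @param path output path, or `NULL` to return the lines.
#' @param header logical: emit the commented tool header line.
#' @return the lines invisibly (or visibly when `path` is `NULL`).
#' @export
write_bed12 <- function(tx, path = NULL, header = !is.null(path)) {
  lines <- purrr::map_chr(seq_len(nrow(tx)), function(i) {
    ex <- tx$exons[[i]]
    paste(tx$chrom[i], tx$start[i], tx$end[i], tx$tx_id[i], 0L, tx$strand[i],
          tx$start[i], tx$end[i], 0L, nrow(ex),
          paste0(paste(ex$end - ex$start, collapse = ","), ","),
          paste0(paste(ex$start - tx$start[i], collapse = ","), ","),
          sep = "\t")
  })
  if (header) lines <- c(tool_header(), lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse BED6 intervals (conserved elements, ECR ground truth)
#'
#' @param lines character vector of BED lines with >= 4 fields (name/score/
#'   strand defaulted when absent).
#' @param score_range integer bounds enforced on the score column.
#' @return an element tibble (see [element_tbl()]).
#' @export
parse_bed6 <- function(lines, score_range = c(1L, 1000L)) {
  kept <- strip_comment_lines(lines)
  if (length(kept$lines) == 0L) {
    return(element_tbl(character(), integer(), integer()))
  }
  f <- strsplit(trimws(kept$lines), "[\t ]+")
  n <- lengths(f)
  if (any(n < 3L)) {
    abort(sprintf("line %d: BED needs >= 3 fields", kept$lineno[which(n < 3L)[1]]))
  }
  get <- function(k, default) {
    purrr::map_chr(f, ~ if (length(.x) >= k) .x[k] else default)
  }
  start <- suppressWarnings(as.integer(get(2, NA)))
  end <- suppressWarnings(as.integer(get(3, NA)))
  bad <- which(is.na(start) | is.na(end) | start >= end)
  if (length(bad) > 0) {
    abort(sprintf("line %d: bad interval coordinates", kept$lineno[bad[1]]))
  }
  score <- suppressWarnings(as.integer(get(5, "500")))
  score[is.na(score)] <- 500L
  score <- pmin(pmax(score, score_range[1]), score_range[2])
  element_tbl(chrom = get(1, NA), start = start, end = end,
              name = get(4, "el"), score = score, strand = get(6, "."))
}

#' @rdname parse_bed6
#' @param path path to a BED file.
#' @export
read_bed6 <- function(path, score_range = c(1L, 1000L)) {
  parse_bed6(readLines(path), score_range = score_range)
}

#' Write BED6 intervals
#'
#' @param elements an element tibble.
#' @inheritParams write_bed12
#' @export
write_bed6 <- function(elements, path = NULL, header = !is.null(path)) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", elements$chrom, elements$start,
                   elements$end, elements$name, elements$score, elements$strand)
  if (header) lines <- c(tool_header(), lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
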