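# bedGraph is the single internal score-track representation; fixed-step
# wiggle is accepted through a pre-conversion utility.

#' Parse a bedGraph conservation track
#'
#' Lines are `chrom start end value` (0-based half-open, non-overlapping);
#' every base in `[start, end)` receives `value`. Values outside \[0, 1\]
#' are an error, not clamped: the track carries phastCons-style posterior
#' probabilities.
#'
#' @param lines character vector of bedGraph lines.
#' @return a score-track tibble (see [score_track()]).
#' @export
parse_bedgraph <- function(lines) {
  kept <- strip_comment_lines(lines)
  if (length(kept$lines) == 0L) {
    return(score_track(character(), integer(), integer(), numeric()))
  }
  f <- strsplit(trimws(kept$lines), "[\t ]+")
  n <- lengths(f)
  if (any(n < 4L)) {
    abort(sprintf("line %d: bedGraph needs 4 fields", kept$lineno[which(n < 4L)[1]]))
  }
  chrom <- purrr::map_chr(f, 1)
  start <- suppressWarnings(as.integer(purrr::map_chr(f, 2)))
  end <- suppressWarnings(as.integer(purrr::map_chr(f, 3)))
  value <- suppressWarnings(as.numeric(purrr::map_chr(f, 4)))
  bad <- which(is.na(start) | is.na(end) | is.na(value))
  if (length(bad) > 0) {
    abort(sprintf("line %d: malformed bedGraph fields", kept$lineno[bad[1]]))
  }
  out_of_range <- which(value < 0 | value > 1)
  if (length(out_of_range) > 0) {
    abort(sprintf("line %d: value %g outside [0, 1]",
                  kept$lineno[out_of_range[1]], value[out_of_range[1]]))
  }
  score_track(chrom, start, end, value)
}

#' @rdname parse_bedgraph
#' @param path path to a bedGraph file.
#' @export
read_bedgraph <- function(path) parse_bedgraph(readLines(path))

#' Write a score track as bedGraph
#'
#' Adjacent equal-valued runs are compacted before writing.
#'
#' @param track a score-track tibble.
#' @inheritParams write_bed12
#' @export
write_bedgraph <- function(track, path = NULL, header = !is.null(path)) {
  track <- compact_track(track)
  lines <- sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                   formatC(track$score, format = "g", digits = 15))
  if (header) lines <- c(tool_header(), lines)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# Fuse abutting runs with identical scores.
compact_track <- function(track) {
  if (nrow(track) < 2L) return(track)
  track <- dplyr::arrange(track, .data$chrom, .data$start)
  new_run <- c(TRUE, track$chrom[-1] != track$chrom[-nrow(track)] |
                 track$start[-1] != track$end[-nrow(track)] |
                 track$score[-1] != track$score[-nrow(track)])
  grp <- cumsum(new_run)
  dplyr::summarise(dplyr::group_by(track, grp = grp),
                   chrom = dplyr::first(.data$chrom),
                   start = dplyr::first(.data$start),
                   end = dplyr::last(.data$end),
                   score = dplyr::first(.data$score),
                   .groups = "drop")[, c("chrom", "start", "end", "score")]
}

#' Convert fixed-step wiggle lines to bedGraph lines
#'
#' Supports `fixedStep chrom=... start=... step=... [span=...]` paragraphs;
#' wiggle `start` is 1-based, the output is 0-based half-open.
#'
#' @param lines character vector of fixedStep wiggle lines.
#' @return character vector of bedGraph lines, parseable by
#'   [parse_bedgraph()].
#' @export
wig_to_bedgraph <- function(lines) {
  out <- character(0)
  chrom <- NULL
  pos <- NA_integer_
  step <- 1L
  span <- 1L
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#") || startsWith(ln, "track")) next
    if (startsWith(ln, "fixedStep")) {
      kv <- strsplit(strsplit(ln, "\\s+")[[1]][-1], "=")
      vals <- setNames(purrr::map_chr(kv, 2), purrr::map_chr(kv, 1))
      getv <- function(nm, default) if (nm %in% names(vals)) vals[[nm]] else default
      chrom <- getv("chrom", NA_character_)
      pos <- as.integer(getv("start", NA)) - 1L
      step <- as.integer(getv("step", "1"))
      span <- as.integer(getv("span", "1"))
      next
    }
    if (is.null(chrom)) abort(sprintf("line %d: data before fixedStep header", i))
    out <- c(out, sprintf("%s\t%d\t%d\t%s", chrom, pos, pos + span, ln))
    pos <- pos + step
  }
  out
}
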