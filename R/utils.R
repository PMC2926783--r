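# Internal helpers shared across modules. Coordinates are 0-based half-open
# everywhere inside the package; 1-based coordinates appear only in
# human-readable report columns.

round_half_up <- function(x) floor(x + 0.5)

#' Merge possibly-overlapping half-open intervals into a disjoint sorted union
#'
#' @param start,end integer vectors of equal length (0-based half-open).
#' @return a tibble with columns `start`, `end`, disjoint and sorted.
#' @keywords internal
#' @noRd
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- integer(0)
  out_e <- integer(0)
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms)
        out_e <- c(out_e, me)
        ms <- start[i]
        me <- end[i]
      }
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Total overlap (in bases) between a disjoint interval set and one interval.
overlap_bases <- function(merged, qs, qe) {
  if (nrow(merged) == 0L) return(0L)
  s <- pmax(merged$start, qs)
  e <- pmin(merged$end, qe)
  sum(pmax(0L, e - s))
}

# Gap between two half-open intervals; 0 if they touch or overlap.
interval_gap <- function(s1, e1, s2, e2) {
  pmax(0L, pmax(s1 - e2, s2 - e1))
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lo, hi))
  }
  invisible(x)
}

write_tsv_report <- function(df, path, header = tool_header(), extra = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, extra), con)
  cat(readr::format_tsv(df), file = con)
  invisible(path)
}

read_tsv_report <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types %||% readr::cols(),
                  progress = FALSE)
}
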