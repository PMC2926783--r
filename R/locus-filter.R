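# lncRNA selection filters and conserved-element overlap statistics.
# Two independent removal rules: (i) any lncRNA exon overlapping any coding
# exon; (ii) locus-to-locus gap to the nearest coding gene below
# min_distance (default 5000 bp, strict inequality: a gap of exactly
# 5000 bp is kept). Proximity is strand-ignored.

#' Filter lncRNA transcripts against protein-coding annotation
#'
#' @param lncrna,coding transcript tibbles on the same assembly.
#' @param min_distance bp; transcripts whose locus gap to the nearest coding
#'   locus is strictly below this are removed (default 5000).
#' @return a tibble with one row per lncRNA: `tx_id`, `kept`, `reason`
#'   (`kept`, `overlaps_coding` or `within_proximity`; exon overlap takes
#'   precedence) and `nearest_coding_distance` (bp, `NA` when no coding gene
#'   shares the chromosome).
#' @export
filter_noncoding <- function(lncrna, coding, min_distance = 5000L) {
  validate_transcripts(lncrna)
  validate_transcripts(coding)
  if (min_distance < 0) abort("`min_distance` must be >= 0")
  out <- annotation_truth(lncrna, coding, min_distance)
  tibble::tibble(
    tx_id = out$tx_id,
    kept = out$class == "kept",
    reason = out$class,
    nearest_coding_distance = out$nearest_coding_distance
  )
}

#' Conserved-element overlap fractions per transcript
#'
#' Elements are unioned before counting, so duplicated or overlapping
#' elements are never double-counted. `exonic_fraction` is the unioned
#' element overlap with exons over total exonic bases; `genic_fraction` is
#' the overlap with the whole locus (exons plus introns) over locus length.
#'
#' @param tx a transcript tibble (one or more transcripts).
#' @param elements an element tibble.
#' @return a tibble with columns `tx_id`, `exonic_fraction`,
#'   `genic_fraction`, `has_constrained`.
#' @export
overlap_fraction <- function(tx, elements) {
  validate_transcripts(tx)
  purrr::map_dfr(seq_len(nrow(tx)), function(i) {
    el <- elements[elements$chrom == tx$chrom[i], , drop = FALSE]
    merged <- merge_intervals(el$start, el$end)
    ex <- tx$exons[[i]]
    exonic_total <- sum(ex$end - ex$start)
    exonic_hit <- sum(purrr::map2_int(ex$start, ex$end,
                                      ~ as.integer(overlap_bases(merged, .x, .y))))
    genic_hit <- overlap_bases(merged, tx$start[i], tx$end[i])
    tibble::tibble(
      tx_id = tx$tx_id[i],
      exonic_fraction = exonic_hit / exonic_total,
      genic_fraction = genic_hit / (tx$end[i] - tx$start[i]),
      has_constrained = genic_hit > 0
    )
  })
}

#' Cohort summary of conserved-element overlap
#'
#' @param summaries output of [overlap_fraction()] over a cohort.
#' @return a one-row tibble: `n`, `n_constrained`, `pct_constrained`,
#'   `mean_exonic_fraction`, `mean_genic_fraction`.
#' @export
summarize_overlap <- function(summaries) {
  if (nrow(summaries) == 0L) abort("no overlap summaries to aggregate")
  tibble::tibble(
    n = nrow(summaries),
    n_constrained = sum(summaries$has_constrained),
    pct_constrained = 100 * mean(summaries$has_constrained),
    mean_exonic_fraction = mean(summaries$exonic_fraction),
    mean_genic_fraction = mean(summaries$genic_fraction)
  )
}

#' Histogram of per-transcript element overlap
#'
#' Bins `genic_fraction` into fixed-width bins (default 2 percentage
#' points), the shape of the per-transcript overlap histogram.
#'
#' @param summaries output of [overlap_fraction()].
#' @param binwidth bin width on the fraction scale (default 0.02).
#' @return a tibble with `bin_start`, `bin_end` (fractions) and `count`.
#' @export
overlap_histogram <- function(summaries, binwidth = 0.02) {
  if (nrow(summaries) == 0L) abort("no overlap summaries to bin")
  breaks <- seq(0, 1 + binwidth, by = binwidth)
  bin <- pmin(findInterval(summaries$genic_fraction, breaks,
                           rightmost.closed = FALSE), length(breaks) - 1L)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  keep <- seq_len(max(bin))
  tibble::tibble(
    bin_start = breaks[keep],
    bin_end = breaks[keep + 1L],
    count = counts[keep]
  )
}

#' Plot the per-transcript element-overlap histogram
#'
#' @param summaries output of [overlap_fraction()].
#' @param binwidth bin width on the fraction scale.
#' @return a ggplot object.
#' @export
plot_overlap_histogram <- function(summaries, binwidth = 0.02) {
  h <- overlap_histogram(summaries, binwidth)
  ggplot2::ggplot(h, ggplot2::aes(x = 100 * (.data$bin_start + .data$bin_end) / 2,
                                  y = .data$count)) +
    ggplot2::geom_col(width = 100 * binwidth * 0.9, fill = "grey30") +
    ggplot2::labs(x = "% of transcript overlapping conserved elements",
                  y = "transcripts") +
    ggplot2::theme_minimal()
}
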