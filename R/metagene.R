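# Generic-locus ("metagene") conservation profile: every multi-exon locus is
# partitioned into six strand-aware regions, each region rescaled to a fixed
# number of sample slots, and per-slot scores averaged across loci with each
# locus contributing once per slot regardless of its length.

#' Region schema for the metagene profile
#'
#' @param regions ordered region names. The default six-region partition is
#'   upstream flank, first exon, introns, middle exons, last exon,
#'   downstream flank (transcriptional order).
#' @param samples_per_region number of sample slots per region (>= 2).
#' @param flank_length bp of upstream/downstream flank; the default 200
#'   matches the putative core promoter definition (200 bp upstream of the
#'   TSS).
#' @return a list of class `region_schema`.
#' @export
region_schema <- function(regions = c("upstream200", "first_exon", "introns",
                                      "middle_exons", "last_exon", "downstream200"),
                          samples_per_region = 200L, flank_length = 200L) {
  if (samples_per_region < 2L) abort("`samples_per_region` must be >= 2")
  if (anyDuplicated(regions)) abort("region names must be unique")
  structure(list(regions = regions,
                 samples_per_region = as.integer(samples_per_region),
                 flank_length = as.integer(flank_length)),
            class = "region_schema")
}

#' Partition a multi-exon locus into metagene regions
#'
#' Strand-aware: the upstream flank covers `flank_length` bases 5' of the
#' TSS, first/middle/last exons are taken in transcriptional order, introns
#' are the gaps between consecutive exons, and the downstream flank follows
#' the 3' end. Output rows are ordered 5' to 3' within each region; a
#' `feature` index separates individual introns / middle exons.
#'
#' @param tx a one-row transcript tibble with >= 2 exons.
#' @param schema a [region_schema()].
#' @return a tibble with columns `region`, `feature`, `chrom`, `start`,
#'   `end`, `strand`. `middle_exons` may be absent (two-exon loci).
#' @export
partition_locus <- function(tx, schema = region_schema()) {
  stopifnot(nrow(tx) == 1L)
  validate_transcripts(tx)
  ex <- tx$exons[[1]]
  if (nrow(ex) < 2L) {
    abort(sprintf("transcript '%s' is single-exon; the metagene cohort is multi-exon",
                  tx$tx_id))
  }
  minus <- tx$strand == "-"
  fl <- schema$flank_length
  ex_tx_order <- if (minus) ex[rev(seq_len(nrow(ex))), ] else ex
  introns <- tibble::tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
  if (minus) introns <- introns[rev(seq_len(nrow(introns))), ]
  upstream <- if (minus) tibble::tibble(start = tx$end, end = tx$end + fl)
              else tibble::tibble(start = tx$start - fl, end = tx$start)
  downstream <- if (minus) tibble::tibble(start = tx$start - fl, end = tx$start)
                else tibble::tibble(start = tx$end, end = tx$end + fl)
  n_ex <- nrow(ex_tx_order)
  mk <- function(region, df) {
    if (nrow(df) == 0L) return(NULL)
    tibble::tibble(region = region, feature = seq_len(nrow(df)),
                   chrom = tx$chrom, start = df$start, end = df$end,
                   strand = tx$strand)
  }
  dplyr::bind_rows(
    mk("upstream200", upstream),
    mk("first_exon", ex_tx_order[1, c("start", "end")]),
    mk("introns", introns),
    mk("middle_exons", if (n_ex > 2L) ex_tx_order[2:(n_ex - 1L), c("start", "end")]
                       else ex_tx_order[0, c("start", "end")]),
    mk("last_exon", ex_tx_order[n_ex, c("start", "end")]),
    mk("downstream200", downstream)
  )
}

# Transcription-ordered genomic positions of an interval set (rows already
# ordered 5'->3'; within an interval, minus strand walks right to left).
tx_order_positions <- function(start, end, strand) {
  pos <- purrr::map2(start, end, function(s, e) {
    p <- seq.int(s, e - 1L)
    if (strand == "-") rev(p) else p
  })
  unlist(pos)
}

#' Sample a region's scores onto evenly spaced slots
#'
#' With `L` concatenated bases and `k` slots: when `L >= k`, slot `i` holds
#' the score of base `round(i * (L-1) / (k-1))` (half-up rounding); when
#' `L < k`, every base is assigned to slot `round(p * (k-1) / (L-1))` and
#' unassigned slots stay missing, so short regions are sampled entirely and
#' never interpolated. Track-undefined positions are missing.
#'
#' @param track a score-track tibble.
#' @param intervals a tibble with `chrom`, `start`, `end`, `strand` rows
#'   ordered 5' to 3' (e.g. one region of [partition_locus()]).
#' @param k number of slots (>= 2).
#' @return numeric vector of length `k`, `NA` for empty slots.
#' @export
sample_region <- function(track, intervals, k = 200L) {
  if (k < 2L) abort("`k` must be >= 2")
  out <- rep(NA_real_, k)
  if (nrow(intervals) == 0L) return(out)
  strand <- intervals$strand[1]
  chrom <- intervals$chrom[1]
  pos <- tx_order_positions(intervals$start, intervals$end, strand)
  L <- length(pos)
  if (L == 0L) return(out)
  if (L >= k) {
    idx <- round_half_up((seq_len(k) - 1L) * (L - 1) / (k - 1)) + 1L
    out <- track_scores(track, chrom, pos[idx])
  } else if (L == 1L) {
    out[1L] <- track_scores(track, chrom, pos)
  } else {
    slots <- round_half_up((seq_len(L) - 1L) * (k - 1) / (L - 1)) + 1L
    vals <- track_scores(track, chrom, pos)
    for (s in unique(slots)) {
      v <- vals[slots == s]
      out[s] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }
  }
  out
}

#' Build the metagene conservation profile of a cohort
#'
#' Per slot, the mean over all contributing loci of that slot's sampled
#' score; a locus contributes once per slot regardless of its length, and
#' loci lacking a region (e.g. no middle exons) contribute nothing to it.
#' Within a locus the `introns` and `middle_exons` regions are rescaled per
#' feature and averaged, so a long intron does not dominate its locus'
#' intron profile. Single-exon transcripts are excluded.
#'
#' @param txs a transcript tibble.
#' @param track a score-track tibble.
#' @param schema a [region_schema()].
#' @return a `metagene_profile`: a tibble with columns `region`, `slot`
#'   (0-based), `mean`, `count`, with the schema and cohort size attached as
#'   attributes.
#' @export
build_metagene <- function(txs, track, schema = region_schema()) {
  validate_transcripts(txs)
  eligible <- which(purrr::map_int(txs$exons, nrow) >= 2L)
  if (length(eligible) == 0L) abort("no multi-exon transcripts in the cohort")
  track <- track_index(track)
  k <- schema$samples_per_region
  sums <- counts <- matrix(0, nrow = length(schema$regions), ncol = k,
                           dimnames = list(schema$regions, NULL))
  per_feature <- c("introns", "middle_exons")
  for (i in eligible) {
    parts <- partition_locus(txs[i, ], schema)
    for (r in schema$regions) {
      rows <- parts[parts$region == r, , drop = FALSE]
      if (nrow(rows) == 0L) next
      if (r %in% per_feature) {
        mat <- vapply(split(rows, rows$feature),
                      function(df) sample_region(track, df, k), numeric(k))
        v <- rowMeans(mat, na.rm = TRUE)
        v[is.nan(v)] <- NA_real_
      } else {
        v <- sample_region(track, rows, k)
      }
      ok <- !is.na(v)
      sums[r, ok] <- sums[r, ok] + v[ok]
      counts[r, ok] <- counts[r, ok] + 1
    }
  }
  out <- tidyr::expand_grid(region = schema$regions, slot = 0:(k - 1L))
  out$count <- as.integer(t(counts))[seq_len(nrow(out))]
  means <- t(sums) / t(counts)
  out$mean <- as.numeric(means)[seq_len(nrow(out))]
  out$mean[out$count == 0L] <- NA_real_
  out <- out[, c("region", "slot", "mean", "count")]
  structure(tibble::as_tibble(out), class = c("metagene_profile", class(out)),
            schema = schema, n_loci = length(eligible))
}

# Regions anchored at their 3' boundary (the TSS for the upstream flank).
end_anchored_regions <- function(schema) schema$regions[1]

#' Call the conservation peak of a profile region
#'
#' Argmax over defined slots; ties resolve to the slot closest to the
#' region's anchor (the TSS for the upstream flank, the 5' region boundary
#' otherwise). For the fixed-length flank regions the offset is reported in
#' bp relative to the anchor (negative = upstream of the TSS); for
#' locus-scaled regions the length varies per locus, so the offset is the
#' slot index relative to the anchor.
#'
#' @param profile a [build_metagene()] result.
#' @param region region name to scan (default the upstream flank).
#' @return a one-row tibble: `region`, `slot`, `offset_bp`, `height`.
#' @export
call_peak <- function(profile, region = "upstream200") {
  schema <- attr(profile, "schema")
  rows <- profile[profile$region == region, , drop = FALSE]
  if (nrow(rows) == 0L || all(is.na(rows$mean))) {
    abort(sprintf("region '%s' has no defined slots", region))
  }
  k <- schema$samples_per_region
  end_anchored <- region %in% end_anchored_regions(schema)
  best <- max(rows$mean, na.rm = TRUE)
  cand <- rows$slot[!is.na(rows$mean) & rows$mean == best]
  slot <- if (end_anchored) max(cand) else min(cand)
  flank_regions <- c(schema$regions[1], schema$regions[length(schema$regions)])
  if (region %in% flank_regions) {
    L <- schema$flank_length
    vpos <- round_half_up(slot * (L - 1) / (k - 1))
    offset <- if (end_anchored) vpos - L else vpos
  } else {
    offset <- slot
  }
  tibble::tibble(region = region, slot = slot, offset_bp = as.numeric(offset),
                 height = best)
}

#' @method tidy metagene_profile
#' @export
tidy.metagene_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @method glance metagene_profile
#' @export
glance.metagene_profile <- function(x, ...) {
  peak <- call_peak(x, attr(x, "schema")$regions[1])
  tibble::tibble(
    n_loci = attr(x, "n_loci"),
    n_regions = length(attr(x, "schema")$regions),
    samples_per_region = attr(x, "schema")$samples_per_region,
    promoter_peak_offset_bp = peak$offset_bp,
    promoter_peak_height = peak$height
  )
}

#' Plot a metagene conservation profile
#'
#' @param object a [build_metagene()] result.
#' @param ... unused.
#' @return a ggplot object: mean score per slot, one panel strip per region
#'   in transcriptional order.
#' @method autoplot metagene_profile
#' @export
autoplot.metagene_profile <- function(object, ...) {
  schema <- attr(object, "schema")
  df <- tibble::as_tibble(unclass(object))
  df$region <- factor(df$region, levels = schema$regions)
  df$x <- as.integer(df$region) - 1L + df$slot / schema$samples_per_region
  ggplot2::ggplot(df[!is.na(df$mean), ],
                  ggplot2::aes(x = .data$x, y = .data$mean)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_x_continuous(
      breaks = seq_along(schema$regions) - 0.5,
      labels = schema$regions, minor_breaks = seq_along(schema$regions) - 1L) +
    ggplot2::labs(x = NULL, y = "mean conservation score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
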