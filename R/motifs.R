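# Poly(A)-signal and splice-site motif annotation. Patterns are IUPAC
# strings; '|' in a pattern is junction annotation only and is stripped
# before matching (MAG|GTRAG marks the exon|intron boundary of the U2-type
# donor consensus).

IUPAC_CODES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Scan a sequence for an IUPAC pattern
#'
#' All forward-strand occurrences, overlapping allowed, case-insensitive.
#'
#' @param seq a nucleotide string.
#' @param pattern an IUPAC pattern; `|` characters are stripped before
#'   matching.
#' @param motif_name name recorded in the output (defaults to the pattern).
#' @return a tibble of hits: `motif`, `pattern`, `position` (0-based start),
#'   `offset_3p` (bases from the motif's first base to the 3' terminus,
#'   motif inclusive: `length(seq) - position`), `context` (hit sequence
#'   with 5 nt on each side).
#' @examples
#' scan_iupac("CAGGTAAG", "MAG|GTRAG")
#' @export
scan_iupac <- function(seq, pattern, motif_name = pattern) {
  seq <- toupper(seq)
  pat <- toupper(gsub("|", "", pattern, fixed = TRUE))
  pat_chars <- strsplit(pat, "")[[1]]
  bad <- which(!pat_chars %in% names(IUPAC_CODES))
  if (length(bad) > 0) {
    abort(sprintf("illegal IUPAC code '%s' in pattern at position %d",
                  pat_chars[bad[1]], bad[1]))
  }
  n <- nchar(seq)
  m <- length(pat_chars)
  if (m == 0L || n < m) {
    return(tibble::tibble(motif = character(), pattern = character(),
                          position = integer(), offset_3p = integer(),
                          context = character()))
  }
  seq_chars <- strsplit(seq, "")[[1]]
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & seq_chars[seq.int(j, n - m + j)] %in% IUPAC_CODES[[pat_chars[j]]]
  }
  pos0 <- which(ok) - 1L
  if (length(pos0) == 0L) {
    return(tibble::tibble(motif = character(), pattern = character(),
                          position = integer(), offset_3p = integer(),
                          context = character()))
  }
  tibble::tibble(
    motif = rep(motif_name, length(pos0)),
    pattern = rep(pattern, length(pos0)),
    position = pos0,
    offset_3p = n - pos0,
    context = substr(seq, pmax(1L, pos0 + 1L - 5L), pmin(n, pos0 + m + 5L))
  )
}

#' Poly(A) signal nearest the 3' end
#'
#' Scans the given patterns (default the canonical AATAAA hexamer and the
#' ATAAA pentamer variant) and returns the hit whose start is nearest the
#' 3' end; at equal distance the earlier pattern in `patterns` wins.
#' `offset_3p` counts from the motif's first base to the 3' terminus, so an
#' ATAAA with `offset_3p = 30` sits 30 bp upstream of the 3' end.
#'
#' @param cdna a cDNA tibble (or single sequence string).
#' @param patterns character vector of IUPAC patterns in priority order.
#' @return a tibble with one row per input record; records with no signal
#'   get an `NA` position (lncRNA orthologs genuinely lacking a poly(A)
#'   signal are a real outcome, not an error).
#' @export
polya_offset <- function(cdna, patterns = c("AATAAA", "ATAAA")) {
  if (is.character(cdna)) cdna <- cdna_tbl(names(cdna) %||% "seq", cdna)
  purrr::map_dfr(seq_len(nrow(cdna)), function(i) {
    hits <- purrr::imap_dfr(patterns, function(p, rank) {
      h <- scan_iupac(cdna$seq[i], p)
      h$priority <- rank
      h
    })
    if (nrow(hits) == 0L) {
      return(tibble::tibble(id = cdna$id[i], motif = NA_character_,
                            position = NA_integer_, offset_3p = NA_integer_,
                            context = NA_character_))
    }
    best <- dplyr::arrange(hits, dplyr::desc(.data$position), .data$priority)[1, ]
    # a hit contained in a higher-priority pattern's hit is the same signal:
    # report the canonical (higher-priority) form
    len_of <- nchar(gsub("|", "", hits$pattern, fixed = TRUE))
    containing <- hits$priority < best$priority &
      hits$position <= best$position &
      hits$position + len_of >= best$position +
        nchar(gsub("|", "", best$pattern, fixed = TRUE))
    if (any(containing)) {
      best <- dplyr::arrange(hits[containing, ], .data$priority,
                             dplyr::desc(.data$position))[1, ]
    }
    tibble::tibble(id = cdna$id[i], motif = best$motif,
                   position = best$position, offset_3p = best$offset_3p,
                   context = best$context)
  })
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

#' Per-intron splice-site consensus report
#'
#' For every intron of every transcript (strand-aware): the donor and
#' acceptor dinucleotides (first/last 2 intronic bases in transcript
#' orientation), whether the intron is canonical GT..AG, and whether the
#' donor junction (last 3 exonic + first 5 intronic bases) matches the
#' U2-type consensus MAG|GTRAG.
#'
#' @param tx a transcript tibble.
#' @param genome named character vector of chromosome sequences (e.g. from
#'   [sim_genome_seq()] or a read FASTA keyed by chromosome).
#' @return a tibble: `tx_id`, `intron` (1-based, transcript order),
#'   `start`, `end` (genome coordinates), `donor`, `acceptor`, `gt_ag`,
#'   `donor_consensus`, `too_short` (introns < 4 nt are flagged, not
#'   scored).
#' @export
splice_consensus_report <- function(tx, genome) {
  validate_transcripts(tx)
  out <- list()
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    if (nrow(ex) < 2L) next
    g <- genome[[tx$chrom[i]]]
    if (is.null(g)) abort(sprintf("no genome sequence for chromosome '%s'", tx$chrom[i]))
    minus <- tx$strand[i] == "-"
    introns <- tibble::tibble(start = ex$end[-nrow(ex)], end = ex$start[-1])
    ord <- if (minus) rev(seq_len(nrow(introns))) else seq_len(nrow(introns))
    for (k in seq_along(ord)) {
      it <- introns[ord[k], ]
      ilen <- it$end - it$start
      if (ilen < 4L) {
        out[[length(out) + 1L]] <- tibble::tibble(
          tx_id = tx$tx_id[i], intron = k, start = it$start, end = it$end,
          donor = NA_character_, acceptor = NA_character_,
          gt_ag = NA, donor_consensus = NA, too_short = TRUE)
        next
      }
      iseq <- substr(g, it$start + 1L, it$end)
      if (minus) iseq <- revcomp(iseq)
      donor <- substr(iseq, 1L, 2L)
      acceptor <- substr(iseq, nchar(iseq) - 1L, nchar(iseq))
      # donor junction: last 3 exonic + first 5 intronic, transcript strand
      junction <- NA_character_
      if (minus) {
        lo <- it$end - 5L  # 0-based first position of the 8-mer on genome
        if (lo >= 0L && it$end + 3L <= nchar(g)) {
          junction <- revcomp(substr(g, lo + 1L, it$end + 3L))
        }
      } else {
        lo <- it$start - 3L
        if (lo >= 0L && it$start + 5L <= nchar(g)) {
          junction <- substr(g, lo + 1L, it$start + 5L)
        }
      }
      consensus <- !is.na(junction) &&
        nrow(scan_iupac(junction, "MAG|GTRAG")) > 0 &&
        scan_iupac(junction, "MAG|GTRAG")$position[1] == 0L
      out[[length(out) + 1L]] <- tibble::tibble(
        tx_id = tx$tx_id[i], intron = k, start = it$start, end = it$end,
        donor = toupper(donor), acceptor = toupper(acceptor),
        gt_ag = toupper(donor) == "GT" && toupper(acceptor) == "AG",
        donor_consensus = consensus, too_short = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(tx_id = character(), intron = integer(),
                          start = integer(), end = integer(),
                          donor = character(), acceptor = character(),
                          gt_ag = logical(), donor_consensus = logical(),
                          too_short = logical()))
  }
  dplyr::bind_rows(out)
}
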