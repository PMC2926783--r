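# Seeded synthetic inputs with the statistical structure the analysis
# assumes: coding genes interleaved with multi-exon lncRNA loci, a
# conservation track with a promoter bump and splice-site bumps, conserved
# elements covering a target fraction of exonic bases, pairwise alignments
# with planted high-identity segments, and ortholog cDNA pairs with a
# planted identical-aligned fraction. Every generator is deterministic under
# (seed, config) and emits machine-readable ground truth.

#' Synthetic-data configuration
#'
#' Defaults encode the regime the conservation analysis assumes: a promoter
#' conservation peak of absolute height 0.19 centred 43 bp upstream of the
#' TSS on a 0.05 background, splice-site bumps, conserved elements covering
#' ~11% of exonic bases, ECRs of several hundred bp at 90% identity on a
#' mid-40s% background, and ortholog cDNA pairs whose conserved blocks leave
#' a controllable identical-aligned fraction.
#'
#' @param seed integer seed; all generators are deterministic under it.
#' @param n_chroms,chrom_length genome shape.
#' @param n_coding,n_lncrna locus counts.
#' @param exon_count_range,exon_len_range,intron_len_range integer ranges
#'   (bp) for locus structure; the exon-count minimum must be >= 2 so the
#'   cohort is multi-exon.
#' @param frac_overlapping,frac_proximal fractions of lncRNA loci planted to
#'   violate the coding-exon-overlap and the <`min_distance` proximity
#'   filters respectively (ground-truth labels are emitted).
#' @param proximal_gap_range,kept_gap_range,locus_spacing gap regimes (bp)
#'   between a lncRNA and its partner coding gene, and between units.
#' @param min_distance bp; the proximity filter threshold (default 5000).
#' @param promoter_peak_offset bp upstream of the TSS at which the planted
#'   promoter bump is centred (default 43).
#' @param promoter_peak_height absolute score at the bump peak (default 0.19).
#' @param promoter_peak_sd Gaussian bump width, bp.
#' @param splice_peak_height absolute score at internal splice-site bumps.
#' @param splice_peak_halfwidth bp on each side of a splice site affected.
#' @param background_score_mean background track score.
#' @param noise_halfwidth half-width of the uniform per-base jitter.
#' @param element_exonic_coverage target fraction of exonic bases covered by
#'   emitted conserved elements.
#' @param track_pad bp of track emitted beyond each lncRNA locus.
#' @param aln_length,aln_ref_start,background_identity,gap_rate pairwise
#'   alignment shape: columns, reference offset, per-column match
#'   probability outside planted segments, gap rate outside planted
#'   segments.
#' @param ecr_specs tibble with columns `start` (reference bp, relative to
#'   `aln_ref_start`), `length`, `identity`: planted conserved segments.
#' @param ortholog_length,ortholog_identity,ortholog_block_len ortholog cDNA
#'   pair shape: query length, planted identical-aligned fraction, typical
#'   conserved-block length.
#' @param add_polya plant an ATAAA poly(A) signal 30 bp upstream of the 3'
#'   end inside a conserved 3' block of the ortholog pair.
#' @return a list of class `lincons_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L, chrom_length = 6e6,
                       n_coding = 60L, n_lncrna = 60L,
                       exon_count_range = c(2L, 5L),
                       exon_len_range = c(100L, 250L),
                       intron_len_range = c(200L, 600L),
                       frac_overlapping = 0.1, frac_proximal = 0.15,
                       proximal_gap_range = c(500L, 4500L),
                       kept_gap_range = c(6000L, 12000L),
                       locus_spacing = 15000L,
                       min_distance = 5000L,
                       promoter_peak_offset = 43L,
                       promoter_peak_height = 0.19,
                       promoter_peak_sd = 10,
                       splice_peak_height = 0.12,
                       splice_peak_halfwidth = 20L,
                       background_score_mean = 0.05,
                       noise_halfwidth = 0.04,
                       element_exonic_coverage = 0.11,
                       track_pad = 300L,
                       aln_length = 3000L, aln_ref_start = 0L,
                       background_identity = 0.45, gap_rate = 0.02,
                       ecr_specs = tibble::tibble(start = 1000L,
                                                  length = 500L,
                                                  identity = 0.9),
                       ortholog_length = 2000L, ortholog_identity = 0.6,
                       ortholog_block_len = 200L,
                       add_polya = TRUE) {
  cfg <- as.list(environment())
  for (f in c("frac_overlapping", "frac_proximal", "background_identity",
              "gap_rate", "element_exonic_coverage", "ortholog_identity",
              "promoter_peak_height", "splice_peak_height",
              "background_score_mean", "noise_halfwidth")) {
    assert_scalar_number(cfg[[f]], f, 0, 1)
  }
  for (f in c("exon_count_range", "exon_len_range", "intron_len_range",
              "proximal_gap_range", "kept_gap_range")) {
    r <- cfg[[f]]
    if (length(r) != 2L || r[1] > r[2] || r[1] < 0) {
      abort(sprintf("`%s` must be a non-empty non-negative range", f))
    }
  }
  if (cfg$exon_count_range[1] < 2L) {
    abort("`exon_count_range` minimum must be >= 2 (multi-exon cohort)")
  }
  if (nrow(cfg$ecr_specs) > 0) {
    if (any(cfg$ecr_specs$length < 100L)) abort("planted ECR length must be >= 100")
    if (any(cfg$ecr_specs$identity < 0.7)) abort("planted ECR identity must be >= 0.7")
    if (any(cfg$ecr_specs$start + cfg$ecr_specs$length > cfg$aln_length)) {
      abort("planted ECR segment extends past the alignment")
    }
  }
  structure(cfg, class = "lincons_config")
}

sample_int_range <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

# Random multi-exon structure starting at `at`; returns an exon tibble.
random_exons <- function(at, cfg) {
  k <- sample_int_range(1L, cfg$exon_count_range)
  sizes <- sample_int_range(k, cfg$exon_len_range)
  gaps <- if (k > 1L) sample_int_range(k - 1L, cfg$intron_len_range) else integer(0)
  starts <- at + cumsum(c(0L, sizes[-k] + gaps))
  tibble::tibble(start = as.integer(starts), end = as.integer(starts + sizes))
}

#' Generate synthetic coding and lncRNA annotation
#'
#' Lays down units of one coding gene plus one lncRNA with a controlled gap:
#' a `frac_overlapping` share of lncRNAs has its first exon overlapping the
#' partner's last coding exon, a `frac_proximal` share sits at a gap drawn
#' from `proximal_gap_range` (< `min_distance`), the remainder at gaps from
#' `kept_gap_range`. Ground-truth filter labels are recomputed from the
#' emitted coordinates by an exhaustive pairwise scan, not taken on trust
#' from the layout.
#'
#' @param cfg a [sim_config()].
#' @return a list with transcript tibbles `coding` and `lncrna`, and `truth`
#'   (columns `tx_id`, `class`, `nearest_coding_distance`).
#' @export
sim_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "lincons_config"))
  set.seed(cfg$seed)
  n_units <- max(cfg$n_coding, cfg$n_lncrna)
  classes <- character(0)
  if (cfg$n_lncrna > 0) {
    n_ov <- round(cfg$frac_overlapping * cfg$n_lncrna)
    n_px <- round(cfg$frac_proximal * cfg$n_lncrna)
    classes <- sample(c(rep("overlaps_coding", n_ov), rep("within_proximity", n_px),
                        rep("kept", cfg$n_lncrna - n_ov - n_px)))
  }
  coding <- list()
  lncrna <- list()
  chrom_i <- 1L
  cursor <- 2000L
  for (i in seq_len(n_units)) {
    unit_len_budget <- 60000L
    if (cursor + unit_len_budget > cfg$chrom_length) {
      chrom_i <- chrom_i + 1L
      cursor <- 2000L
      if (chrom_i > cfg$n_chroms) {
        abort("loci do not fit in the genome; increase chrom_length or n_chroms")
      }
    }
    chrom <- sprintf("chr%d", chrom_i)
    cod_ex <- NULL
    if (i <= cfg$n_coding) {
      cod_ex <- random_exons(cursor, cfg)
      coding[[length(coding) + 1L]] <- list(
        tx_id = sprintf("cod%03d", i), chrom = chrom,
        strand = sample(c("+", "-"), 1L), exons = cod_ex)
      cursor <- cod_ex$end[nrow(cod_ex)]
    }
    if (i <= cfg$n_lncrna) {
      cls <- classes[i]
      if (is.null(cod_ex)) cls <- "kept"
      at <- switch(cls,
        overlaps_coding = {
          last_ex <- cod_ex[nrow(cod_ex), ]
          as.integer(last_ex$start + max(1L, (last_ex$end - last_ex$start) %/% 2L))
        },
        within_proximity = cursor + sample_int_range(1L, cfg$proximal_gap_range),
        kept = cursor + sample_int_range(1L, cfg$kept_gap_range)
      )
      lnc_ex <- random_exons(at, cfg)
      lncrna[[length(lncrna) + 1L]] <- list(
        tx_id = sprintf("lnc%03d", i), chrom = chrom,
        strand = sample(c("+", "-"), 1L), exons = lnc_ex)
      cursor <- max(cursor, lnc_ex$end[nrow(lnc_ex)])
    }
    cursor <- cursor + cfg$locus_spacing
  }
  as_tx <- function(recs, biotype) {
    if (length(recs) == 0L) {
      return(transcript_tbl(character(), character(), integer(), integer(),
                            character(), list(), biotype))
    }
    transcript_tbl(
      tx_id = purrr::map_chr(recs, "tx_id"),
      chrom = purrr::map_chr(recs, "chrom"),
      start = purrr::map_int(recs, ~ .x$exons$start[1]),
      end = purrr::map_int(recs, ~ .x$exons$end[nrow(.x$exons)]),
      strand = purrr::map_chr(recs, "strand"),
      exons = purrr::map(recs, "exons"),
      biotype = biotype
    )
  }
  coding_tbl <- as_tx(coding, "coding")
  lncrna_tbl <- as_tx(lncrna, "lncRNA")
  truth <- annotation_truth(lncrna_tbl, coding_tbl, cfg$min_distance)
  list(coding = coding_tbl, lncrna = lncrna_tbl, truth = truth)
}

# Exhaustive-scan ground truth for the filter stage.
annotation_truth <- function(lncrna, coding, min_distance) {
  purrr::map_dfr(seq_len(nrow(lncrna)), function(i) {
    lx <- lncrna$exons[[i]]
    same <- coding[coding$chrom == lncrna$chrom[i], , drop = FALSE]
    ov <- FALSE
    dist <- NA_integer_
    if (nrow(same) > 0) {
      for (j in seq_len(nrow(same))) {
        cx <- same$exons[[j]]
        for (a in seq_len(nrow(lx))) {
          if (any(lx$start[a] < cx$end & cx$start < lx$end[a])) ov <- TRUE
        }
      }
      dist <- min(interval_gap(lncrna$start[i], lncrna$end[i], same$start, same$end))
    }
    cls <- if (ov) "overlaps_coding"
           else if (!is.na(dist) && dist < min_distance) "within_proximity"
           else "kept"
    tibble::tibble(tx_id = lncrna$tx_id[i], class = cls,
                   nearest_coding_distance = dist)
  })
}

gauss_bump <- function(pos, centre, amp, sd, halfwidth = Inf) {
  d <- abs(pos - centre)
  v <- amp * exp(-(d^2) / (2 * sd^2))
  v[d > halfwidth] <- 0
  v
}

#' Generate a conservation score track with planted structure
#'
#' Emits per-base scores over every lncRNA locus (padded by
#' `cfg$track_pad`): a uniform-jitter background around
#' `background_score_mean`, a Gaussian bump reaching
#' `promoter_peak_height` centred `promoter_peak_offset` bp 5' of each TSS
#' (strand-aware), and bumps reaching `splice_peak_height` within
#' `splice_peak_halfwidth` bp of every internal splice site. Conserved
#' elements are the maximal runs above a threshold chosen (as an exonic
#' score quantile) so the fraction of exonic bases covered hits
#' `element_exonic_coverage`.
#'
#' @param cfg a [sim_config()].
#' @param lncrna a lncRNA transcript tibble from [sim_annotation()].
#' @return a list with `track` (score-track tibble), `elements` (element
#'   tibble) and `threshold` (the score cut used for elements).
#' @export
sim_score_track <- function(cfg, lncrna) {
  stopifnot(inherits(cfg, "lincons_config"))
  if (nrow(lncrna) == 0L) abort("no lncRNA loci to build a track over")
  set.seed(cfg$seed + 1L)
  bg <- cfg$background_score_mean
  amp_p <- cfg$promoter_peak_height - bg
  amp_s <- cfg$splice_peak_height - bg
  pieces <- vector("list", nrow(lncrna))
  exonic_mask <- vector("list", nrow(lncrna))
  for (i in seq_len(nrow(lncrna))) {
    lo <- lncrna$start[i] - cfg$track_pad
    hi <- lncrna$end[i] + cfg$track_pad
    pos <- seq.int(lo, hi - 1L)
    mu <- rep(bg, length(pos))
    tss <- if (lncrna$strand[i] == "-") lncrna$end[i] - 1L else lncrna$start[i]
    centre <- if (lncrna$strand[i] == "-") tss + cfg$promoter_peak_offset
              else tss - cfg$promoter_peak_offset
    mu <- pmax(mu, bg + gauss_bump(pos, centre, amp_p, cfg$promoter_peak_sd))
    ex <- lncrna$exons[[i]]
    if (nrow(ex) > 1L && amp_s > 0) {
      sites <- c(ex$end[-nrow(ex)] - 1L, ex$start[-1])  # donor/acceptor flanks
      for (s in sites) {
        mu <- pmax(mu, bg + gauss_bump(pos, s, amp_s, cfg$splice_peak_halfwidth / 2,
                                       cfg$splice_peak_halfwidth))
      }
    }
    score <- mu + runif(length(pos), -cfg$noise_halfwidth, cfg$noise_halfwidth)
    score <- pmin(pmax(score, 0), 1)
    pieces[[i]] <- tibble::tibble(chrom = lncrna$chrom[i], pos = pos, score = score)
    in_exon <- rep(FALSE, length(pos))
    for (e in seq_len(nrow(ex))) {
      in_exon[pos >= ex$start[e] & pos < ex$end[e]] <- TRUE
    }
    exonic_mask[[i]] <- in_exon
  }
  perbase <- dplyr::bind_rows(pieces)
  exonic <- unlist(exonic_mask)
  track <- score_track(perbase$chrom, perbase$pos, perbase$pos + 1L, perbase$score)

  cov <- cfg$element_exonic_coverage
  if (cov <= 0) {
    return(list(track = track,
                elements = element_tbl(character(), integer(), integer()),
                threshold = NA_real_))
  }
  ex_scores <- perbase$score[exonic]
  thr <- as.numeric(quantile(ex_scores, 1 - cov, names = FALSE))
  achieved <- mean(ex_scores >= thr)
  if (abs(achieved - cov) > 0.05) {
    abort(sprintf("requested exonic element coverage %.2f unreachable (achieved %.2f)",
                  cov, achieved))
  }
  above <- perbase$score >= thr
  n_pb <- nrow(perbase)
  run_id <- cumsum(c(TRUE, perbase$chrom[-1] != perbase$chrom[-n_pb] |
                       perbase$pos[-1] != perbase$pos[-n_pb] + 1L |
                       above[-1] != above[-n_pb]))
  first_of_run <- !duplicated(run_id)
  last_of_run <- rev(!duplicated(rev(run_id)))
  runs <- tibble::tibble(
    chrom = perbase$chrom[first_of_run],
    start = perbase$pos[first_of_run],
    end = perbase$pos[last_of_run] + 1L,
    above = above[first_of_run],
    mean_score = as.numeric(rowsum(perbase$score, run_id)) /
      as.numeric(rowsum(rep(1, n_pb), run_id)))
  runs <- runs[runs$above, , drop = FALSE]
  elements <- element_tbl(
    chrom = runs$chrom, start = runs$start, end = runs$end,
    name = sprintf("el%05d", seq_len(nrow(runs))),
    score = pmin(1000L, pmax(1L, as.integer(round_half_up(runs$mean_score * 1000)))))
  list(track = track, elements = elements, threshold = thr)
}

#' Generate a pairwise alignment with planted conserved segments
#'
#' One two-species alignment block with an ungapped reference row. Outside
#' planted segments each column matches with probability
#' `background_identity` and the non-reference row is gapped at `gap_rate`;
#' inside a planted segment columns match with that segment's identity and
#' are never gapped.
#'
#' @param cfg a [sim_config()].
#' @param ref_species,other_species row names for the emitted block.
#' @return a list with `blocks` (alignment tibble) and `truth` (planted
#'   segment coordinates in reference space).
#' @export
sim_alignment <- function(cfg, ref_species = "mouse", other_species = "chicken") {
  stopifnot(inherits(cfg, "lincons_config"))
  set.seed(cfg$seed + 2L)
  n <- cfg$aln_length
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  p <- rep(cfg$background_identity, n)
  planted <- rep(FALSE, n)
  specs <- cfg$ecr_specs
  for (k in seq_len(nrow(specs))) {
    idx <- seq.int(specs$start[k] + 1L, specs$start[k] + specs$length[k])
    p[idx] <- specs$identity[k]
    planted[idx] <- TRUE
  }
  match <- runif(n) < p
  gap <- runif(n) < cfg$gap_rate & !planted
  other <- ref
  mism <- which(!match & !gap)
  other[mism] <- purrr::map_chr(ref[mism],
    ~ sample(setdiff(c("A", "C", "G", "T"), .x), 1L))
  other[gap] <- "-"
  other_size <- sum(!gap)
  blocks <- tibble::tibble(
    block_id = 1L,
    species = c(ref_species, other_species),
    src_chrom = c("chr1", "chr1"),
    src_start = c(cfg$aln_ref_start, 0L),
    src_size = c(n, other_size),
    strand = "+",
    src_length = c(cfg$aln_ref_start + n, other_size),
    text = c(paste(ref, collapse = ""), paste(other, collapse = ""))
  )
  truth <- tibble::tibble(
    chrom = "chr1",
    start = cfg$aln_ref_start + specs$start,
    end = cfg$aln_ref_start + specs$start + specs$length,
    identity = specs$identity
  )
  list(blocks = validate_maf_blocks(blocks), truth = truth)
}

DNA_BASES <- c("A", "C", "G", "T")

scrub_polya <- function(chars, keep_start) {
  # remove chance ATAAA/AATAAA starts 3' of the planted one
  s <- paste(chars, collapse = "")
  for (iter in 1:100) {
    hits <- c(unlist(gregexpr("ATAAA", s, fixed = TRUE)),
              unlist(gregexpr("AATAAA", s, fixed = TRUE)))
    hits <- hits[hits > 0 & hits - 1L > keep_start]  # 0-based start beyond planted
    if (length(hits) == 0L) break
    i <- hits[1] + 2L  # disrupt the middle of the motif
    chars <- strsplit(s, "")[[1]]
    chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    s <- paste(chars, collapse = "")
  }
  strsplit(s, "")[[1]]
}

#' Generate an ortholog cDNA pair with a planted identity regime
#'
#' The query is a random cDNA partitioned into conserved blocks (copied
#' verbatim into the subject) separated by diverged segments (every base
#' point-substituted, plus short 1-10 bp indels, never inside conserved
#' blocks). The conserved blocks cover a fraction
#' `ortholog_identity` of the query, so the identical-aligned fraction
#' recoverable by local alignment is the configured value by construction.
#' With `add_polya` the 3'-terminal region is conserved and carries an
#' ATAAA signal starting exactly 30 bp upstream of the 3' end.
#'
#' @param cfg a [sim_config()].
#' @return a list with `query` and `subject` (one-row cDNA tibbles) and
#'   `truth` (planted identical fraction and poly(A) position).
#' @export
sim_ortholog_pair <- function(cfg) {
  stopifnot(inherits(cfg, "lincons_config"))
  set.seed(cfg$seed + 3L)
  L <- cfg$ortholog_length
  f <- cfg$ortholog_identity
  cons_total <- as.integer(round_half_up(f * L))
  qry <- sample(DNA_BASES, L, replace = TRUE)
  # conserved-block layout; when a poly(A) tail is requested the 3'-terminal
  # block is carved out of the conserved budget so the planted identical
  # fraction stays at `f`
  tail_len <- if (cfg$add_polya && L >= 60L && cons_total > 0L) {
    min(cons_total, max(40L, min(cfg$ortholog_block_len, L %/% 4L)))
  } else 0L
  remaining <- cons_total - tail_len
  interior <- tibble::tibble(start = integer(), end = integer())
  if (remaining > 0L) {
    n_blocks <- max(1L, min(as.integer(round_half_up(remaining / cfg$ortholog_block_len)),
                            remaining))
    sizes <- rep(remaining %/% n_blocks, n_blocks)
    sizes[n_blocks] <- sizes[n_blocks] + remaining - sum(sizes)
    div_total <- (L - tail_len) - remaining
    n_gaps <- n_blocks + 1L
    div_sizes <- rep(div_total %/% n_gaps, n_gaps)
    div_sizes[1] <- div_sizes[1] + div_total - sum(div_sizes)
    starts <- cumsum(div_sizes[seq_len(n_blocks)] + c(0L, sizes[-n_blocks]))
    interior <- tibble::tibble(start = as.integer(starts),
                               end = as.integer(starts + sizes))
    interior <- interior[interior$end > interior$start, , drop = FALSE]
  }
  blocks <- interior
  if (tail_len > 0L) {
    blocks <- dplyr::bind_rows(blocks, tibble::tibble(start = L - tail_len, end = L))
  }
  blocks <- merge_intervals(blocks$start, blocks$end)
  polya_pos <- NA_integer_
  if (cfg$add_polya && L >= 60L) {
    polya_pos <- L - 30L
    qry[(polya_pos + 1L):(polya_pos + 5L)] <- c("A", "T", "A", "A", "A")
    if (polya_pos >= 1L) qry[polya_pos] <- sample(c("C", "G", "T"), 1L)
    qry <- scrub_polya(qry, keep_start = polya_pos)
  }
  cons_mask <- rep(FALSE, L)
  for (b in seq_len(nrow(blocks))) {
    cons_mask[seq.int(blocks$start[b] + 1L, blocks$end[b])] <- TRUE
  }
  # subject: conserved blocks verbatim; diverged segments heavily substituted
  sbj_pieces <- list()
  bounds <- sort(unique(c(0L, blocks$start, blocks$end, L)))
  for (k in seq_len(length(bounds) - 1L)) {
    seg <- seq.int(bounds[k] + 1L, bounds[k + 1L])
    seg_chars <- qry[seg]
    if (cons_mask[seg[1]]) {
      sbj_pieces[[k]] <- seg_chars
    } else {
      # every diverged base is substituted, so the identical-aligned
      # fraction equals the conserved coverage by construction
      seg_chars <- purrr::map_chr(seg_chars,
        ~ sample(setdiff(DNA_BASES, .x), 1L))
      # one short (1-10 bp) indel per diverged segment, away from block edges
      if (length(seg_chars) > 30L) {
        if (runif(1) < 0.5) {
          at <- sample(10:(length(seg_chars) - 20L), 1L)
          del_end <- min(at + sample(1:10, 1L) - 1L, length(seg_chars) - 10L)
          seg_chars <- seg_chars[-(at:del_end)]
        } else {
          at <- sample(10:(length(seg_chars) - 10L), 1L)
          ins <- sample(DNA_BASES, sample(1:10, 1L), replace = TRUE)
          seg_chars <- append(seg_chars, ins, after = at)
        }
      }
      sbj_pieces[[k]] <- seg_chars
    }
  }
  sbj <- unlist(sbj_pieces)
  truth <- tibble::tibble(
    identical_fraction = sum(cons_mask) / L,
    polya_query_pos = polya_pos,
    n_conserved_blocks = nrow(blocks)
  )
  list(query = cdna_tbl("query", paste(qry, collapse = ""), "synthetic ortholog query"),
       subject = cdna_tbl("subject", paste(sbj, collapse = ""), "synthetic ortholog subject"),
       truth = truth)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulate a neutrally evolving codon-sequence pair
#'
#' Both sequences descend from a random stop-free ancestor; every nucleotide
#' site mutates independently with probability `sub_rate` per lineage
#' (uniform across the three alternatives). A mutation creating an in-frame
#' stop codon is rejected (that codon reverts to the ancestral state). With
#' no selection on protein sequence this is the regime in which dN/dS is
#' expected to be ~1.
#'
#' @param n_codons number of codons.
#' @param sub_rate per-site, per-lineage substitution probability.
#' @param seed integer seed.
#' @return a list with `a` and `b`, codon-aligned nucleotide strings.
#' @export
sim_neutral_codon_pair <- function(n_codons = 300L, sub_rate = 0.05, seed = 1L) {
  set.seed(seed)
  sense <- setdiff(apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1,
                         paste, collapse = ""), STOP_CODONS)
  anc <- sample(sense, n_codons, replace = TRUE)
  mutate_lineage <- function(codons) {
    chars <- strsplit(paste(codons, collapse = ""), "")[[1]]
    hit <- runif(length(chars)) < sub_rate
    chars[hit] <- purrr::map_chr(chars[hit], ~ sample(setdiff(DNA_BASES, .x), 1L))
    out <- substring(paste(chars, collapse = ""),
                     seq(1, 3 * length(codons), 3), seq(3, 3 * length(codons), 3))
    bad <- out %in% STOP_CODONS
    out[bad] <- codons[bad]
    out
  }
  list(a = paste(mutate_lineage(anc), collapse = ""),
       b = paste(mutate_lineage(anc), collapse = ""))
}

#' Generate genome sequence consistent with an annotation
#'
#' Random sequence per chromosome with, for every multi-exon transcript,
#' canonical GT..AG intron-terminal dinucleotides planted strand-aware, and
#' (optionally) a `CAGGTAAG` donor consensus spanning each exon/intron
#' junction. Used to exercise splice-site reporting without real genome
#' downloads.
#'
#' @param tx a transcript tibble.
#' @param chrom_lengths named integer vector; defaults to covering `tx`.
#' @param seed integer seed.
#' @param plant_donor also plant the 8-mer donor consensus (last 3 exonic +
#'   first 5 intronic bases).
#' @return named character vector of chromosome sequences.
#' @export
sim_genome_seq <- function(tx, chrom_lengths = NULL, seed = 1L, plant_donor = TRUE) {
  set.seed(seed)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(tx$end, tx$chrom), function(e) max(e) + 100L, 1L)
  }
  genome <- lapply(chrom_lengths, function(n) sample(DNA_BASES, n, replace = TRUE))
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(tx))) {
    ex <- tx$exons[[i]]
    if (nrow(ex) < 2L) next
    g <- genome[[tx$chrom[i]]]
    for (k in seq_len(nrow(ex) - 1L)) {
      istart <- ex$end[k]       # first intronic base (0-based)
      iend <- ex$start[k + 1L]  # one past last intronic base
      if (iend - istart < 8L) next
      if (tx$strand[i] == "-") {
        # genome-forward CT..AC; donor consensus reverse-complemented at iend
        g[(istart + 1L):(istart + 2L)] <- c("C", "T")
        g[(iend - 1L):iend] <- c("A", "C")
        if (plant_donor && iend + 3L <= length(g)) {
          donor <- c("C", "A", "G", "G", "T", "A", "A", "G")
          rc_donor <- rev(unname(rc[donor]))
          g[(iend - 4L):(iend + 3L)] <- rc_donor
        }
      } else {
        g[(istart + 1L):(istart + 2L)] <- c("G", "T")
        g[(iend - 1L):iend] <- c("A", "G")
        if (plant_donor && istart >= 3L) {
          g[(istart - 2L):(istart + 5L)] <- c("C", "A", "G", "G", "T", "A", "A", "G")
        }
      }
    }
    genome[[tx$chrom[i]]] <- g
  }
  vapply(genome, paste, collapse = "", FUN.VALUE = "")
}
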