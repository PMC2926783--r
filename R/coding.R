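# Coding-potential screen: longest-ORF detection with the >100 aa rule, and
# Nei-Gojobori (NG86) dN/dS with Jukes-Cantor correction on pre-aligned
# ortholog ORF pairs. NG86 counting is fully desk-verifiable: per codon the
# nine single-nucleotide mutants partition into synonymous and
# non-synonymous site fractions (stop mutants excluded, rescaled to 3), and
# per differing codon pair the observed differences are classified by
# averaging over all substitution orderings that avoid stop intermediates.

codon_table <- function() {
  if (is.null(the$codons)) {
    gc <- Biostrings::GENETIC_CODE
    the$codons <- gc
  }
  the$codons
}

translate_codon <- function(codon) {
  aa <- codon_table()[codon]
  if (is.na(aa)) abort(sprintf("invalid codon '%s'", codon))
  unname(aa)
}

#' Find the longest open reading frame of each cDNA
#'
#' Scans the forward strand only (inputs are oriented cDNAs), all three
#' frames, from each ATG to the first in-frame stop. The longest ORF by
#' amino-acid length wins, ties to the 5'-most start. ORFs containing N are
#' skipped. An ATG with no downstream in-frame stop yields an incomplete
#' ORF counted by its current amino-acid length.
#'
#' @param cdna a cDNA tibble (or a single sequence string).
#' @param long_aa strict amino-acid threshold for the `long_orf` flag
#'   (default 100: an ORF is "long" only when > 100 aa).
#' @return a tibble with one row per record: `id`, `frame` (0/1/2),
#'   `nt_start`, `nt_end` (0-based half-open on the transcript, stop codon
#'   included when present), `aa_length` (codons excluding stop),
#'   `complete`, `long_orf`. Records with no ORF get `NA` coordinates and
#'   `long_orf = FALSE`.
#' @export
find_longest_orf <- function(cdna, long_aa = 100L) {
  if (is.character(cdna)) cdna <- cdna_tbl(names(cdna) %||% "seq", cdna)
  purrr::map_dfr(seq_len(nrow(cdna)), function(i) {
    orf <- longest_orf_one(cdna$seq[i])
    if (is.null(orf)) {
      return(tibble::tibble(id = cdna$id[i], frame = NA_integer_,
                            nt_start = NA_integer_, nt_end = NA_integer_,
                            aa_length = NA_integer_, complete = NA,
                            long_orf = FALSE))
    }
    tibble::tibble(id = cdna$id[i], frame = orf$frame,
                   nt_start = orf$nt_start, nt_end = orf$nt_end,
                   aa_length = orf$aa_length, complete = orf$complete,
                   long_orf = orf$aa_length > long_aa)
  })
}

longest_orf_one <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    n_codons <- (n - frame) %/% 3L
    if (n_codons < 1L) next
    starts <- frame + 3L * (seq_len(n_codons) - 1L)  # 0-based codon starts
    codons <- substring(seq, starts + 1L, starts + 3L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% STOP_CODONS
    if (!any(is_atg)) next
    stop_idx <- which(is_stop)
    seg <- findInterval(which(is_atg), stop_idx) + 1L  # stop segment of each ATG
    for (s in unique(seg)) {
      atg_i <- min(which(is_atg)[seg == s])  # 5'-most ATG before this stop
      stop_i <- if (s <= length(stop_idx)) stop_idx[s] else NA_integer_
      complete <- !is.na(stop_i)
      last_codon <- if (complete) stop_i else n_codons
      aa_len <- (if (complete) stop_i - atg_i else n_codons - atg_i + 1L)
      nt_start <- starts[atg_i]
      nt_end <- starts[last_codon] + 3L
      body <- substr(seq, nt_start + 1L, nt_end)
      if (grepl("N", body, fixed = TRUE)) next
      cand <- list(frame = frame, nt_start = nt_start, nt_end = nt_end,
                   aa_length = as.integer(aa_len), complete = complete)
      if (is.null(best) || cand$aa_length > best$aa_length ||
          (cand$aa_length == best$aa_length && cand$nt_start < best$nt_start)) {
        best <- cand
      }
    }
  }
  best
}

#' Nei-Gojobori synonymous/non-synonymous site counts of one codon
#'
#' Enumerates the nine single-nucleotide mutants; mutants that are stop
#' codons are excluded and the remainder rescaled so that `n + s = 3`.
#'
#' @param codon a 3-mer over ACGT, not a stop codon.
#' @return a named numeric vector `c(n = , s = )`.
#' @examples
#' ng86_sites("TTT")  # s = 1/3: only TTT->TTC is synonymous
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    abort(sprintf("codon must be a 3-mer over ACGT, got '%s'", codon))
  }
  if (codon %in% STOP_CODONS) abort(sprintf("'%s' is a stop codon", codon))
  key <- paste0("sites_", codon)
  if (!is.null(the[[key]])) return(the[[key]])
  aa <- translate_codon(codon)
  syn <- 0L
  counted <- 0L
  chars <- strsplit(codon, "")[[1]]
  for (p in 1:3) {
    for (b in setdiff(DNA_BASES, chars[p])) {
      mut <- chars
      mut[p] <- b
      mut_codon <- paste(mut, collapse = "")
      if (mut_codon %in% STOP_CODONS) next
      counted <- counted + 1L
      if (translate_codon(mut_codon) == aa) syn <- syn + 1L
    }
  }
  s <- 3 * syn / counted
  out <- c(n = 3 - s, s = s)
  the[[key]] <- out
  out
}

# Differences between one codon pair, averaged over all substitution
# orderings that avoid stop intermediates. Returns c(nd, sd) or NULL when
# every pathway crosses a stop.
ng86_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(nd = 0, sd = 0))
  perms <- list(seq_along(pos))
  if (length(pos) == 2L) perms <- list(c(1L, 2L), c(2L, 1L))
  if (length(pos) == 3L) {
    perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                  c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  }
  tgt <- strsplit(c2, "")[[1]]
  acc <- c(nd = 0, sd = 0)
  n_valid <- 0L
  for (perm in perms) {
    cur <- strsplit(c1, "")[[1]]
    nd <- sd <- 0
    ok <- TRUE
    for (step in perm) {
      prev <- paste(cur, collapse = "")
      cur[pos[step]] <- tgt[pos[step]]
      now <- paste(cur, collapse = "")
      if (now %in% STOP_CODONS) { ok <- FALSE; break }
      if (translate_codon(prev) == translate_codon(now)) sd <- sd + 1
      else nd <- nd + 1
    }
    if (ok) {
      acc <- acc + c(nd = nd, sd = sd)
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(NULL)
  acc / n_valid
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -(3 / 4) * log(1 - 4 * p / 3)
}

#' Nei-Gojobori dN/dS for a pre-aligned codon pair
#'
#' @param a,b equal-length nucleotide strings (gaps as `-`), length
#'   divisible by 3, codon-aligned. Codons gapped or ambiguous in either
#'   sequence are dropped pairwise; a stop codon before the final codon
#'   position is an error; terminal stop codons are dropped.
#' @return an object of class `dnds_estimate`: site counts `N`, `S`
#'   (averaged over the two sequences), difference counts `Nd`, `Sd`
#'   (pathway-averaged), proportions `pN`, `pS`, Jukes-Cantor corrected
#'   rates `dN`, `dS` (`NA` when the correction is undefined, i.e.
#'   p >= 3/4), `ratio` = dN/dS (`NA` when dS is 0 or undefined), the
#'   number of codons compared and QC drop counts. Symmetric in its
#'   arguments.
#' @export
ng86_dnds <- function(a, b) {
  a <- toupper(gsub("\\s", "", a))
  b <- toupper(gsub("\\s", "", b))
  if (nchar(a) != nchar(b)) abort("sequences must be equal length (aligned)")
  if (nchar(a) %% 3L != 0L) abort("alignment length must be divisible by 3")
  n_codons <- nchar(a) %/% 3L
  if (n_codons == 0L) abort("empty alignment")
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  ca <- substring(a, starts, starts + 2L)
  cb <- substring(b, starts, starts + 2L)
  gapped <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  ambiguous <- !gapped & (grepl("[^ACGT]", ca) | grepl("[^ACGT]", cb))
  # terminal stops dropped; internal stops are an error
  is_stop <- !gapped & !ambiguous & (ca %in% STOP_CODONS | cb %in% STOP_CODONS)
  internal_stop <- which(is_stop & seq_len(n_codons) < n_codons)
  if (length(internal_stop) > 0) {
    abort(sprintf("internal stop codon at codon %d", internal_stop[1]))
  }
  keep <- !gapped & !ambiguous & !is_stop
  N <- S <- Nd <- Sd <- 0
  n_stop_path <- 0L
  compared <- 0L
  for (i in which(keep)) {
    d <- ng86_pair_diffs(ca[i], cb[i])
    if (is.null(d)) {
      n_stop_path <- n_stop_path + 1L
      next
    }
    sa <- ng86_sites(ca[i])
    sb <- ng86_sites(cb[i])
    N <- N + (sa["n"] + sb["n"]) / 2
    S <- S + (sa["s"] + sb["s"]) / 2
    Nd <- Nd + d["nd"]
    Sd <- Sd + d["sd"]
    compared <- compared + 1L
  }
  pN <- if (N > 0) Nd / N else NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  dN <- jc_correct(unname(pN))
  dS <- jc_correct(unname(pS))
  ratio <- if (is.na(dN) || is.na(dS) || dS == 0) NA_real_ else dN / dS
  structure(list(
    N = unname(N), S = unname(S), Nd = unname(Nd), Sd = unname(Sd),
    pN = unname(pN), pS = unname(pS), dN = dN, dS = dS, ratio = ratio,
    codons_compared = compared,
    n_gapped_dropped = sum(gapped),
    n_ambiguous_dropped = sum(ambiguous),
    n_stop_path_dropped = n_stop_path,
    dN_defined = !is.na(dN), dS_defined = !is.na(dS),
    ratio_defined = !is.na(ratio)
  ), class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("Nei-Gojobori dN/dS (Jukes-Cantor corrected), %d codons compared\n",
              x$codons_compared))
  cat(sprintf("  sites     N = %.3f  S = %.3f\n", x$N, x$S))
  cat(sprintf("  diffs    Nd = %.3f Sd = %.3f\n", x$Nd, x$Sd))
  cat(sprintf("  rates    dN = %s  dS = %s  dN/dS = %s\n",
              format(x$dN, digits = 4), format(x$dS, digits = 4),
              format(x$ratio, digits = 4)))
  invisible(x)
}

#' @method glance dnds_estimate
#' @export
glance.dnds_estimate <- function(x, ...) {
  tibble::tibble(N = x$N, S = x$S, Nd = x$Nd, Sd = x$Sd, pN = x$pN, pS = x$pS,
                 dN = x$dN, dS = x$dS, ratio = x$ratio,
                 codons_compared = x$codons_compared,
                 n_gapped_dropped = x$n_gapped_dropped,
                 n_ambiguous_dropped = x$n_ambiguous_dropped,
                 n_stop_path_dropped = x$n_stop_path_dropped)
}

#' @method tidy dnds_estimate
#' @export
tidy.dnds_estimate <- function(x, ...) {
  terms <- c("N", "S", "Nd", "Sd", "pN", "pS", "dN", "dS", "ratio")
  tibble::tibble(term = terms,
                 estimate = purrr::map_dbl(terms, ~ as.numeric(x[[.x]] %||% NA_real_)))
}
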