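# FASTA in/out for cDNA records. File IO rides on Biostrings; parsing from
# in-memory lines (the parser the rest of the package and the tests use)
# applies the same normalisation: upper-case, U -> T, strict ACGTN alphabet.

#' Parse FASTA cDNA records
#'
#' @param lines character vector of FASTA lines.
#' @return a cDNA tibble (see [cdna_tbl()]); sequences are upper-cased and
#'   `U` is mapped to `T`.
#' @examples
#' parse_fasta(c(">x", "acgu"))
#' @export
parse_fasta <- function(lines) {
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) abort("FASTA input contains no '>' header")
  ids <- character(length(hdr))
  descs <- character(length(hdr))
  seqs <- character(length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    h <- sub("^>", "", lines[hdr[i]])
    sp <- regexpr("\\s", h)
    ids[i] <- if (sp > 0) substr(h, 1, sp - 1) else h
    descs[i] <- if (sp > 0) trimws(substr(h, sp + 1, nchar(h))) else ""
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)[seq_len(max(0L, bounds[i + 1L] - hdr[i] - 1L))]]
    seqs[i] <- paste(gsub("\\s", "", body), collapse = "")
    if (!nzchar(seqs[i])) abort(sprintf("record '%s': empty sequence body", ids[i]))
  }
  cdna_tbl(ids, seqs, descs)
}

#' Read cDNA records from a FASTA file
#'
#' @param path path to a FASTA file.
#' @return a cDNA tibble.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  sp <- regexpr("\\s", hdr)
  ids <- ifelse(sp > 0, substr(hdr, 1, sp - 1), hdr)
  descs <- ifelse(sp > 0, trimws(substr(hdr, sp + 1, nchar(hdr))), "")
  cdna_tbl(ids, as.character(set), descs)
}

#' Write cDNA records as FASTA
#'
#' @param cdna a cDNA tibble.
#' @param path output path.
#' @param width line width for the sequence body.
#' @export
write_fasta <- function(cdna, path, width = 70L) {
  nm <- ifelse(nzchar(cdna$desc), paste(cdna$id, cdna$desc), cdna$id)
  set <- Biostrings::DNAStringSet(setNames(cdna$seq, nm))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
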