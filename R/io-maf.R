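# MAF (multiple alignment format) reader/writer. Blocks are stored flat: one
# tibble row per "s" line, grouped by block_id, first row = reference.
# Soft-masked lower-case bases are preserved; all identity comparisons in the
# package are case-insensitive.

#' Parse MAF alignment blocks
#'
#' @param lines character vector of MAF lines.
#' @return a tibble with columns `block_id`, `species`, `src_chrom`,
#'   `src_start`, `src_size`, `strand`, `src_length`, `text`, validated by
#'   [validate_maf_blocks()]. Species and source chromosome are split from
#'   the MAF `src` field at the first dot; a dotless `src` is used for both.
#' @export
parse_maf <- function(lines) {
  rows <- list()
  block_id <- 0L
  in_block <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) {
      in_block <- FALSE
      next
    }
    if (startsWith(ln, "a")) {
      block_id <- block_id + 1L
      in_block <- TRUE
      next
    }
    if (startsWith(ln, "s ")) {
      if (!in_block) abort(sprintf("line %d: 's' line outside an 'a' block", i))
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) != 7L) abort(sprintf("line %d: 's' line needs 7 fields", i))
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substr(src, 1, dot - 1) else src
      src_chrom <- if (dot > 0) substr(src, dot + 1, nchar(src)) else src
      nums <- suppressWarnings(as.integer(f[c(3, 4, 6)]))
      if (anyNA(nums)) abort(sprintf("line %d: non-integer MAF coordinates", i))
      if (!f[5] %in% c("+", "-")) abort(sprintf("line %d: bad strand '%s'", i, f[5]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block_id = block_id, species = species, src_chrom = src_chrom,
        src_start = nums[1], src_size = nums[2], strand = f[5],
        src_length = nums[3], text = f[7]
      )
      next
    }
    # other MAF line types (q, i, e) are ignored
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(block_id = integer(), species = character(),
                          src_chrom = character(), src_start = integer(),
                          src_size = integer(), strand = character(),
                          src_length = integer(), text = character()))
  }
  validate_maf_blocks(dplyr::bind_rows(rows))
}

#' @rdname parse_maf
#' @param path path to a MAF file.
#' @export
read_maf <- function(path) parse_maf(readLines(path))

#' Write alignment blocks as MAF
#'
#' @param blocks an alignment-block tibble.
#' @inheritParams write_bed12
#' @export
write_maf <- function(blocks, path = NULL, header = !is.null(path)) {
  lines <- "##maf version=1"
  if (header) lines <- c(tool_header(), lines)
  for (b in unique(blocks$block_id)) {
    rows <- blocks[blocks$block_id == b, , drop = FALSE]
    lines <- c(lines, "", "a score=0.0",
               sprintf("s %s.%s %d %d %s %d %s", rows$species, rows$src_chrom,
                       rows$src_start, rows$src_size, rows$strand,
                       rows$src_length, rows$text))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
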