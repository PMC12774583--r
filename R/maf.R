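#' Parse a multiple alignment in MAF format
#'
#' Reads alignment blocks from a MAF file. Each block is returned as a
#' data frame of its `s` rows with columns `src`, `species`, `chrom`,
#' `start` (0-based), `size`, `strand`, `src_size` and `text` (the gapped
#' sequence, uppercased). The species label is the part of `src` before the
#' first dot; the remainder is the chromosome (a dotless `src` is used for
#' both). `e`, `i` and `q` lines are ignored.
#'
#' @param path path to a MAF file.
#' @return list of blocks (data frames), in file order.
#' @export
parse_maf <- function(path) {
  lines <- readLines(path)
  blocks <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || nrow(cur) == 0L) return(NULL)
    if (length(unique(nchar(cur$text))) != 1L)
      stop2("MAF block ending near line %d: row texts differ in length", cur$line[nrow(cur)])
    cur$line <- NULL
    cur
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) {
      b <- flush(cur); if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- NULL
      next
    }
    tag <- substr(ln, 1L, 1L)
    if (tag == "a") {
      b <- flush(cur); if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
      cur <- data.frame(src = character(0), species = character(0),
                        chrom = character(0), start = integer(0),
                        size = integer(0), strand = character(0),
                        src_size = integer(0), text = character(0),
                        line = integer(0), stringsAsFactors = FALSE)
    } else if (tag == "s") {
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) != 7L)
        stop2("malformed 's' line at line %d: expected 7 fields, got %d", i, length(f))
      start <- suppressWarnings(as.integer(f[3]))
      size <- suppressWarnings(as.integer(f[4]))
      src_size <- suppressWarnings(as.integer(f[6]))
      if (anyNA(c(start, size, src_size)))
        stop2("malformed 's' line at line %d: non-numeric coordinates", i)
      if (!f[5] %in% c("+", "-"))
        stop2("malformed 's' line at line %d: bad strand '%s'", i, f[5])
      text <- toupper(f[7])
      ngap <- nchar(gsub("-", "", text, fixed = TRUE))
      if (ngap != size)
        stop2("malformed 's' line at line %d: size %d but %d non-gap characters",
              i, size, ngap)
      if (start < 0L || start + size > src_size)
        stop2("malformed 's' line at line %d: coordinates exceed src size", i)
      if (is.null(cur))
        stop2("'s' line at line %d outside any 'a' block", i)
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- if (dot > 0) substr(src, 1L, dot - 1L) else src
      chrom <- if (dot > 0) substr(src, dot + 1L, nchar(src)) else src
      cur <- rbind(cur, data.frame(src = src, species = species, chrom = chrom,
                                   start = start, size = size, strand = f[5],
                                   src_size = src_size, text = text, line = i,
                                   stringsAsFactors = FALSE))
    }
    # e/i/q lines ignored
  }
  b <- flush(cur); if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  blocks
}

#' Write alignment blocks as MAF
#'
#' Inverse of [parse_maf()]: serialises a list of block data frames to a
#' MAF file (single-space field separation, one blank line between blocks).
#'
#' @param blocks list of block data frames as returned by [parse_maf()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  writeLines("", con)
  for (b in blocks) {
    writeLines("a", con)
    writeLines(sprintf("s %s %d %d %s %d %s",
                       b$src, b$start, b$size, b$strand, b$src_size, b$text), con)
    writeLines("", con)
  }
  invisible(path)
}

# forward 1-based reference positions of the non-gap columns of a row,
# in text order. For minus-strand rows the text runs along the reverse
# strand, so the k-th non-gap character sits at src_size - start - k + 1.
row_positions <- function(row) {
  ch <- seq_chars(row$text)
  nongap <- ch != "-"
  k <- cumsum(nongap)
  pos <- if (row$strand == "+") row$start + k else row$src_size - row$start - k + 1L
  list(chars = ch, nongap = nongap, pos = pos)
}
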