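# shared internal helpers

DNA_BASES <- c("A", "C", "G", "T")
UNALIGNED <- "."
AMBIGUOUS <- "?"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn2 <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Complement nucleotide characters
#'
#' Vectorised complement over single-character nucleotide strings; gaps
#' (`-`) and `N` are returned unchanged.
#'
#' @param x character vector of single bases.
#' @return character vector of the same length.
#' @keywords internal
comp_base <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# reverse-complement a (possibly gapped) sequence string
revcomp_str <- function(s) {
  vapply(s, function(one) {
    ch <- rev(strsplit(comp_base(one), "", fixed = TRUE)[[1]])
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# evaluate `code` with the RNG seeded to `seed`, restoring RNG state after
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# split sequence string into a character vector of single bases (uppercase)
seq_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

# empty SNV table with canonical columns
empty_snvs <- function() {
  data.frame(chrom = character(0), pos = integer(0), from = character(0),
             to = character(0), class = character(0), af = numeric(0),
             stringsAsFactors = FALSE)
}

check_snv_frame <- function(x, what = "variant table") {
  need <- c("chrom", "pos", "from", "to")
  if (!all(need %in% names(x)))
    stop2("%s must have columns %s", what, paste(need, collapse = ", "))
  invisible(x)
}

snv_key <- function(chrom, pos, to) paste(chrom, pos, to, sep = ":")
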