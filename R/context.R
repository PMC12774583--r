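#' Sequence-context features around positions
#'
#' GC fraction and CpG dinucleotide count in a window of `+-window` bp
#' around each position, clipped at chromosome ends. GC fraction is counted
#' over non-N bases; a window containing only N is reported as 0 with its
#' missing flag set. CpG sites are counted by their first base lying inside
#' the (clipped) window.
#'
#' Implemented with cumulative-sum lookups so whole-genome sweeps cost O(1)
#' per query after one pass over the chromosome.
#'
#' @param genome reference genome.
#' @param chrom chromosome name (single value).
#' @param pos integer vector of 1-based positions.
#' @param window half-width of the context window in bp.
#' @return data frame `gc_fraction, cpg_count, gc_missing` aligned with `pos`.
#' @export
sequence_context_features <- function(genome, chrom, pos, window = 75L) {
  s <- unclass(genome)[[chrom]]
  if (is.null(s) || is.na(s)) stop2("chromosome %s not in genome", chrom)
  n <- nchar(s)
  if (any(pos < 1L | pos > n)) stop2("position outside chromosome %s", chrom)
  b <- charToRaw(s)
  G <- charToRaw("G"); C <- charToRaw("C"); A <- charToRaw("A"); T <- charToRaw("T")
  is_gc <- b == G | b == C
  is_base <- is_gc | b == A | b == T
  cum_gc <- c(0, cumsum(is_gc))
  cum_base <- c(0, cumsum(is_base))
  is_cpg <- if (n >= 2L) b[-n] == C & b[-1L] == G else logical(0)
  cum_cpg <- c(0, cumsum(is_cpg))  # indexed by dinucleotide start position
  start <- pmax(1L, pos - as.integer(window))
  end <- pmin(n, pos + as.integer(window))
  gc <- cum_gc[end + 1L] - cum_gc[start]
  nb <- cum_base[end + 1L] - cum_base[start]
  # CpG starts in [start, end-1]
  lo <- pmin(start, n - 1L + (n < 2L))
  hi <- pmax(end - 1L, lo - 1L)
  cpg <- if (n >= 2L) cum_cpg[pmin(hi, n - 1L) + 1L] - cum_cpg[lo] else rep(0, length(pos))
  cpg[end - 1L < start] <- 0
  missing <- nb == 0
  gc_fraction <- ifelse(missing, 0, gc / pmax(nb, 1))
  data.frame(gc_fraction = gc_fraction, cpg_count = as.numeric(cpg),
             gc_missing = missing)
}
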