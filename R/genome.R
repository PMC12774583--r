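#' Read a reference genome from FASTA
#'
#' Loads a FASTA file into a named character vector of uppercase sequences,
#' one element per chromosome. This plain representation keeps downstream
#' per-position arithmetic simple and fast at the scales this package
#' targets.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences, class `genome`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop2("genome FASTA not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(ss))
  class(g) <- c("genome", "character")
  g
}

#' Write a genome to FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome named character vector of sequences.
#' @return named integer vector of lengths.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

# fetch single reference bases, vectorised over pos (one chromosome)
ref_base_at <- function(genome, chrom, pos) {
  s <- unclass(genome)[[chrom]]
  if (is.null(s) || is.na(s)) stop2("chromosome %s not in genome", chrom)
  substring(s, pos, pos)
}
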