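#' Read population allele frequencies from a VCF
#'
#' Extracts per-alt allele frequencies from the `AF` INFO field, falling
#' back to `AC/AN` when `AF` is absent. Multiallelic records are decomposed
#' into one row per alternate allele.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @return data frame `chrom, pos, ref, alt, af`, class `population_af`.
#' @export
read_population_vcf <- function(path) {
  if (!file.exists(path)) stop2("population VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), af = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("population_af", "data.frame")
    return(out)
  }
  af_raw <- vcfR::extract.info(v, "AF")
  if (all(is.na(af_raw))) {
    ac <- vcfR::extract.info(v, "AC")
    an <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AN")))
    if (all(is.na(ac)))
      stop2("VCF %s carries neither AF nor AC/AN INFO fields", path)
    af_raw <- vapply(seq_along(ac), function(i) {
      if (is.na(ac[i]) || is.na(an[i]) || an[i] <= 0) return(NA_character_)
      paste(as.numeric(strsplit(ac[i], ",", fixed = TRUE)[[1]]) / an[i], collapse = ",")
    }, character(1))
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  afs <- strsplit(af_raw, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  out <- data.frame(
    chrom = rep(fix$CHROM, n_alt),
    pos = rep(as.integer(fix$POS), n_alt),
    ref = rep(toupper(fix$REF), n_alt),
    alt = toupper(unlist(alts)),
    af = suppressWarnings(as.numeric(unlist(afs))),
    stringsAsFactors = FALSE)
  if (anyNA(out$af))
    stop2("VCF %s: unparseable or missing AF for %d record(s)", path, sum(is.na(out$af)))
  if (any(out$af < 0 | out$af > 1))
    stop2("VCF %s: AF outside [0,1]", path)
  out <- out[nchar(out$ref) == 1L & nchar(out$alt) == 1L & out$alt %in% DNA_BASES, ]
  rownames(out) <- NULL
  class(out) <- c("population_af", "data.frame")
  out
}

#' Write a minimal population VCF
#'
#' Serialises a `chrom, pos, ref, alt, af` table as a biallelic-per-row VCF
#' with `AF` in INFO. Used by the synthetic-fixture generator and for
#' exporting variant sets.
#'
#' @param df data frame with columns `chrom, pos, ref, alt, af`.
#' @param genome reference genome, used to emit contig header lines.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(df, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  lens <- genome_lengths(genome)
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
               "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(df) > 0L) {
    o <- order(match(df$chrom, names(lens)), df$pos, df$alt)
    df <- df[o, ]
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAF=%s",
                       df$chrom, df$pos, df$ref, df$alt,
                       sprintf("%.6g", df$af)), con)
  }
  invisible(path)
}

# reference-allele frequency per (chrom,pos): 1 - sum of alt AFs
ref_af_by_pos <- function(pop) {
  key <- paste(pop$chrom, pop$pos, sep = ":")
  alt_sum <- tapply(pop$af, key, sum)
  stats::setNames(pmax(0, 1 - as.numeric(alt_sum)), names(alt_sum))
}
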