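#' Enumerate every possible SNV
#'
#' Yields, for each reference position carrying a concrete base, the three
#' alternate alleles in fixed `A < C < G < T` order (the reference allele is
#' skipped); positions with `N` are skipped entirely. Order is chromosomes
#' as stored in the genome, positions ascending.
#'
#' @param genome reference genome.
#' @param region optional restriction, `"chrom"` or `"chrom:from-to"`.
#' @return data frame `chrom, pos, ref, alt`.
#' @export
enumerate_snvs <- function(genome, region = NULL) {
  lens <- genome_lengths(genome)
  spans <- if (is.null(region)) {
    lapply(stats::setNames(nm = names(lens)), function(ch) c(1L, lens[[ch]]))
  } else {
    p <- parse_region(region, lens)
    stats::setNames(list(c(p$from, p$to)), p$chrom)
  }
  out <- vector("list", length(spans))
  alt_sets <- lapply(stats::setNames(nm = DNA_BASES), function(b) setdiff(DNA_BASES, b))
  for (i in seq_along(spans)) {
    ch <- names(spans)[i]
    fr <- spans[[i]][1]; to <- spans[[i]][2]
    r <- seq_chars(unclass(genome)[[ch]])[fr:to]
    keep <- which(r %in% DNA_BASES)
    if (length(keep) == 0L) next
    pos <- fr + keep - 1L
    refb <- r[keep]
    alt <- do.call(rbind, alt_sets[refb])
    out[[i]] <- data.frame(chrom = ch, pos = rep(pos, each = 3L),
                           ref = rep(refb, each = 3L),
                           alt = as.vector(t(alt)), stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

parse_region <- function(region, lens) {
  m <- regmatches(region, regexec("^([^:]+)(:([0-9]+)-([0-9]+))?$", region))[[1]]
  if (length(m) == 0L || !m[2] %in% names(lens))
    stop2("bad region '%s' (expected 'chrom' or 'chrom:from-to' within the genome)", region)
  ch <- m[2]
  if (m[3] == "") return(list(chrom = ch, from = 1L, to = lens[[ch]]))
  fr <- as.integer(m[4]); to <- as.integer(m[5])
  if (fr < 1L || to > lens[[ch]] || fr > to)
    stop2("region '%s' outside chromosome bounds", region)
  list(chrom = ch, from = fr, to = to)
}

#' PHRED-scale raw scores
#'
#' Ranks raw scores descending (rank 1 = highest = most
#' proxy-deleterious-like) and maps rank `i` of `N` to `-10 log10(i / N)`.
#' Tied raw scores share the minimum rank of their tie group, so equal
#' inputs always receive equal scaled scores; the lowest-ranked score maps
#' to exactly 0. Because only ranks enter, the result is invariant under any
#' strictly increasing transformation of the raw scores.
#'
#' @param raw_scores finite numeric vector.
#' @return numeric vector of PHRED-like scores, aligned with the input.
#' @export
phred_scale <- function(raw_scores) {
  if (length(raw_scores) == 0L) stop2("phred_scale: empty input")
  if (any(!is.finite(raw_scores))) stop2("phred_scale: non-finite raw scores")
  n <- length(raw_scores)
  i <- rank(-raw_scores, ties.method = "min")
  -10 * log10(i / n)
}

#' Score a variant set with a trained model
#'
#' Re-encodes the variants with the model's own feature specs and frozen
#' imputation statistics and returns the raw linear scores.
#'
#' @param model a `cadd_model` carrying `specs` and `imputation_stats`.
#' @param variants data frame `chrom, pos, ref/from, alt/to`.
#' @param tracks named list of loaded annotation tracks.
#' @param genome reference genome.
#' @param gff optional GFF3 for consequence features.
#' @param context_window half-width for sequence-context built-ins.
#' @return numeric vector of raw scores.
#' @export
score_variants <- function(model, variants, tracks = list(), genome = NULL,
                           gff = NULL, context_window = 75L) {
  if (is.null(model$specs) || length(model$specs) == 0L)
    stop2("model carries no feature specs; cannot encode variants")
  v <- variants
  if (!"from" %in% names(v) && "ref" %in% names(v)) v$from <- v$ref
  if (!"to" %in% names(v) && "alt" %in% names(v)) v$to <- v$alt
  rec <- assemble_features(v, model$specs, tracks = tracks, genome = genome,
                           gff = gff, context_window = context_window)
  fm <- encode_and_impute(rec, model$specs, labels = NULL,
                          stats = model$imputation_stats)
  raw_score(model, fm)
}

#' Score all possible SNVs and PHRED-scale them
#'
#' Enumerates every SNV in the genome (or a region), scores each in chunks
#' with the trained model, and PHRED-scales the ranks globally over the
#' scored set.
#'
#' @inheritParams score_variants
#' @param region optional `"chrom"` or `"chrom:from-to"` restriction; ranks
#'   (and therefore PHRED scores) are then relative to the region.
#' @param chunk_size number of SNVs encoded per chunk.
#' @return score table: `chrom, pos, ref, alt, raw_score, phred`.
#' @export
score_genome <- function(model, genome, tracks = list(), gff = NULL,
                         region = NULL, context_window = 75L,
                         chunk_size = 1e6L) {
  snvs <- enumerate_snvs(genome, region)
  n <- nrow(snvs)
  if (n == 0L)
    return(cbind(snvs, data.frame(raw_score = numeric(0), phred = numeric(0))))
  raw <- numeric(n)
  starts <- seq(1L, n, by = as.integer(chunk_size))
  for (st in starts) {
    en <- min(st + as.integer(chunk_size) - 1L, n)
    raw[st:en] <- score_variants(model, snvs[st:en, , drop = FALSE],
                                 tracks = tracks, genome = genome, gff = gff,
                                 context_window = context_window)
  }
  snvs$raw_score <- raw
  snvs$phred <- phred_scale(raw)
  snvs
}

#' Write a score table
#'
#' Coordinate-sorted TSV with header `#Chrom Pos Ref Alt RawScore PHRED`
#' (PHRED printed to 3 decimals), suitable for block compression and
#' position indexing. Input must already be sorted by chromosome block,
#' position, then alternate allele.
#'
#' @param table score table from [score_genome()].
#' @param path output path.
#' @return `write_scores` returns `path` invisibly; `read_scores` the table.
#' @export
write_scores <- function(table, path) {
  if (nrow(table) > 0L) {
    o <- order(match(table$chrom, unique(table$chrom)), table$pos,
               match(table$alt, DNA_BASES))
    if (!identical(o, seq_len(nrow(table))))
      stop2("score table is not sorted by (chrom, pos, alt)")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#Chrom\tPos\tRef\tAlt\tRawScore\tPHRED", con)
  if (nrow(table) > 0L) {
    n <- nrow(table)
    starts <- seq(1L, n, by = 500000L)
    for (st in starts) {
      en <- min(st + 499999L, n)
      writeLines(sprintf("%s\t%d\t%s\t%s\t%.6g\t%.3f",
                         table$chrom[st:en], table$pos[st:en], table$ref[st:en],
                         table$alt[st:en], table$raw_score[st:en],
                         table$phred[st:en]), con)
    }
  }
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, skip = 1L, header = FALSE,
                          col.names = c("chrom", "pos", "ref", "alt",
                                        "raw_score", "phred"),
                          colClasses = c("character", "integer", "character",
                                         "character", "numeric", "numeric"))
  df
}
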