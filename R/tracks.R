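#' Load an annotation track
#'
#' Reads one annotation source into a per-position or per-variant lookup.
#' Interval formats (`bedGraph`, `bed`) use 0-based half-open coordinates on
#' disk and are expanded to 1-based per-position lookups; a `tsv` track is
#' per-variant, keyed on `chrom, pos, ref, alt` (tab-separated, with a
#' header); `vcf-info` pulls a numeric INFO field from a VCF, keyed per
#' variant. Records outside the genome are skipped with a warning and
#' counted in the `skipped` attribute. When intervals overlap, the later
#' record wins.
#'
#' @param path file path.
#' @param format one of `"bedGraph"`, `"bed"`, `"tsv"`, `"vcf-info"`.
#' @param name feature name the track will serve.
#' @param kind `"numeric"` or `"categorical"`.
#' @param genome reference genome (provides chromosome bounds).
#' @param field INFO field name, for `format = "vcf-info"`.
#' @return an `annotation_track`.
#' @export
load_track <- function(path, format = c("bedGraph", "bed", "tsv", "vcf-info"),
                       name, kind = c("numeric", "categorical"), genome,
                       field = NULL) {
  format <- match.arg(format)
  kind <- match.arg(kind)
  if (!file.exists(path)) stop2("track file not found: %s", path)
  lens <- genome_lengths(genome)
  skipped <- 0L
  if (format %in% c("bedGraph", "bed")) {
    gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "bedGraph")
    vals <- if (format == "bedGraph") {
      if (kind != "numeric") stop2("bedGraph tracks are numeric")
      GenomicRanges::mcols(gr)$score
    } else {
      nm <- GenomicRanges::mcols(gr)$name
      if (is.null(nm)) stop2("BED track %s lacks a name column for its levels", path)
      as.character(nm)
    }
    data <- lapply(lens, function(n) {
      if (kind == "numeric") rep(NA_real_, n) else rep(NA_character_, n)
    })
    ch <- as.character(GenomicRanges::seqnames(gr))
    st <- GenomicRanges::start(gr)  # rtracklayer converts to 1-based inclusive
    en <- GenomicRanges::end(gr)
    ok <- ch %in% names(lens) & st >= 1L & en <= unname(lens[match(ch, names(lens))])
    ok[is.na(ok)] <- FALSE
    skipped <- sum(!ok)
    for (chn in unique(ch[ok])) {
      sel <- which(ok & ch == chn)
      w <- en[sel] - st[sel] + 1L
      pos <- sequence(w, from = st[sel])
      data[[chn]][pos] <- rep(vals[sel], w)  # later records win on overlap
    }
    if (skipped > 0L)
      warn2("track %s: skipped %d record(s) outside the genome", name, skipped)
    tr <- list(name = name, kind = kind, resolution = "per_position", data = data)
  } else if (format == "tsv") {
    df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            comment.char = "")
    names(df) <- sub("^X\\.", "", names(df))  # tolerate a '#'-prefixed header
    need <- c("chrom", "pos", "ref", "alt", "value")
    if (!all(need %in% names(df)))
      stop2("per-variant TSV %s must have columns %s", path, paste(need, collapse = ", "))
    ok <- df$chrom %in% names(lens) & df$pos >= 1L &
      df$pos <= lens[match(df$chrom, names(lens))]
    skipped <- sum(!ok)
    if (skipped > 0L)
      warn2("track %s: skipped %d record(s) outside the genome", name, skipped)
    df <- df[ok, , drop = FALSE]
    val <- if (kind == "numeric") as.numeric(df$value) else as.character(df$value)
    tr <- list(name = name, kind = kind, resolution = "per_variant",
               data = data.frame(chrom = df$chrom, pos = as.integer(df$pos),
                                 from = toupper(df$ref), to = toupper(df$alt),
                                 value = val, stringsAsFactors = FALSE))
  } else {  # vcf-info
    if (is.null(field)) stop2("format 'vcf-info' requires a field name")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    raw <- vcfR::extract.info(v, field)
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    vals <- strsplit(ifelse(is.na(raw), "", raw), ",", fixed = TRUE)
    n_alt <- lengths(alts)
    vals <- mapply(function(v, n) c(v, rep(NA_character_, max(0L, n - length(v))))[seq_len(n)],
                   vals, n_alt, SIMPLIFY = FALSE)
    df <- data.frame(chrom = rep(fix$CHROM, n_alt), pos = rep(as.integer(fix$POS), n_alt),
                     from = rep(toupper(fix$REF), n_alt), to = toupper(unlist(alts)),
                     value = suppressWarnings(as.numeric(unlist(vals))),
                     stringsAsFactors = FALSE)
    ok <- df$chrom %in% names(lens) & df$pos >= 1L &
      df$pos <= lens[match(df$chrom, names(lens))]
    skipped <- sum(!ok)
    if (skipped > 0L)
      warn2("track %s: skipped %d record(s) outside the genome", name, skipped)
    tr <- list(name = name, kind = kind, resolution = "per_variant",
               data = df[ok, , drop = FALSE])
  }
  attr(tr, "skipped") <- skipped
  structure(tr, class = "annotation_track")
}

#' Look up track values for variants
#'
#' Per-position tracks key on `(chrom, pos)`; per-variant tracks on
#' `(chrom, pos, from, to)`. Missing keys return `NA`.
#'
#' @param track an `annotation_track`.
#' @param variants SNV data frame (`chrom, pos, from, to`).
#' @return vector of values aligned with `variants` rows.
#' @export
track_lookup <- function(track, variants) {
  check_snv_frame(variants)
  if (track$resolution == "per_position") {
    out <- if (track$kind == "numeric") rep(NA_real_, nrow(variants))
           else rep(NA_character_, nrow(variants))
    for (ch in unique(variants$chrom)) {
      v <- track$data[[ch]]
      sel <- variants$chrom == ch
      if (!is.null(v)) out[sel] <- v[variants$pos[sel]]
    }
    out
  } else {
    key <- paste(variants$chrom, variants$pos, variants$from, variants$to)
    tk <- paste(track$data$chrom, track$data$pos, track$data$from, track$data$to)
    track$data$value[match(key, tk)]
  }
}

#' Write a bedGraph track
#'
#' One interval per value run is not attempted; each position becomes a
#' single 0-based half-open interval. Used by the fixture generator.
#'
#' @param df data frame `chrom, pos, value` (1-based positions).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(df, path) {
  o <- order(df$chrom, df$pos)
  df <- df[o, ]
  writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$pos - 1L, df$pos,
                     sprintf("%.6g", df$value)), path)
  invisible(path)
}
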