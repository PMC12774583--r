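#' Project the inferred ancestral sequence onto reference coordinates
#'
#' Walks every alignment block, finds the reference-species row, and records
#' the aligned ancestral base at each reference position. The ancestral base
#' is taken either from an explicit ancestor row (`ancestor_label`, as
#' ancestral-reconstruction alignments emit) or from one or more outgroup
#' rows combined by `strict_consensus` (all outgroups must agree) or
#' `majority` (modal base; ties ambiguous).
#'
#' Positions covered by no block stay unaligned. A gap or `N` in the
#' ancestor column makes the position unaligned (no information), while two
#' blocks asserting different concrete bases for the same position mark it
#' ambiguous; both states are excluded from variant calling downstream. A
#' concrete base from one block is kept when another block only shows a gap.
#' Minus-strand reference rows are converted to forward coordinates and the
#' aligned column characters complemented.
#'
#' @param blocks list of MAF blocks from [parse_maf()].
#' @param genome reference genome ([read_genome()]).
#' @param ref_species species label of the reference rows.
#' @param ancestor_label species label of the ancestor rows (primary mode).
#' @param outgroup_labels character vector of outgroup species labels
#'   (fallback mode, used when `ancestor_label` is `NULL`).
#' @param strategy outgroup combination rule, `"strict_consensus"` or
#'   `"majority"`.
#' @return an `ancestor_map`: named list (one element per chromosome) of
#'   character vectors over `A C G T`, `"."` (unaligned) and `"?"`
#'   (ambiguous), indexed by 1-based position.
#' @export
build_ancestor_map <- function(blocks, genome, ref_species,
                               ancestor_label = NULL, outgroup_labels = NULL,
                               strategy = c("strict_consensus", "majority")) {
  strategy <- match.arg(strategy)
  if (is.null(ancestor_label) && is.null(outgroup_labels))
    stop2("one of ancestor_label or outgroup_labels is required")
  lens <- genome_lengths(genome)
  map <- lapply(lens, function(n) rep(UNALIGNED, n))
  ref_seen <- FALSE
  anc_seen <- FALSE
  for (b in blocks) {
    ref_rows <- which(b$species == ref_species)
    if (length(ref_rows) == 0L) next
    ref_seen <- TRUE
    rrow <- b[ref_rows[1L], ]
    if (!rrow$chrom %in% names(map)) next
    rp <- row_positions(rrow)
    if (!is.null(ancestor_label)) {
      arow <- which(b$species == ancestor_label)
      if (length(arow) == 0L) next
      anc_seen <- TRUE
      ach <- seq_chars(b$text[arow[1L]])
      v <- ifelse(ach %in% DNA_BASES, ach, UNALIGNED)
    } else {
      orows <- which(b$species %in% outgroup_labels)
      if (length(orows) == 0L) next
      anc_seen <- TRUE
      och <- lapply(orows, function(i) seq_chars(b$text[i]))
      v <- combine_outgroups(och, strategy)
    }
    use <- rp$nongap
    pos <- rp$pos[use]
    val <- v[use]
    if (rrow$strand == "-") {
      concrete <- val %in% DNA_BASES
      val[concrete] <- comp_base(val[concrete])
    }
    cur <- map[[rrow$chrom]][pos]
    newv <- ifelse(val == UNALIGNED, cur,
            ifelse(val == AMBIGUOUS | cur == AMBIGUOUS, AMBIGUOUS,
            ifelse(cur == UNALIGNED, val,
            ifelse(cur == val, cur, AMBIGUOUS))))
    map[[rrow$chrom]][pos] <- newv
  }
  if (!ref_seen)
    stop2("reference species '%s' absent from every alignment block", ref_species)
  if (!anc_seen) {
    if (!is.null(ancestor_label))
      stop2("ancestor label '%s' absent from every alignment block", ancestor_label)
    stop2("no outgroup rows (%s) found in any alignment block",
          paste(outgroup_labels, collapse = ", "))
  }
  structure(map, class = "ancestor_map")
}

# per-column combination of outgroup characters into an ancestral call
combine_outgroups <- function(char_lists, strategy) {
  m <- do.call(rbind, char_lists)
  apply(m, 2L, function(col) {
    bases <- col[col %in% DNA_BASES]
    if (length(bases) == 0L) return(UNALIGNED)
    if (strategy == "strict_consensus") {
      if (length(bases) < length(col)) return(UNALIGNED)  # a gap/N breaks consensus
      if (length(unique(bases)) == 1L) bases[1L] else AMBIGUOUS
    } else {
      tab <- table(bases)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1L) top else AMBIGUOUS
    }
  })
}

#' Ancestral-coverage statistics
#'
#' Fraction of reference positions carrying a concrete ancestral base
#' (neither unaligned nor ambiguous), per chromosome and genome-wide.
#'
#' @param map an `ancestor_map`.
#' @param genome the matching reference genome.
#' @return list with `by_chrom` (data frame: chrom, length, covered,
#'   fraction) and `total` (overall fraction).
#' @export
coverage_stats <- function(map, genome) {
  lens <- genome_lengths(genome)
  extra <- setdiff(names(map), names(lens))
  if (length(extra) > 0L)
    stop2("ancestor map chromosome(s) absent from genome: %s",
          paste(extra, collapse = ", "))
  covered <- vapply(names(lens), function(ch) {
    v <- map[[ch]]
    if (is.null(v)) 0L else sum(v %in% DNA_BASES)
  }, integer(1))
  df <- data.frame(chrom = names(lens), length = as.integer(lens),
                   covered = covered, fraction = covered / as.numeric(lens),
                   row.names = NULL, stringsAsFactors = FALSE)
  list(by_chrom = df, total = sum(covered) / sum(as.numeric(lens)))
}

#' Serialise an ancestor map
#'
#' `"fasta"` writes one record per chromosome with `.` for unaligned and
#' `?` for ambiguous positions; `"tsv"` writes `chrom pos allele` rows for
#' positions carrying information.
#'
#' @param map an `ancestor_map`.
#' @param path output path.
#' @param format `"fasta"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_ancestor_map <- function(map, path, format = c("fasta", "tsv")) {
  format <- match.arg(format)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    for (ch in names(map)) {
      writeLines(paste0(">", ch), con)
      s <- paste(map[[ch]], collapse = "")
      starts <- seq(1L, nchar(s), by = 80L)
      writeLines(substring(s, starts, pmin(starts + 79L, nchar(s))), con)
    }
  } else {
    writeLines("#chrom\tpos\tallele", con)
    for (ch in names(map)) {
      v <- map[[ch]]
      keep <- which(v != UNALIGNED)
      if (length(keep) > 0L)
        writeLines(paste(ch, keep, v[keep], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a serialised ancestor map
#'
#' Auto-detects the two formats written by [write_ancestor_map()]. The
#' genome provides chromosome names and lengths for the TSV form.
#'
#' @param path path written by [write_ancestor_map()].
#' @param genome the matching reference genome.
#' @return an `ancestor_map`.
#' @export
read_ancestor_map <- function(path, genome) {
  first <- readLines(path, n = 1L)
  lens <- genome_lengths(genome)
  if (startsWith(first, ">")) {
    lines <- readLines(path)
    hdr <- grep("^>", lines)
    map <- list()
    for (i in seq_along(hdr)) {
      ch <- sub("^>", "", lines[hdr[i]])
      to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
      s <- paste(lines[(hdr[i] + 1L):to], collapse = "")
      map[[ch]] <- strsplit(s, "", fixed = TRUE)[[1]]
    }
  } else {
    df <- utils::read.delim(path, comment.char = "", skip = 1L, header = FALSE,
                            col.names = c("chrom", "pos", "allele"),
                            colClasses = c("character", "integer", "character"))
    map <- lapply(lens, function(n) rep(UNALIGNED, n))
    for (ch in unique(df$chrom)) {
      sel <- df$chrom == ch
      map[[ch]][df$pos[sel]] <- df$allele[sel]
    }
  }
  bad <- setdiff(names(map), names(lens))
  if (length(bad) > 0L)
    stop2("ancestor map chromosome(s) absent from genome: %s", paste(bad, collapse = ", "))
  structure(map[names(lens)[names(lens) %in% names(map)]], class = "ancestor_map")
}
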