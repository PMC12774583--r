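#' Call derived (proxy-neutral) variants
#'
#' A derived variant marks a position where the reference genome carries a
#' base different from the inferred ancestral base, i.e. a substitution that
#' ran to (near) fixation since the common ancestor. The ancestral base is
#' the `from` allele and the reference base the `to` allele. When population
#' frequencies are supplied, positions that are still polymorphic are kept
#' only if the reference (derived) allele frequency, computed as one minus
#' the sum of alternate-allele frequencies at the position, exceeds
#' `af_fixed`; positions absent from the population table count as fixed.
#'
#' @param genome reference genome ([read_genome()]).
#' @param anc `ancestor_map` built against the same genome.
#' @param pop optional `population_af` table ([read_population_vcf()]).
#' @param af_fixed minimum derived-allele frequency for a polymorphic site
#'   to count as (nearly) fixed; in (0, 1].
#' @return SNV data frame: `chrom, pos, from, to, class ("derived"), af`
#'   (`af` is the derived-allele frequency where known, `NA` otherwise).
#' @export
call_derived_variants <- function(genome, anc, pop = NULL, af_fixed = 0.9) {
  if (!is.numeric(af_fixed) || length(af_fixed) != 1L || af_fixed <= 0 || af_fixed > 1)
    stop2("af_fixed must be a single number in (0, 1], got %s", format(af_fixed))
  out <- list()
  for (ch in names(anc)) {
    a <- anc[[ch]]
    r <- seq_chars(unclass(genome)[[ch]])
    if (length(a) != length(r))
      stop2("ancestor map and genome disagree on length of %s", ch)
    idx <- which(a %in% DNA_BASES & r %in% DNA_BASES & a != r)
    if (length(idx) == 0L) next
    out[[ch]] <- data.frame(chrom = ch, pos = idx, from = a[idx], to = r[idx],
                            class = "derived", af = NA_real_,
                            stringsAsFactors = FALSE)
  }
  snvs <- if (length(out) == 0L) empty_snvs() else do.call(rbind, out)
  rownames(snvs) <- NULL
  if (!is.null(pop) && nrow(snvs) > 0L && nrow(pop) > 0L) {
    raf <- ref_af_by_pos(pop)
    hit <- match(paste(snvs$chrom, snvs$pos, sep = ":"), names(raf))
    snvs$af[!is.na(hit)] <- raf[hit[!is.na(hit)]]
    snvs <- snvs[is.na(snvs$af) | snvs$af > af_fixed, ]
    rownames(snvs) <- NULL
  }
  snvs
}

#' Estimate local ancestor-to-reference substitution rates
#'
#' Tiles each chromosome into windows and, at every position where both the
#' ancestral and reference base are concrete, counts the ancestral base;
#' where they differ it also counts the substitution type. The per-window
#' rate of substitution `from -> to` is `count / ancestral base count`.
#' Windows with fewer aligned bases than `min_window_bases` are flagged and
#' fall back to the genome-wide rate matrix when queried.
#'
#' @param genome reference genome.
#' @param anc `ancestor_map` for the same genome.
#' @param window_size window width in bp.
#' @param min_window_bases minimum aligned bases for a window to use its
#'   own rates.
#' @return a `mutation_rate_model`.
#' @export
estimate_mutation_rates <- function(genome, anc, window_size = 1e5,
                                    min_window_bases = 1000) {
  if (!is.numeric(window_size) || window_size < 1)
    stop2("window_size must be >= 1")
  window_size <- as.integer(window_size)
  pair_levels <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  chroms <- list()
  g_counts <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  g_bases <- stats::setNames(numeric(4), DNA_BASES)
  total_aligned <- 0
  for (ch in names(anc)) {
    a <- anc[[ch]]
    r <- seq_chars(unclass(genome)[[ch]])
    n <- length(r)
    nwin <- max(1L, as.integer(ceiling(n / window_size)))
    aligned <- a %in% DNA_BASES & r %in% DNA_BASES
    total_aligned <- total_aligned + sum(aligned)
    win <- ((which(aligned) - 1L) %/% window_size) + 1L
    base_counts <- table(factor(a[aligned], levels = DNA_BASES),
                         factor(win, levels = seq_len(nwin)))
    diffs <- aligned & a != r
    wind <- ((which(diffs) - 1L) %/% window_size) + 1L
    sub_counts <- table(factor(paste0(a[diffs], r[diffs]), levels = pair_levels),
                        factor(wind, levels = seq_len(nwin)))
    counts <- array(as.numeric(sub_counts), dim = c(4, 4, nwin),
                    dimnames = list(DNA_BASES, DNA_BASES, NULL))
    bc <- matrix(as.numeric(base_counts), nrow = 4,
                 dimnames = list(DNA_BASES, NULL))
    chroms[[ch]] <- list(counts = counts, base_counts = bc,
                         fallback = colSums(bc) < min_window_bases,
                         n_windows = nwin)
    g_counts <- g_counts + apply(counts, c(1, 2), sum)
    g_bases <- g_bases + rowSums(bc)
  }
  if (total_aligned == 0)
    stop2("no aligned positions: cannot estimate a mutation rate model")
  structure(list(window_size = window_size, min_window_bases = min_window_bases,
                 chroms = chroms, genome_counts = g_counts, genome_bases = g_bases),
            class = "mutation_rate_model")
}

# genome-wide 4x4 rate matrix of a model
genome_rates <- function(model) {
  r <- sweep(model$genome_counts, 1, pmax(model$genome_bases, 1), "/")
  r[model$genome_bases == 0, ] <- 0
  r
}

#' Per-window rate matrix
#'
#' Returns the 4x4 substitution-rate matrix of one window, substituting the
#' genome-wide matrix for sparse windows.
#'
#' @param model a `mutation_rate_model`.
#' @param chrom chromosome name.
#' @param window 1-based window index.
#' @return 4x4 numeric matrix, rows `from`, columns `to`.
#' @export
rate_matrix <- function(model, chrom, window) {
  cm <- model$chroms[[chrom]]
  if (is.null(cm)) stop2("no rate model for chromosome %s", chrom)
  if (window < 1L || window > cm$n_windows) stop2("window %d out of range", window)
  if (cm$fallback[window]) return(genome_rates(model))
  bc <- cm$base_counts[, window]
  r <- sweep(cm$counts[, , window], 1, pmax(bc, 1), "/")
  r[bc == 0, ] <- 0
  r
}

#' @export
print.mutation_rate_model <- function(x, ...) {
  cat(sprintf("mutation_rate_model: %d chromosome(s), window %d bp\n",
              length(x$chroms), x$window_size))
  cat("genome-wide rates:\n")
  print(round(genome_rates(x), 6))
  invisible(x)
}

#' Simulate proxy-deleterious variants
#'
#' Draws `n_target` single-nucleotide variants without replacement over
#' (position, alternate allele) pairs at ancestrally aligned positions. The
#' sampling weight of substituting reference base `b` by `t` at position `p`
#' is the local window rate `r[b, t]` from `model`, so the draw mirrors the
#' neutral substitution spectrum free of selective filtering. Candidates
#' whose alternate allele segregates in the population above `af_exclude`
#' are removed (such alleles are unlikely to be deleterious), as are
#' candidates listed in `exclude` (typically the back-mutations to the
#' ancestral allele at derived-variant positions, so the two training
#' classes can never contradict each other).
#'
#' Sampling uses exponential race keys (`rexp(n)/weight`, keep the
#' `n_target` smallest), a weighted without-replacement scheme that is fully
#' deterministic given `seed`.
#'
#' @param model `mutation_rate_model` from [estimate_mutation_rates()].
#' @param genome reference genome.
#' @param anc `ancestor_map`.
#' @param n_target number of variants to draw.
#' @param pop optional `population_af` table.
#' @param af_exclude candidates with population AF above this are excluded.
#' @param seed integer seed controlling the draw.
#' @param exclude optional data frame `chrom, pos, to` (or an SNV table
#'   whose `to` holds the allele to ban) of candidates to remove.
#' @return SNV data frame `chrom, pos, from, to, class ("simulated"), af`,
#'   sorted by position.
#' @export
simulate_variants <- function(model, genome, anc, n_target, pop = NULL,
                              af_exclude = 0.1, seed = 1L, exclude = NULL) {
  if (n_target < 0) stop2("n_target must be >= 0")
  n_target <- as.integer(n_target)
  chrom_v <- character(0); pos_v <- integer(0); from_v <- character(0)
  to_v <- character(0); w_v <- numeric(0)
  for (ch in names(anc)) {
    a <- anc[[ch]]
    r <- seq_chars(unclass(genome)[[ch]])
    aligned <- which(a %in% DNA_BASES & r %in% DNA_BASES)
    if (length(aligned) == 0L) next
    refb <- r[aligned]
    ref_i <- match(refb, DNA_BASES)
    win <- ((aligned - 1L) %/% model$window_size) + 1L
    cm <- model$chroms[[ch]]
    if (is.null(cm)) stop2("rate model does not cover chromosome %s", ch)
    # effective per-window rate array with fallback substituted
    eff <- cm$counts
    bc <- cm$base_counts
    gw <- genome_rates(model)
    for (wdx in seq_len(cm$n_windows)) {
      if (cm$fallback[wdx]) {
        eff[, , wdx] <- gw
      } else {
        b <- bc[, wdx]
        m <- sweep(cm$counts[, , wdx], 1, pmax(b, 1), "/")
        m[b == 0, ] <- 0
        eff[, , wdx] <- m
      }
    }
    for (alt_i in seq_along(DNA_BASES)) {
      alt <- DNA_BASES[alt_i]
      keep <- ref_i != alt_i
      if (!any(keep)) next
      w <- eff[cbind(ref_i[keep], alt_i, win[keep])]
      nz <- w > 0
      if (!any(nz)) next
      sel <- which(keep)[nz]
      chrom_v <- c(chrom_v, rep(ch, length(sel)))
      pos_v <- c(pos_v, aligned[sel])
      from_v <- c(from_v, refb[sel])
      to_v <- c(to_v, rep(alt, length(sel)))
      w_v <- c(w_v, w[nz])
    }
  }
  if (length(w_v) == 0L) {
    if (n_target == 0L) return(empty_snvs())
    stop2("all-zero rate model: no candidate substitutions have positive weight")
  }
  drop <- rep(FALSE, length(w_v))
  af_v <- rep(NA_real_, length(w_v))
  if (!is.null(pop) && nrow(pop) > 0L) {
    hit <- match(snv_key(chrom_v, pos_v, to_v), snv_key(pop$chrom, pop$pos, pop$alt))
    af_v[!is.na(hit)] <- pop$af[hit[!is.na(hit)]]
    drop <- drop | (!is.na(af_v) & af_v > af_exclude)
  }
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    ex_to <- if ("to" %in% names(exclude)) exclude$to else exclude$alt
    drop <- drop | snv_key(chrom_v, pos_v, to_v) %in%
      snv_key(exclude$chrom, exclude$pos, ex_to)
  }
  keep <- which(!drop)
  if (n_target == 0L) return(empty_snvs())
  if (length(keep) < n_target)
    stop2("candidate pool (%d after exclusions) smaller than n_target (%d)",
          length(keep), n_target)
  sel <- with_seed(seed, {
    keys <- stats::rexp(length(keep)) / w_v[keep]
    keep[order(keys)[seq_len(n_target)]]
  })
  out <- data.frame(chrom = chrom_v[sel], pos = pos_v[sel], from = from_v[sel],
                    to = to_v[sel], class = "simulated", af = af_v[sel],
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, names(anc)), out$pos, out$to), ]
  rownames(out) <- NULL
  out
}

#' Read/write SNV tables
#'
#' Plain TSV serialisation of the package's variant tables
#' (`chrom pos from to class af`).
#'
#' @param snvs SNV data frame.
#' @param path file path.
#' @return `write_snvs` returns `path` invisibly; `read_snvs` the table.
#' @export
write_snvs <- function(snvs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tfrom\tto\tclass\taf", con)
  if (nrow(snvs) > 0L)
    writeLines(paste(snvs$chrom, snvs$pos, snvs$from, snvs$to, snvs$class,
                     ifelse(is.na(snvs$af), "NA", sprintf("%.10g", snvs$af)),
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_snvs
#' @export
read_snvs <- function(path) {
  df <- utils::read.delim(path, skip = 1L, header = FALSE,
                          col.names = c("chrom", "pos", "from", "to", "class", "af"),
                          colClasses = c("character", "integer", "character",
                                         "character", "character", "numeric"))
  if (nrow(df) == 0L) return(empty_snvs())
  df
}

#' Serialise a mutation rate model as JSON
#'
#' @param model a `mutation_rate_model`.
#' @param path file path.
#' @return `write_rate_model` returns `path` invisibly; `read_rate_model`
#'   the model.
#' @export
write_rate_model <- function(model, path) {
  obj <- list(window_size = model$window_size,
              min_window_bases = model$min_window_bases,
              genome_counts = model$genome_counts,
              genome_bases = as.list(model$genome_bases),
              chroms = lapply(model$chroms, function(cm) list(
                n_windows = cm$n_windows,
                counts = as.vector(cm$counts),
                base_counts = as.vector(cm$base_counts),
                fallback = cm$fallback)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rate_model
#' @export
read_rate_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  chroms <- lapply(obj$chroms, function(cm) {
    nw <- as.integer(cm$n_windows)
    list(counts = array(as.numeric(cm$counts), dim = c(4, 4, nw),
                        dimnames = list(DNA_BASES, DNA_BASES, NULL)),
         base_counts = matrix(as.numeric(cm$base_counts), nrow = 4,
                              dimnames = list(DNA_BASES, NULL)),
         fallback = as.logical(cm$fallback), n_windows = nw)
  })
  gb <- unlist(obj$genome_bases)[DNA_BASES]
  gc <- matrix(as.numeric(as.matrix(obj$genome_counts)), 4, 4,
               dimnames = list(DNA_BASES, DNA_BASES))
  structure(list(window_size = as.integer(obj$window_size),
                 min_window_bases = obj$min_window_bases,
                 chroms = chroms, genome_counts = gc, genome_bases = gb),
            class = "mutation_rate_model")
}
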