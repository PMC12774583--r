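#' Configuration of the synthetic-fixture generator
#'
#' Bundles every knob of the toy study system the generator emulates: an
#' i.i.d. reference genome, an ancestral sequence at a chosen divergence
#' (transition/transversion ratio `ts_tv`) with unaligned gap spans, a
#' population of biallelic sites with Beta-distributed allele frequencies,
#' and class-dependent planted annotation features (Gaussian numeric effects
#' and a class-conditional categorical) with injected missingness. Defaults
#' describe the standard toy study: a 1 Mb single-chromosome genome at ~1%
#' ancestor/reference divergence, 2,000 polymorphic sites, four numeric and
#' one categorical planted feature.
#'
#' @param genome_length total genome length in bp.
#' @param n_chroms number of chromosomes (length split evenly).
#' @param base_probs base composition (A, C, G, T).
#' @param divergence per-site probability that the ancestral base differs
#'   from the reference.
#' @param ts_tv transition/transversion ratio of those differences.
#' @param gap_fraction fraction of the ancestor left unaligned.
#' @param mean_gap_len mean length of unaligned spans.
#' @param block_size MAF block width in bp.
#' @param minus_strand_block index of the per-chromosome block emitted on
#'   the minus strand (0 = none).
#' @param outgroup_divergence extra divergence of the outgroup row beyond
#'   the ancestor.
#' @param n_pop_sites number of polymorphic sites in the population VCF.
#' @param af_beta shape parameters of the Beta allele-frequency spectrum.
#' @param beta planted numeric effect sizes (class-1 means).
#' @param noise_sd within-class standard deviation of numeric features.
#' @param cat_levels labels of the planted categorical feature.
#' @param cat_probs 2-row matrix of class-conditional level probabilities
#'   (row 1 = derived, row 2 = simulated).
#' @param missingness per-feature probability that a planted value is
#'   withheld.
#' @param ref_species,ancestor_label,outgroup_label row labels in the MAF.
#' @param seed master seed; every generator output is a deterministic
#'   function of it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(genome_length = 1e6, n_chroms = 1L,
                         base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         divergence = 0.01, ts_tv = 2, gap_fraction = 0.05,
                         mean_gap_len = 200, block_size = 10000L,
                         minus_strand_block = 2L, outgroup_divergence = 0.01,
                         n_pop_sites = 2000L, af_beta = c(0.5, 0.5),
                         beta = c(f1 = 1.0, f2 = 0.8, f3 = 0.5, f4 = 0.3),
                         noise_sd = 1.0,
                         cat_levels = c("low", "mid", "high"),
                         cat_probs = rbind(derived = c(0.5, 0.3, 0.2),
                                           simulated = c(0.2, 0.3, 0.5)),
                         missingness = 0.1, ref_species = "ref",
                         ancestor_label = "anc", outgroup_label = "out",
                         seed = 1L) {
  if (genome_length < 1) stop2("genome_length must be >= 1")
  if (abs(sum(base_probs) - 1) > 1e-8) stop2("base_probs must sum to 1")
  if (divergence < 0 || divergence >= 1) stop2("divergence must be in [0, 1)")
  if (any(af_beta <= 0)) stop2("Beta AF parameters must be positive")
  if (ncol(cat_probs) != length(cat_levels))
    stop2("cat_probs must have one column per categorical level")
  structure(list(genome_length = as.integer(genome_length),
                 n_chroms = as.integer(n_chroms), base_probs = base_probs,
                 divergence = divergence, ts_tv = ts_tv,
                 gap_fraction = gap_fraction, mean_gap_len = mean_gap_len,
                 block_size = as.integer(block_size),
                 minus_strand_block = as.integer(minus_strand_block),
                 outgroup_divergence = outgroup_divergence,
                 n_pop_sites = as.integer(n_pop_sites), af_beta = af_beta,
                 beta = beta, noise_sd = noise_sd, cat_levels = cat_levels,
                 cat_probs = cat_probs, missingness = missingness,
                 ref_species = ref_species, ancestor_label = ancestor_label,
                 outgroup_label = outgroup_label, seed = as.integer(seed)),
            class = "synth_config")
}

# transition partner of each base
transition_of <- c(A = "G", G = "A", C = "T", T = "C")

# per-row substitution distribution given a mutation happens:
# transitions:all-transversions = ts_tv, so P(transition) = ts_tv/(1 + ts_tv)
# and each of the two transversion partners gets half the remainder
mutate_bases <- function(bases, ts_tv) {
  p_ts <- ts_tv / (1 + ts_tv)
  u <- stats::runif(length(bases))
  out <- character(length(bases))
  ts <- u < p_ts
  out[ts] <- transition_of[bases[ts]]
  tv <- !ts
  if (any(tv)) {
    pick <- u[tv] >= (p_ts + (1 - p_ts) / 2)  # second transversion partner
    tvsets <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
    m <- do.call(rbind, tvsets[bases[tv]])
    out[tv] <- m[cbind(seq_len(sum(tv)), pick + 1L)]
  }
  out
}

#' Generate a toy reference genome
#'
#' i.i.d. bases drawn from the configured composition; deterministic for a
#' given seed.
#'
#' @param cfg a [synth_config()].
#' @return a `genome` (named character vector).
#' @export
make_genome <- function(cfg) {
  per <- rep(cfg$genome_length %/% cfg$n_chroms, cfg$n_chroms)
  per[cfg$n_chroms] <- per[cfg$n_chroms] + cfg$genome_length %% cfg$n_chroms
  g <- with_seed(cfg$seed, {
    vapply(per, function(n)
      paste(sample(DNA_BASES, n, replace = TRUE, prob = cfg$base_probs),
            collapse = ""), character(1))
  })
  names(g) <- paste0("chr", seq_len(cfg$n_chroms))
  class(g) <- c("genome", "character")
  g
}

#' Evolve an ancestor and serialise the alignment as MAF
#'
#' For every reference position an ancestral base is planted: identical to
#' the reference except at `divergence` of sites, where it is substituted
#' with the configured transition/transversion mix. Unaligned spans
#' (geometric lengths around `mean_gap_len`, totalling about `gap_fraction`
#' of the genome) become gaps in the ancestor and outgroup rows. The genome
#' is tiled into blocks of `block_size`; one block per chromosome is written
#' on the minus strand to exercise strand arithmetic. An outgroup row (the
#' ancestor mutated further) accompanies every block so the
#' outgroup-consensus mode can also be tested.
#'
#' @param genome output of [make_genome()].
#' @param cfg the same [synth_config()].
#' @return list: `blocks` (MAF blocks), `ancestor_truth` (per-chromosome
#'   character vectors with `"."` at unaligned positions), `diffs` (data
#'   frame `chrom, pos, anc, ref` of planted aligned differences).
#' @export
make_ancestor_and_maf <- function(genome, cfg) {
  lens <- genome_lengths(genome)
  blocks <- list()
  anc_truth <- list()
  diffs <- list()
  with_seed(cfg$seed + 1L, {
    for (ch in names(lens)) {
      n <- lens[[ch]]
      r <- seq_chars(unclass(genome)[[ch]])
      anc <- r
      mut <- which(stats::runif(n) < cfg$divergence)
      if (length(mut) > 0L) anc[mut] <- mutate_bases(r[mut], cfg$ts_tv)
      # unaligned spans
      aligned <- rep(TRUE, n)
      n_gaps <- round(n * cfg$gap_fraction / cfg$mean_gap_len)
      if (n_gaps > 0L) {
        gs <- sort(sample.int(n, n_gaps))
        gl <- stats::rgeom(n_gaps, 1 / cfg$mean_gap_len) + 1L
        for (i in seq_len(n_gaps)) aligned[gs[i]:min(n, gs[i] + gl[i] - 1L)] <- FALSE
      }
      outg <- anc
      omut <- which(stats::runif(n) < cfg$outgroup_divergence)
      if (length(omut) > 0L) outg[omut] <- mutate_bases(anc[omut], cfg$ts_tv)
      anc_gapped <- ifelse(aligned, anc, "-")
      outg_gapped <- ifelse(aligned, outg, "-")
      truth <- ifelse(aligned, anc, UNALIGNED)
      anc_truth[[ch]] <- truth
      d <- which(aligned & anc != r)
      diffs[[ch]] <- data.frame(chrom = rep(ch, length(d)), pos = d,
                                anc = anc[d], ref = r[d],
                                stringsAsFactors = FALSE)
      # tile into blocks; track cumulative ungapped ancestor/outgroup offsets
      anc_len <- sum(aligned)
      anc_off <- 0L; out_off <- 0L
      starts <- seq(1L, n, by = cfg$block_size)
      for (bi in seq_along(starts)) {
        s <- starts[bi]; e <- min(n, s + cfg$block_size - 1L)
        ref_txt <- paste(r[s:e], collapse = "")
        anc_txt <- paste(anc_gapped[s:e], collapse = "")
        out_txt <- paste(outg_gapped[s:e], collapse = "")
        a_sz <- sum(aligned[s:e])
        blk <- data.frame(
          src = paste(c(cfg$ref_species, cfg$ancestor_label, cfg$outgroup_label),
                      ch, sep = "."),
          species = c(cfg$ref_species, cfg$ancestor_label, cfg$outgroup_label),
          chrom = ch,
          start = c(s - 1L, anc_off, out_off),
          size = c(e - s + 1L, a_sz, a_sz),
          strand = "+",
          src_size = c(n, anc_len, anc_len),
          text = c(ref_txt, anc_txt, out_txt),
          stringsAsFactors = FALSE)
        if (bi == cfg$minus_strand_block) {
          blk$text <- revcomp_str(blk$text)
          blk$start <- blk$src_size - blk$start - blk$size
          blk$strand <- "-"
        }
        blocks[[length(blocks) + 1L]] <- blk
        anc_off <- anc_off + a_sz
        out_off <- out_off + a_sz
      }
    }
  })
  list(blocks = blocks,
       ancestor_truth = structure(anc_truth, class = "ancestor_map"),
       diffs = {
         d <- do.call(rbind, diffs)
         rownames(d) <- NULL
         d
       })
}

#' Generate a population VCF with a Beta allele-frequency spectrum
#'
#' Places `n_pop_sites` biallelic SNPs uniformly over the genome (alternate
#' allele never the reference base) with frequencies drawn from
#' `Beta(af_beta[1], af_beta[2])`. Frequencies are rounded to the precision
#' printed in the VCF so the written file and the returned truth table agree
#' exactly.
#'
#' @param genome output of [make_genome()].
#' @param cfg the same [synth_config()].
#' @return `population_af` data frame (`chrom, pos, ref, alt, af`), sorted.
#' @export
make_population_vcf <- function(genome, cfg) {
  lens <- genome_lengths(genome)
  total <- sum(lens)
  df <- with_seed(cfg$seed + 2L, {
    gpos <- sort(sample.int(total, min(cfg$n_pop_sites, total)))
    bnd <- cumsum(as.numeric(lens))
    chi <- findInterval(gpos - 1, c(0, bnd), rightmost.closed = TRUE)
    pos <- gpos - c(0, bnd)[chi]
    ch <- names(lens)[chi]
    refb <- vapply(seq_along(pos), function(i) ref_base_at(genome, ch[i], pos[i]),
                   character(1))
    keep <- refb %in% DNA_BASES
    ch <- ch[keep]; pos <- pos[keep]; refb <- refb[keep]
    alt <- vapply(refb, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
    af <- as.numeric(sprintf("%.6g", stats::rbeta(length(pos), cfg$af_beta[1],
                                                  cfg$af_beta[2])))
    data.frame(chrom = ch, pos = as.integer(pos), ref = refb, alt = alt,
               af = af, stringsAsFactors = FALSE)
  })
  df <- df[order(match(df$chrom, names(lens)), df$pos), ]
  rownames(df) <- NULL
  class(df) <- c("population_af", "data.frame")
  df
}

#' Plant class-dependent annotation tracks for a variant set
#'
#' For each labelled variant, numeric feature `j` is drawn
#' `Normal(y * beta[j], noise_sd)` (class `y` = 1 for simulated variants)
#' and the categorical level from the class-conditional probabilities;
#' a `missingness` fraction of values is withheld per feature. Numeric
#' features are emitted as per-position bedGraph tracks (when variants of
#' both classes share a position, the first variant's class wins — a rare
#' collision at toy scale); the categorical feature as a per-variant TSV.
#' Alongside, the Bayes-optimal AUC of the generative model — the AUC of the
#' exact log-likelihood-ratio classifier, the ceiling no trained model can
#' beat — is estimated by Monte Carlo.
#'
#' @param variants SNV data frame with a `class` column
#'   (`derived`/`simulated`).
#' @param cfg the [synth_config()].
#' @param dir directory the track files are written to.
#' @param n_mc Monte Carlo draws for the Bayes AUC oracle.
#' @return list: `paths` (named track files), `specs` (feature specs
#'   mirroring the planted design), `oracle_auc`, `truth` (per-variant
#'   planted values).
#' @export
make_tracks <- function(variants, cfg, dir, n_mc = 1e6) {
  stopifnot(nrow(variants) > 0L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  y <- as.integer(variants$class == "simulated")
  n <- nrow(variants)
  nb <- length(cfg$beta)
  truth <- variants[, c("chrom", "pos", "from", "to", "class")]
  paths <- character(0)
  # numeric tracks are per-position: draw one value per distinct position
  # (class taken from the first variant there, a rare collision at toy
  # densities) so the written track and the truth table always agree
  key <- paste(variants$chrom, variants$pos)
  first <- !duplicated(key)
  ukey <- key[first]
  uy <- y[first]
  idx <- match(key, ukey)
  with_seed(cfg$seed + 3L, {
    for (j in seq_len(nb)) {
      nm <- names(cfg$beta)[j] %||% paste0("f", j)
      val <- stats::rnorm(sum(first), mean = uy * cfg$beta[j], sd = cfg$noise_sd)
      val <- as.numeric(sprintf("%.6g", val))  # match bedGraph precision
      miss <- stats::runif(sum(first)) < cfg$missingness
      truth[[nm]] <- ifelse(miss[idx], NA_real_, val[idx])
      df <- data.frame(chrom = variants$chrom[first], pos = variants$pos[first],
                       value = val)[!miss, ]
      p <- file.path(dir, paste0(nm, ".bedGraph"))
      write_bedgraph(df, p)
      paths[nm] <- p
    }
    lev <- character(n)
    for (cls in 0:1) {
      idx <- y == cls
      if (any(idx))
        lev[idx] <- sample(cfg$cat_levels, sum(idx), replace = TRUE,
                           prob = cfg$cat_probs[cls + 1L, ])
    }
    miss <- stats::runif(n) < cfg$missingness
    truth$category <- ifelse(miss, NA_character_, lev)
    cat_df <- data.frame(chrom = variants$chrom, pos = variants$pos,
                         ref = variants$from, alt = variants$to,
                         value = lev, stringsAsFactors = FALSE)[!miss, ]
    p <- file.path(dir, "category.tsv")
    utils::write.table(cat_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["category"] <- p
  })
  specs <- planted_feature_specs(cfg, paths)
  list(paths = paths, specs = specs,
       oracle_auc = bayes_oracle_auc(cfg, n_mc = n_mc, seed = cfg$seed + 4L),
       truth = truth)
}

# feature specs mirroring the planted design: the three imputation
# strategies are all exercised across the numeric features
planted_feature_specs <- function(cfg, paths = NULL) {
  nb <- length(cfg$beta)
  imps <- rep(c("indicator", "indicator", "mean_from_simulated", "fixed"),
              length.out = nb)
  specs <- lapply(seq_len(nb), function(j) {
    nm <- names(cfg$beta)[j] %||% paste0("f", j)
    feature_spec(nm, source = "track", kind = "numeric", imputation = imps[j],
                 value = if (imps[j] == "fixed") 0 else NULL,
                 path = unname(paths[nm]), format = "bedGraph")
  })
  specs[[nb + 1L]] <- feature_spec("category", source = "track",
                                   kind = "categorical",
                                   imputation = "indicator",
                                   levels = cfg$cat_levels,
                                   path = unname(paths["category"]),
                                   format = "tsv")
  specs
}

#' Monte-Carlo Bayes-optimal AUC of the planted generative model
#'
#' Draws labels and features from the configured class-conditional
#' distributions (including missingness, which carries no class signal) and
#' computes the AUC of the exact log-likelihood ratio. For a single Gaussian
#' feature without missingness this converges to
#' `pnorm(beta / (noise_sd * sqrt(2)))`, which [gaussian_pair_auc()] gives
#' in closed form.
#'
#' @param cfg a [synth_config()].
#' @param n_mc number of Monte Carlo draws.
#' @param seed RNG seed for the oracle (independent of the fixture draws).
#' @return estimated Bayes AUC.
#' @export
bayes_oracle_auc <- function(cfg, n_mc = 1e6, seed = 99L) {
  with_seed(seed, {
    n <- as.integer(n_mc)
    y <- stats::rbinom(n, 1L, 0.5)
    llr <- numeric(n)
    s2 <- cfg$noise_sd^2
    for (j in seq_along(cfg$beta)) {
      b <- cfg$beta[j]
      x <- stats::rnorm(n, mean = y * b, sd = cfg$noise_sd)
      present <- stats::runif(n) >= cfg$missingness
      llr <- llr + ifelse(present, (x * b - b^2 / 2) / s2, 0)
    }
    p0 <- cfg$cat_probs[1L, ]; p1 <- cfg$cat_probs[2L, ]
    lv <- integer(n)
    for (cls in 0:1) {
      idx <- y == cls
      if (any(idx))
        lv[idx] <- sample.int(length(cfg$cat_levels), sum(idx), replace = TRUE,
                              prob = cfg$cat_probs[cls + 1L, ])
    }
    present <- stats::runif(n) >= cfg$missingness
    llr <- llr + ifelse(present, log(p1[lv] / p0[lv]), 0)
    roc_auc(y, llr)
  })
}

#' Closed-form AUC of two equal-variance Gaussians
#'
#' @param beta mean separation.
#' @param sd common standard deviation.
#' @return `pnorm(beta / (sd * sqrt(2)))`.
#' @export
gaussian_pair_auc <- function(beta, sd = 1) stats::pnorm(beta / (sd * sqrt(2)))
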