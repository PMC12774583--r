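#' Declare one model feature
#'
#' A feature spec names a feature, where its values come from, whether it is
#' numeric or categorical, and how missing values are handled:
#' \describe{
#'   \item{indicator}{fill the value column with 0 and add a 0/1
#'     `<name>_missing` column;}
#'   \item{mean_from_simulated}{fill with the mean computed over
#'     simulated-class training rows only (stored for reuse at scoring
#'     time);}
#'   \item{fixed}{fill with a constant `value`.}
#' }
#' Categorical features are one-hot encoded over their declared `levels`
#' and always carry a missing-indicator column (which also absorbs levels
#' unseen at training time); their imputation must be `"indicator"`.
#'
#' Sources: `"track"` (values served by a loaded annotation track of the
#' same name, or by `path`/`format`), or the built-ins `"gc_fraction"`,
#' `"cpg_count"`, `"ref_base"`, `"consequence"`, `"grantham"` (the last two
#' need a GFF3 annotation).
#'
#' @param name feature (column) name.
#' @param source value source, see Details.
#' @param kind `"numeric"` or `"categorical"`.
#' @param imputation missing-value strategy.
#' @param value constant for `imputation = "fixed"`.
#' @param levels level set for categorical features.
#' @param path,format,field optional track file behind a `"track"` source.
#' @return a `feature_spec`.
#' @export
feature_spec <- function(name, source = "track",
                         kind = c("numeric", "categorical"),
                         imputation = c("indicator", "mean_from_simulated", "fixed"),
                         value = NULL, levels = NULL,
                         path = NULL, format = NULL, field = NULL) {
  kind <- match.arg(kind)
  imputation <- match.arg(imputation)
  if (imputation == "fixed" && (is.null(value) || !is.finite(value)))
    stop2("feature '%s': imputation 'fixed' requires a finite value", name)
  if (kind == "categorical") {
    if (is.null(levels) || length(levels) == 0L)
      stop2("feature '%s': categorical features need a non-empty level set", name)
    if (imputation != "indicator")
      stop2("feature '%s': categorical features use the indicator strategy", name)
  }
  structure(list(name = name, source = source, kind = kind,
                 imputation = imputation, value = value, levels = levels,
                 path = path, format = format, field = field),
            class = "feature_spec")
}

builtin_sources <- c("gc_fraction", "cpg_count", "ref_base", "consequence", "grantham")

#' Assemble raw (pre-encoding) feature records for variants
#'
#' Joins every declared feature onto the variant table: per-position tracks
#' by `(chrom, pos)`, per-variant tracks by `(chrom, pos, from, to)`,
#' built-ins computed from the genome (and GFF3 where consequences are
#' requested). Absent values are `NA`; Grantham distances attach only to
#' missense variants.
#'
#' @param variants SNV data frame.
#' @param specs list of [feature_spec()]s.
#' @param tracks named list of loaded `annotation_track`s.
#' @param genome reference genome (needed by built-ins).
#' @param gff GFF3 path or `GRanges` (needed by consequence/grantham).
#' @param context_window half-width for the sequence-context built-ins.
#' @return data frame: variant identity columns then one column per feature;
#'   the specs are attached as attribute `"specs"`.
#' @export
assemble_features <- function(variants, specs, tracks = list(), genome = NULL,
                              gff = NULL, context_window = 75L) {
  check_snv_frame(variants)
  n <- nrow(variants)
  ctx <- NULL
  cons <- NULL
  need_ctx <- any(vapply(specs, function(s) s$source %in% c("gc_fraction", "cpg_count"),
                         logical(1)))
  need_cons <- any(vapply(specs, function(s) s$source %in% c("consequence", "grantham"),
                          logical(1)))
  if (need_ctx) {
    if (is.null(genome)) stop2("sequence-context features need the genome")
    ctx <- data.frame(gc_fraction = rep(NA_real_, n), cpg_count = rep(NA_real_, n))
    for (ch in unique(variants$chrom)) {
      sel <- variants$chrom == ch
      cf <- sequence_context_features(genome, ch, variants$pos[sel], context_window)
      ctx$gc_fraction[sel] <- ifelse(cf$gc_missing, NA_real_, cf$gc_fraction)
      ctx$cpg_count[sel] <- cf$cpg_count
    }
  }
  if (need_cons) {
    if (is.null(gff) || is.null(genome))
      stop2("consequence features need a GFF3 annotation and the genome")
    cons <- call_consequences(variants, gff, genome)
  }
  out <- variants[, c("chrom", "pos", "from", "to")]
  for (s in specs) {
    col <- switch(s$source,
      track = {
        tr <- tracks[[s$name]]
        if (is.null(tr)) stop2("feature '%s' references a track that was not loaded", s$name)
        track_lookup(tr, variants)
      },
      gc_fraction = ctx$gc_fraction,
      cpg_count = ctx$cpg_count,
      ref_base = ifelse(variants$from %in% DNA_BASES, variants$from, NA_character_),
      consequence = cons$consequence,
      grantham = {
        g <- rep(NA_real_, n)
        mis <- which(cons$consequence == "missense")
        g[mis] <- as.numeric(grantham(cons$aa_ref[mis], cons$aa_alt[mis]))
        g
      },
      stop2("feature '%s': unknown source '%s'", s$name, s$source))
    if (s$kind == "numeric") col <- as.numeric(col)
    out[[s$name]] <- col
  }
  attr(out, "specs") <- specs
  out
}

#' Encode and impute a feature matrix
#'
#' Turns raw feature records into the numeric design matrix used for
#' training and scoring: categorical columns become one-hot groups over
#' their declared levels plus a missing indicator; numeric columns are
#' imputed per their spec. Means requested by `mean_from_simulated` are
#' computed over simulated-class rows only and recorded in
#' `imputation_stats`; passing previously recorded `stats` (as at scoring
#' time) reuses them instead of recomputing, so the encoding of new variants
#' is a pure function of the training-time statistics.
#'
#' @param records output of [assemble_features()].
#' @param specs list of [feature_spec()]s (defaults to the attribute on
#'   `records`).
#' @param labels class labels, 1 = simulated/proxy-deleterious,
#'   0 = derived/proxy-neutral (or the strings `"simulated"`/`"derived"`);
#'   may be `NULL` at scoring time.
#' @param stats named list of imputation means to reuse.
#' @return a `feature_matrix`: list with `X` (numeric matrix), `y`,
#'   `row_keys`, `column_names`, `imputation_stats`.
#' @export
encode_and_impute <- function(records, specs = attr(records, "specs"),
                              labels = NULL, stats = NULL) {
  if (is.null(specs)) stop2("no feature specs supplied")
  if (!is.null(labels)) {
    if (is.character(labels)) labels <- as.integer(labels == "simulated")
    if (length(labels) != nrow(records))
      stop2("labels (%d) and records (%d) differ in length", length(labels), nrow(records))
  }
  stats_out <- list()
  cols <- list()
  for (s in specs) {
    x <- records[[s$name]]
    if (is.null(x)) stop2("records lack feature column '%s'", s$name)
    if (s$kind == "numeric") {
      x <- as.numeric(x)
      miss <- !is.finite(x)
      filled <- x
      if (s$imputation == "indicator") {
        filled[miss] <- 0
        cols[[s$name]] <- filled
        cols[[paste0(s$name, "_missing")]] <- as.numeric(miss)
      } else if (s$imputation == "mean_from_simulated") {
        m <- stats[[s$name]]
        if (is.null(m)) {
          if (is.null(labels))
            stop2("feature '%s': mean_from_simulated needs labels or stored stats", s$name)
          simv <- x[labels == 1L & !miss]
          if (length(simv) == 0L)
            stop2("feature '%s' is missing in every simulated record; cannot impute its mean",
                  s$name)
          m <- mean(simv)
        }
        filled[miss] <- m
        stats_out[[s$name]] <- m
        cols[[s$name]] <- filled
      } else {  # fixed
        filled[miss] <- s$value
        cols[[s$name]] <- filled
      }
    } else {
      x <- as.character(x)
      known <- !is.na(x) & x %in% s$levels
      for (lv in s$levels)
        cols[[paste0(s$name, ".", lv)]] <- as.numeric(known & x == lv)
      cols[[paste0(s$name, "_missing")]] <- as.numeric(!known)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  if (any(!is.finite(X))) stop2("encoded matrix contains non-finite values")
  structure(list(X = X, y = labels,
                 row_keys = records[, c("chrom", "pos", "from", "to")],
                 column_names = colnames(X),
                 imputation_stats = stats_out),
            class = "feature_matrix")
}
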