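# known configuration keys and their defaults (NULL = no default, may be
# required). Thresholds follow the published workflow: derived variants must
# have derived-allele frequency > 0.9, simulated candidates with population
# AF > 0.1 are excluded, L2 constant 0.1, at most 100 solver iterations,
# 5-fold cross-validation.
config_defaults <- function() {
  list(reference = NULL, maf = NULL, population_vcf = NULL, gff = NULL,
       ref_species = NULL, ancestor_label = NULL, outgroup_labels = NULL,
       outgroup_strategy = "strict_consensus", output_dir = NULL,
       af_fixed = 0.9, af_exclude = 0.1, window_size = 100000L,
       min_window_bases = 1000L, context_window = 75L, l2 = 0.1,
       max_iter = 100L, k_folds = 5L, standardize = FALSE, seed = 42L,
       region = NULL, features = list(), subsets = list())
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration, applies defaults, and validates every field,
#' collecting all problems into a single error: unknown keys are rejected by
#' name, thresholds must lie in (0, 1], `k_folds >= 2`, and all referenced
#' input paths must exist. Feature entries are converted to
#' [feature_spec()]s; subset entries are `name`/`feature`/`levels` triples
#' evaluated over the raw feature records.
#'
#' @param path YAML file path.
#' @return a validated `cadd_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  validate_config(raw, base_dir = base)
}

#' @rdname load_config
#' @param cfg a raw configuration list (as from `yaml::read_yaml`).
#' @param base_dir directory relative paths are resolved against.
#' @export
validate_config <- function(cfg, base_dir = ".") {
  defs <- config_defaults()
  errs <- character(0)
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown) > 0L)
    errs <- c(errs, sprintf("unknown configuration key(s): %s",
                            paste(unknown, collapse = ", ")))
  out <- defs
  for (key in intersect(names(cfg), names(defs)))
    if (!is.null(cfg[[key]])) out[[key]] <- cfg[[key]]
  num_in <- function(key, lo, hi, lo_open = TRUE) {
    v <- out[[key]]
    if (!is.numeric(v) || length(v) != 1L ||
        (if (lo_open) v <= lo else v < lo) || v > hi)
      errs <<- c(errs, sprintf("%s must be a number in %s%g, %g], got %s", key,
                               if (lo_open) "(" else "[", lo, hi,
                               paste(format(v), collapse = ",")))
  }
  for (key in c("reference", "maf", "ref_species", "output_dir"))
    if (is.null(out[[key]]))
      errs <- c(errs, sprintf("required key '%s' is missing", key))
  if (is.null(out$ancestor_label) && is.null(out$outgroup_labels))
    errs <- c(errs, "one of 'ancestor_label' or 'outgroup_labels' is required")
  num_in("af_fixed", 0, 1)
  num_in("af_exclude", 0, 1)
  if (!is.numeric(out$window_size) || out$window_size < 1)
    errs <- c(errs, "window_size must be >= 1")
  if (!is.numeric(out$l2) || out$l2 <= 0)
    errs <- c(errs, "l2 must be > 0")
  if (!is.numeric(out$max_iter) || out$max_iter < 1)
    errs <- c(errs, "max_iter must be >= 1")
  if (!is.numeric(out$k_folds) || out$k_folds < 2)
    errs <- c(errs, "k_folds must be >= 2")
  if (!out$outgroup_strategy %in% c("strict_consensus", "majority"))
    errs <- c(errs, "outgroup_strategy must be strict_consensus or majority")
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) return(normalizePath(p))
    file.path(base_dir, p)
  }
  for (key in c("reference", "maf", "population_vcf", "gff")) {
    if (is.null(out[[key]])) next
    out[[key]] <- resolve(out[[key]])
    if (!file.exists(out[[key]]))
      errs <- c(errs, sprintf("%s path does not exist: %s", key, out[[key]]))
  }
  if (!is.null(out$output_dir) && !file.exists(out$output_dir) &&
      !dir.exists(dirname(out$output_dir))) {
    # parent may be created later; only flag clearly bad values
  }
  specs <- list()
  for (i in seq_along(out$features)) {
    f <- out$features[[i]]
    sp <- tryCatch(
      feature_spec(name = f$name, source = f$source %||% "track",
                   kind = f$kind %||% "numeric",
                   imputation = f$imputation %||% "indicator",
                   value = f$value, levels = unlist(f$levels),
                   path = if (!is.null(f$path)) resolve(f$path),
                   format = f$format, field = f$field),
      error = function(e) {
        errs <<- c(errs, sprintf("feature %d: %s", i, conditionMessage(e)))
        NULL
      })
    if (!is.null(sp)) {
      if (sp$source == "track") {
        if (is.null(sp$path))
          errs <- c(errs, sprintf("feature '%s': track source needs a path", sp$name))
        else if (!file.exists(sp$path))
          errs <- c(errs, sprintf("feature '%s': track path does not exist: %s",
                                  sp$name, sp$path))
      } else if (!sp$source %in% builtin_sources) {
        errs <- c(errs, sprintf("feature '%s': unknown source '%s'", sp$name, sp$source))
      }
      specs[[length(specs) + 1L]] <- sp
    }
  }
  for (i in seq_along(out$subsets)) {
    s <- out$subsets[[i]]
    if (is.null(s$name) || is.null(s$feature) || is.null(s$levels))
      errs <- c(errs, sprintf("subset %d needs name, feature and levels", i))
  }
  if (length(errs) > 0L)
    stop2("invalid configuration:\n  - %s", paste(errs, collapse = "\n  - "))
  out$features <- specs
  out$seed <- as.integer(out$seed)
  out$k_folds <- as.integer(out$k_folds)
  out$max_iter <- as.integer(out$max_iter)
  out$window_size <- as.integer(out$window_size)
  structure(out, class = "cadd_config")
}

#' Write a configuration as YAML
#'
#' @param config a `cadd_config` or plain list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$features <- lapply(cfg$features, function(s) {
    if (inherits(s, "feature_spec")) s <- unclass(s)
    s[!vapply(s, is.null, logical(1))]
  })
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}
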