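# dependency-ordered stage runner. Each stage reads its declared inputs,
# writes its artifacts under output_dir, and records a manifest (inputs,
# parameters, checksums); unchanged stages are skipped unless forced.

pipeline_stages <- function() {
  list(
    ancestor = list(deps = character(0)),
    derive   = list(deps = "ancestor"),
    rates    = list(deps = "ancestor"),
    simulate = list(deps = c("derive", "rates")),
    annotate = list(deps = c("derive", "simulate")),
    train    = list(deps = "annotate"),
    validate = list(deps = "annotate"),
    score    = list(deps = "train")
  )
}

artifact_paths <- function(config) {
  o <- config$output_dir
  list(ancestor = file.path(o, "ancestor", "ancestor_map.fa"),
       coverage = file.path(o, "ancestor", "coverage.tsv"),
       derived = file.path(o, "variants", "derived.tsv"),
       rates = file.path(o, "variants", "rate_model.json"),
       simulated = file.path(o, "variants", "simulated.tsv"),
       features = file.path(o, "annotate", "features.tsv"),
       model = file.path(o, "model", "model.json"),
       cv = file.path(o, "model", "cv_report.tsv"),
       subsets = file.path(o, "model", "subset_auc.tsv"),
       scores = file.path(o, "scores", "scores.tsv"))
}

stage_outputs <- function(config) {
  a <- artifact_paths(config)
  list(ancestor = c(a$ancestor, a$coverage), derive = a$derived,
       rates = a$rates, simulate = a$simulated, annotate = a$features,
       train = a$model, validate = c(a$cv, a$subsets), score = a$scores)
}

manifest_path <- function(config, stage)
  file.path(config$output_dir, "manifests", paste0(stage, ".json"))

stage_params <- function(config, stage) {
  keep <- switch(stage,
    ancestor = c("ref_species", "ancestor_label", "outgroup_labels", "outgroup_strategy"),
    derive = "af_fixed",
    rates = c("window_size", "min_window_bases"),
    simulate = c("af_exclude", "seed"),
    annotate = "context_window",
    train = c("l2", "max_iter", "standardize"),
    validate = c("l2", "max_iter", "standardize", "k_folds", "seed"),
    score = c("region", "context_window"))
  cfg <- unclass(config)[keep]
  cfg[!vapply(cfg, is.null, logical(1))]
}

stage_inputs <- function(config, stage) {
  a <- artifact_paths(config)
  track_paths <- unlist(lapply(config$features, function(s) s$path))
  switch(stage,
    ancestor = c(config$reference, config$maf),
    derive = c(config$reference, a$ancestor,
               if (!is.null(config$population_vcf)) config$population_vcf),
    rates = c(config$reference, a$ancestor),
    simulate = c(config$reference, a$ancestor, a$rates, a$derived,
                 if (!is.null(config$population_vcf)) config$population_vcf),
    annotate = c(config$reference, a$derived, a$simulated, track_paths,
                 if (!is.null(config$gff)) config$gff),
    train = a$features,
    validate = a$features,
    score = c(config$reference, a$model, track_paths,
              if (!is.null(config$gff)) config$gff))
}

write_manifest <- function(config, stage, inputs, outputs) {
  mp <- manifest_path(config, stage)
  dir.create(dirname(mp), showWarnings = FALSE, recursive = TRUE)
  obj <- list(stage = stage, created = format(Sys.time(), tz = "UTC"),
              params = stage_params(config, stage),
              inputs = lapply(inputs, function(p)
                list(path = p, md5 = unname(tools::md5sum(p)))),
              outputs = lapply(outputs, function(p)
                list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(obj, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

stage_up_to_date <- function(config, stage) {
  mp <- manifest_path(config, stage)
  outs <- stage_outputs(config)[[stage]]
  if (!file.exists(mp) || !all(file.exists(outs))) return(FALSE)
  man <- tryCatch(jsonlite::read_json(mp), error = function(e) NULL)
  if (is.null(man)) return(FALSE)
  ins <- stage_inputs(config, stage)
  if (!all(file.exists(ins))) return(FALSE)
  old <- vapply(man$inputs, function(x) paste(x$path, x$md5), character(1))
  new <- paste(ins, unname(tools::md5sum(ins)))
  same_params <- identical(
    as.character(jsonlite::toJSON(man$params, auto_unbox = TRUE, digits = NA)),
    as.character(jsonlite::toJSON(stage_params(config, stage), auto_unbox = TRUE,
                                  digits = NA)))
  identical(sort(old), sort(new)) && same_params
}

log_stage <- function(fmt, ...) message(sprintf(paste0("[caddforge] ", fmt), ...))

load_config_tracks <- function(config, genome) {
  tracks <- list()
  for (s in config$features) {
    if (s$source != "track") next
    tracks[[s$name]] <- load_track(s$path, format = s$format %||% "bedGraph",
                                   name = s$name, kind = s$kind, genome = genome,
                                   field = s$field)
  }
  tracks
}

#' Run the scoring pipeline
#'
#' Executes the requested stages in dependency order:
#' `ancestor` (project the ancestral sequence from the MAF), `derive`
#' (proxy-neutral variants), `rates` (windowed substitution-rate model),
#' `simulate` (proxy-deleterious variants, matched in number to the derived
#' set), `annotate` (raw feature records for both classes), `train`
#' (penalised logistic model on the full training set), `validate`
#' (stratified cross-validation and subset AUC report) and `score`
#' (PHRED-scaled scores for every possible SNV). Each stage writes its
#' artifacts plus a manifest with input checksums; a stage whose inputs and
#' parameters are unchanged is skipped unless `force`.
#'
#' @param config a validated `cadd_config` ([load_config()]).
#' @param stages character vector of stages, or `"all"`.
#' @param force rerun stages even when up to date.
#' @return named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, stages = "all", force = FALSE) {
  all_stages <- names(pipeline_stages())
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0L)
    stop2("unknown stage(s): %s", paste(bad, collapse = ", "))
  stages <- all_stages[all_stages %in% stages]
  a <- artifact_paths(config)
  deps <- pipeline_stages()
  outs <- stage_outputs(config)
  for (st in stages) {
    for (d in deps[[st]]$deps) {
      if (!d %in% stages && !all(file.exists(outs[[d]])))
        stop2("stage '%s' needs the output of stage '%s'; run that stage first", st, d)
    }
  }
  genome <- read_genome(config$reference)
  for (st in stages) {
    if (!force && stage_up_to_date(config, st)) {
      log_stage("stage %-8s up to date, skipped", st)
      next
    }
    t0 <- Sys.time()
    for (p in outs[[st]]) dir.create(dirname(p), showWarnings = FALSE, recursive = TRUE)
    switch(st,
      ancestor = {
        blocks <- parse_maf(config$maf)
        anc <- build_ancestor_map(blocks, genome, config$ref_species,
                                  ancestor_label = config$ancestor_label,
                                  outgroup_labels = config$outgroup_labels,
                                  strategy = config$outgroup_strategy)
        write_ancestor_map(anc, a$ancestor, format = "fasta")
        cov <- coverage_stats(anc, genome)
        df <- cov$by_chrom
        df <- rbind(df, data.frame(chrom = "TOTAL", length = sum(df$length),
                                   covered = sum(df$covered), fraction = cov$total))
        utils::write.table(format(df, digits = 6), a$coverage, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        log_stage("ancestor coverage %.4f", cov$total)
      },
      derive = {
        anc <- read_ancestor_map(a$ancestor, genome)
        pop <- if (!is.null(config$population_vcf))
          read_population_vcf(config$population_vcf)
        der <- call_derived_variants(genome, anc, pop, af_fixed = config$af_fixed)
        write_snvs(der, a$derived)
        log_stage("derived %d proxy-neutral variants", nrow(der))
      },
      rates = {
        anc <- read_ancestor_map(a$ancestor, genome)
        model <- estimate_mutation_rates(genome, anc,
                                         window_size = config$window_size,
                                         min_window_bases = config$min_window_bases)
        write_rate_model(model, a$rates)
        log_stage("rate model: %d window(s)",
                  sum(vapply(model$chroms, function(c) c$n_windows, integer(1))))
      },
      simulate = {
        anc <- read_ancestor_map(a$ancestor, genome)
        model <- read_rate_model(a$rates)
        der <- read_snvs(a$derived)
        pop <- if (!is.null(config$population_vcf))
          read_population_vcf(config$population_vcf)
        exclude <- data.frame(chrom = der$chrom, pos = der$pos, to = der$from)
        sim <- simulate_variants(model, genome, anc, n_target = nrow(der),
                                 pop = pop, af_exclude = config$af_exclude,
                                 seed = config$seed + 101L, exclude = exclude)
        write_snvs(sim, a$simulated)
        log_stage("simulated %d proxy-deleterious variants", nrow(sim))
      },
      annotate = {
        der <- read_snvs(a$derived)
        sim <- read_snvs(a$simulated)
        variants <- rbind(der, sim)
        tracks <- load_config_tracks(config, genome)
        rec <- assemble_features(variants, config$features, tracks = tracks,
                                 genome = genome, gff = config$gff,
                                 context_window = config$context_window)
        out <- cbind(rec, class = variants$class)
        utils::write.table(out, a$features, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        log_stage("annotated %d variants with %d feature(s)",
                  nrow(out), length(config$features))
      },
      train = {
        rec <- utils::read.delim(a$features, stringsAsFactors = FALSE)
        fm <- encode_and_impute(rec, config$features, labels = rec$class)
        model <- train_cadd(fm, l2 = config$l2, max_iter = config$max_iter,
                            standardize = config$standardize)
        model$imputation_stats <- fm$imputation_stats
        model$specs <- config$features
        write_model(model, a$model)
        log_stage("trained on %d x %d matrix (%s)", nrow(fm$X), ncol(fm$X),
                  if (model$converged) "converged" else "iteration cap reached")
      },
      validate = {
        rec <- utils::read.delim(a$features, stringsAsFactors = FALSE)
        fm <- encode_and_impute(rec, config$features, labels = rec$class)
        cv <- cross_validate(fm, k = config$k_folds, seed = config$seed + 202L,
                             l2 = config$l2, max_iter = config$max_iter,
                             standardize = config$standardize)
        cvdf <- data.frame(fold = c(seq_len(cv$k), NA), auc = c(cv$fold_auc, cv$mean_auc))
        cvdf$fold <- ifelse(is.na(cvdf$fold), "mean", as.character(cvdf$fold))
        utils::write.table(cvdf, a$cv, sep = "\t", quote = FALSE, row.names = FALSE)
        subs <- list()
        for (s in config$subsets) {
          vals <- as.character(rec[[s$feature]])
          subs[[s$name]] <- !is.na(vals) & vals %in% unlist(s$levels)
        }
        sdf <- if (length(subs) > 0L) subset_auc(cv, subs) else
          data.frame(subset = character(0), n = integer(0), n_pos = integer(0),
                     n_neg = integer(0), auc = numeric(0))
        utils::write.table(sdf, a$subsets, sep = "\t", quote = FALSE, row.names = FALSE)
        log_stage("cross-validated mean AUC %.4f over %d folds", cv$mean_auc, cv$k)
      },
      score = {
        model <- read_model(a$model)
        tracks <- load_config_tracks(config, genome)
        tab <- score_genome(model, genome, tracks = tracks, gff = config$gff,
                            region = config$region,
                            context_window = config$context_window)
        write_scores(tab, a$scores)
        log_stage("scored %d SNVs (max PHRED %.3f)", nrow(tab),
                  if (nrow(tab) > 0) max(tab$phred) else NA)
      })
    write_manifest(config, st, stage_inputs(config, st), outs[[st]])
    log_stage("stage %-8s done in %.1fs", st,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  invisible(a)
}

#' Write a complete synthetic study to disk
#'
#' Generates every pipeline input with known ground truth under `dir`:
#' reference FASTA, MAF with ancestor and outgroup rows, population VCF,
#' planted annotation tracks, truth tables, and a ready-to-run
#' `config.yaml`. Because the planted features depend on the variant
#' classes, the generator runs the variant stages itself (with the same
#' seeds the pipeline will use) to learn which variants exist, then plants
#' the tracks; a subsequent full pipeline run reproduces those variant sets
#' exactly.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory.
#' @param n_mc Monte Carlo draws for the Bayes AUC oracle.
#' @return list with `config_path`, the parsed `config`, `oracle_auc`,
#'   truth tables and fixture paths, invisibly.
#' @export
write_synth_fixtures <- function(cfg, dir, n_mc = 1e6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- make_genome(cfg)
  ref_path <- file.path(dir, "ref.fa")
  write_genome(genome, ref_path)
  anc <- make_ancestor_and_maf(genome, cfg)
  maf_path <- file.path(dir, "aln.maf")
  write_maf(anc$blocks, maf_path)
  pop <- make_population_vcf(genome, cfg)
  vcf_path <- file.path(dir, "pop.vcf")
  write_population_vcf(pop, genome, vcf_path)
  truth_dir <- file.path(dir, "truth")
  dir.create(truth_dir, showWarnings = FALSE)
  write_ancestor_map(anc$ancestor_truth, file.path(truth_dir, "ancestor.fa"))
  utils::write.table(anc$diffs, file.path(truth_dir, "diffs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(pop, file.path(truth_dir, "population.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  # variant stages with the pipeline's own seeds, to plant class-aware tracks
  der <- call_derived_variants(genome, anc$ancestor_truth, pop, af_fixed = 0.9)
  rates <- estimate_mutation_rates(genome, anc$ancestor_truth)
  sim <- simulate_variants(rates, genome, anc$ancestor_truth,
                           n_target = nrow(der), pop = pop, af_exclude = 0.1,
                           seed = cfg$seed + 101L,
                           exclude = data.frame(chrom = der$chrom, pos = der$pos,
                                                to = der$from))
  variants <- rbind(der, sim)
  tr <- make_tracks(variants, cfg, file.path(dir, "tracks"), n_mc = n_mc)
  utils::write.table(tr$truth, file.path(truth_dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(oracle_auc = tr$oracle_auc, n_derived = nrow(der),
                            n_simulated = nrow(sim)),
                       file.path(truth_dir, "oracle.json"),
                       auto_unbox = TRUE, digits = NA)
  config <- list(reference = "ref.fa", maf = "aln.maf", population_vcf = "pop.vcf",
                 ref_species = cfg$ref_species, ancestor_label = cfg$ancestor_label,
                 output_dir = file.path(dir, "out"), seed = cfg$seed,
                 features = lapply(tr$specs, function(s) {
                   s <- unclass(s)
                   s$path <- basename(s$path)
                   s$path <- file.path("tracks", s$path)
                   s[!vapply(s, is.null, logical(1))]
                 }),
                 subsets = list(
                   list(name = "high_category", feature = "category",
                        levels = list("high")),
                   list(name = "low_category", feature = "category",
                        levels = list("low"))))
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  parsed <- load_config(config_path)
  invisible(list(config_path = config_path, config = parsed,
                 oracle_auc = tr$oracle_auc, genome = genome,
                 ancestor_truth = anc$ancestor_truth, diffs = anc$diffs,
                 population = pop, derived = der, simulated = sim,
                 tracks = tr$paths, feature_truth = tr$truth))
}
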