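# One shared full-scale synthetic study for the end-to-end tests: the
# standard toy conditions (1 Mb genome, ~1% divergence, 2,000 polymorphic
# sites, 4 numeric + 1 categorical planted features). Generated and run once
# per session, then reused.
e2e_cache <- new.env(parent = emptyenv())

full_e2e <- function() {
  if (!is.null(e2e_cache$run)) return(e2e_cache$run)
  dir <- file.path(tempdir(), "caddforge-e2e")
  cfg <- synth_config(seed = 20260920L)
  fx <- write_synth_fixtures(cfg, dir, n_mc = 1e6)
  elapsed <- system.time(suppressMessages(run_pipeline(fx$config, "all")))[["elapsed"]]
  e2e_cache$run <- list(fx = fx, dir = dir, elapsed = elapsed,
                        artifacts = caddforge:::artifact_paths(fx$config))
  e2e_cache$run
}
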