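# Scaled-down Monte-Carlo runs shared between acceptance checks. Each
# configuration is the full 11-point theta grid at 10 seeds of 30 s; the
# result is cached so several checks can reuse one run.
.mc_cache <- new.env(parent = emptyenv())

mc_config_fit <- function(area, fs, rf_sp, n_seeds = 10, master_seed = 1) {
  key <- paste(area, fs, rf_sp, n_seeds, master_seed, sep = "_")
  hit <- .mc_cache[[key]]
  if (!is.null(hit)) return(hit)
  design <- factorial_design(area_grid = area, fs_grid = fs,
                             n_seeds = n_seeds, Rf_sp = rf_sp)
  st <- run_breach_factorial(design, master_seed = master_seed,
                             metrics = "resid_rms")
  .mc_cache[[key]] <- st$summary
  st$summary
}
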