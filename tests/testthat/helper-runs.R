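# Lazily computed, shared experiment runs for the acceptance checks
# (several checks reuse the same full-scale runs; computing them once keeps
# the suite fast).

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, maker) {
  if (is.null(.run_cache[[key]])) .run_cache[[key]] <- maker()
  .run_cache[[key]]
}

full_default_run <- function() {
  cached_run("full_default", function()
    run_experiment(experiment_config(seed = 1L)))
}

zero_noise_run <- function() {
  cached_run("zero_noise", function()
    run_experiment(experiment_config(seed = 1L, noise_scale = 0)))
}

noise_sweep_run <- function(kp_sd) {
  if (kp_sd == 10) return(full_default_run())  # the default noise level
  cached_run(paste0("sweep_", kp_sd), function() {
    ns <- noise_spec(keypoint_sd = kp_sd)
    run_experiment(experiment_config(seed = 1L, noise = ns))
  })
}
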