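# Shared cache for full-length simulation runs so the expensive scenarios
# are integrated once per test session.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(key, scenario) {
  if (is.null(.run_cache[[key]])) {
    .run_cache[[key]] <- run_scenario(scenario)
  }
  .run_cache[[key]]
}

fig3_runs <- function() {
  presets <- scenario_presets("fig3")
  stats::setNames(
    lapply(names(presets), function(nm) cached_run(paste0("fig3_", nm),
                                                   presets[[nm]])),
    names(presets))
}

fig5_runs <- function() {
  presets <- scenario_presets("fig5")
  stats::setNames(
    lapply(names(presets), function(nm) cached_run(paste0("fig5_", nm),
                                                   presets[[nm]])),
    names(presets))
}
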