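# Shared fixtures: baseline simulations are expensive enough to memoize
# across test files.

.sim_cache <- new.env(parent = emptyenv())

cached_baseline_sim <- function(scenario = "level") {
  key <- paste0("sim_", scenario)
  if (is.null(.sim_cache[[key]])) {
    p <- baseline_gait_preset(scenario)
    .sim_cache[[key]] <- simulate_gait(p$theta, p$scenario, anthro = p$anthro)
  }
  .sim_cache[[key]]
}

cached_optimized_baseline <- function(scenario = "level") {
  key <- paste0("bl_", scenario)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- compute_baseline(scenario, optimize = TRUE,
                                          budget = 300, seed = 1)
  }
  .sim_cache[[key]]
}

# static posture: both legs identical, straight-ish, zero stride
static_theta <- function(hip0 = 0, knee0 = 0.05) {
  controller_theta(T_stride = 1, stride_length = 0,
                   hip = c(hip0, 0, 0, 0, 0), knee = c(knee0, 0, 0, 0, 0),
                   ankle = c(0, 0, 0), pelvis_fluct = c(0, 0),
                   stance_load_threshold = 0.2)
}
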