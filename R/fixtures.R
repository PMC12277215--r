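# Synthetic fixtures: scripted leg-state traces with hand-derivable labels,
# packaged baseline gait presets, and a known-optimum noisy design-cost
# surface used as the outer-loop test oracle.

#' Specification of the synthetic design-cost surface
#'
#' A noisy quadratic-in-damping surface with a per-pattern offset and a known
#' analytic minimum: `cost = base + k (c - c_star)^2 + offset(pattern) +
#' N(0, sigma)`, where `offset` grows with the symmetric difference from the
#' optimal pattern (zero only at `p_star`). Designs in the penalty region
#' (very high damping with the clutch engaged in Swing) are flagged invalid
#' and receive the penalty value, mimicking unstable simulations.
#'
#' @param c_star Optimal damping coefficient.
#' @param p_star Optimal clutch pattern.
#' @param base Noiseless cost at the optimum.
#' @param k Curvature; default scales the damping cost range over
#'   `[c_min, c_max]` to about 0.5.
#' @param offset_per_phase Offset added per phase of symmetric difference
#'   from `p_star`.
#' @param sigma Gaussian noise standard deviation.
#' @param penalty Cost of invalid designs.
#' @param c_min,c_max Damping bounds of the intended space.
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(c_star = 2, p_star = c("ES", "LS"), base = 0.85,
                           k = NULL, offset_per_phase = 0.04, sigma = 0.01,
                           penalty = 10, c_min = 0, c_max = 5) {
  if (is.null(k)) k <- 0.5 / max(c_star - c_min, c_max - c_star)^2
  stopifnot(k > 0, sigma >= 0, offset_per_phase > 0)
  structure(list(c_star = c_star, p_star = p_star, base = base, k = k,
                 offset_per_phase = offset_per_phase, sigma = sigma,
                 penalty = penalty, c_min = c_min, c_max = c_max),
            class = "surrogate_spec")
}

#' Noiseless value of the surrogate surface
#'
#' @param design A [design_params()] (or list with the two fields).
#' @param spec A [surrogate_spec()].
#' @return The closed-form cost without noise (penalty if invalid).
#' @export
surrogate_mean <- function(design, spec) {
  if (surrogate_invalid(design, spec)) return(spec$penalty)
  sym_diff <- length(setdiff(design$clutch_pattern, spec$p_star)) +
    length(setdiff(spec$p_star, design$clutch_pattern))
  spec$base + spec$k * (design$damping_coefficient - spec$c_star)^2 +
    spec$offset_per_phase * sym_diff
}

# penalty region: near-maximal damping with the damper engaged in Swing
surrogate_invalid <- function(design, spec) {
  design$damping_coefficient > spec$c_min + 0.9 * (spec$c_max - spec$c_min) &&
    "SW" %in% design$clutch_pattern
}

#' Noisy draw from the surrogate surface
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param design A [design_params()].
#' @param spec A [surrogate_spec()].
#' @return A single noisy cost value.
#' @export
surrogate_cost <- function(design, spec = surrogate_spec()) {
  m <- surrogate_mean(design, spec)
  if (m >= spec$penalty) return(m)  # penalties are deterministic
  m + stats::rnorm(1, 0, spec$sigma)
}

#' Build a leg-state trace from a phase-machine script
#'
#' A script is a data frame with columns `sagittal`, `load`, `load_contra`
#' (one row per time step, constant or stepwise values chosen to cross
#' specific thresholds), so the exact phase labeling is known by
#' construction.
#'
#' @param script Data frame with the three columns above.
#' @return A [leg_state()] data frame.
#' @export
make_scripted_leg_trace <- function(script) {
  need <- c("sagittal", "load", "load_contra")
  if (!is.data.frame(script) || !all(need %in% names(script)) ||
      nrow(script) == 0L) {
    stop("script must be a nonempty data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(as.matrix(script[need]))) ||
      any(script$load < 0) || any(script$load_contra < 0)) {
    stop("inconsistent script: loads must be finite and >= 0", call. = FALSE)
  }
  leg_state(script$sagittal, script$load, script$load_contra)
}

#' Packaged phase-machine scripts with hand-derived label sequences
#'
#' Each script is designed against the default [phase_thresholds()] so that
#' its labeling is known by construction; together they fire every one of
#' the five transition rules, including both branches of the Late Stance ->
#' Lift Off disjunction.
#'
#' @return Named list of lists with `script`, `initial`, `expected` labels.
#' @export
packaged_scripts <- function() {
  row <- function(sagittal, load, load_contra = 0)
    data.frame(sagittal = sagittal, load = load, load_contra = load_contra)
  full <- rbind(
    row(0.30, 0.50),        # LN -> ES (load > 0.2)
    row(0.30, 0.90),        # ES holds (sagittal > 0)
    row(-0.10, 0.90),       # ES -> LS (sagittal < 0)
    row(-0.10, 0.90),       # LS holds
    row(-0.30, 0.80),       # LS -> LO (sagittal < -0.25)
    row(-0.30, 0.50),       # LO holds (load > 0.1)
    row(-0.30, 0.05, 0.5),  # LO -> SW (load < 0.1)
    row(0.00, 0.00, 0.5),   # SW holds (sagittal < 0.15)
    row(0.20, 0.00, 0.5),   # SW -> LN (sagittal > 0.15)
    row(0.25, 0.10, 0.5)    # LN holds (load < 0.2)
  )
  full_expected <- c("ES", "ES", "LS", "LS", "LO", "LO", "SW", "SW", "LN", "LN")
  contra <- rbind(
    row(0.30, 0.50),        # LN -> ES
    row(-0.05, 0.90),       # ES -> LS
    row(-0.05, 0.90, 0.40), # LS -> LO via contralateral load > 0.2
    row(-0.05, 0.05, 0.90), # LO -> SW
    row(0.20, 0.00, 0.90)   # SW -> LN
  )
  contra_expected <- c("ES", "LS", "LO", "SW", "LN")
  two_cycle <- rbind(full, full, row(0.25, 0.50, 0.5))
  two_expected <- c(full_expected, full_expected, "ES")
  all_stance <- row(rep(0.30, 8), rep(0.90, 8))
  list(
    full_cycle = list(script = full, initial = "LN", expected = full_expected),
    contralateral_liftoff = list(script = contra, initial = "LN",
                                 expected = contra_expected),
    two_cycle = list(script = two_cycle, initial = "LN",
                     expected = two_expected),
    all_stance = list(script = all_stance, initial = "ES",
                      expected = rep("ES", 8))
  )
}

#' Packaged baseline gait presets
#'
#' Controller vectors whose simulation is a valid periodic gait (speed within
#' tolerance, non-negative normal GRF, legal phase sequence, >= 3 complete
#' strides in 10 s) with a negative-knee-power region in Early Stance. The
#' joint trajectories were fit once to standard sagittal-plane gait waypoints
#' (knee double-bump, hip sinusoid); the downhill preset walks a -5 degree
#' slope with deeper loading-response knee flexion, which yields a larger
#' Early Stance negative knee power peak than the level preset.
#'
#' @param scenario `"level"` or `"downhill"`.
#' @return List: `theta` ([controller_theta()]), `anthro`, `scenario`.
#' @export
baseline_gait_preset <- function(scenario = c("level", "downhill")) {
  scenario <- match.arg(scenario)
  if (scenario == "level") {
    theta <- controller_theta(
      T_stride = 1.1, stride_length = 1.32,
      hip = c(0.0975, 0.3609, -0.0510, -0.0501, -0.0260),
      knee = c(0.4401, -0.1059, -0.3699, -0.2127, 0.1685),
      ankle = c(0.02, 0.08, -0.05),
      pelvis_fluct = c(0.012, 0),
      stance_load_threshold = 0.2)
    sc <- scenario_config(slope_deg = 0)
  } else {
    theta <- controller_theta(
      T_stride = 1.1, stride_length = 1.32,
      hip = c(0.1031, 0.3420, -0.0418, -0.0548, -0.0202),
      knee = c(0.4719, -0.0920, -0.3395, -0.2189, 0.1833),
      ankle = c(0.02, 0.08, -0.05),
      pelvis_fluct = c(0.012, 0),
      stance_load_threshold = 0.2)
    sc <- scenario_config(slope_deg = -5)
  }
  list(theta = theta, anthro = anthropometry(), scenario = sc)
}

#' Serialize / load a gait preset as JSON
#'
#' @param preset List from [baseline_gait_preset()].
#' @param path JSON path.
#' @return `path` invisibly (write); the preset list (read).
#' @export
write_preset_json <- function(preset, path) {
  obj <- list(theta = unclass(preset$theta),
              anthro = list(total_mass = preset$anthro$total_mass,
                            height = preset$anthro$height),
              scenario = unclass(preset$scenario))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preset_json
#' @export
read_preset_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  th <- obj$theta
  sc <- obj$scenario
  list(theta = controller_theta(th$T_stride, th$stride_length, th$hip,
                                th$knee, th$ankle, th$pelvis_fluct,
                                th$stance_load_threshold),
       anthro = anthropometry(obj$anthro$total_mass, obj$anthro$height),
       scenario = scenario_config(sc$slope_deg, sc$target_speed, sc$duration,
                                  sc$dt, sc$gravity, sc$speed_tolerance))
}
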