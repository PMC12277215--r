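# Five-phase gait segmentation state machine and stride detection.
#
# Phase cycle: ES -> LS -> LO -> SW -> LN -> ES. Transitions are driven by the
# sagittal foot position (relative to the whole-body CoM, positive in the
# walking direction) and the normalized leg load (GRF magnitude / body weight).
# All threshold comparisons are strict: ties do not fire a transition.

#' Phase transition thresholds
#'
#' @param stance_load_threshold Leg load (body-weight fraction) above which
#'   Landing becomes Early Stance. In the full platform this threshold is part
#'   of the optimized controller vector.
#' @param late_stance_sagittal_threshold Sagittal foot position (m, CoM-relative)
#'   below which Early Stance becomes Late Stance.
#' @param liftoff_sagittal_threshold Sagittal position (m) below which Late
#'   Stance becomes Lift Off (alternative trigger to contralateral loading).
#' @param swing_load_threshold Leg load below which Lift Off becomes Swing.
#' @param landing_sagittal_threshold Sagittal position (m) above which Swing
#'   becomes Landing.
#' @return An object of class `phase_thresholds`.
#' @export
phase_thresholds <- function(stance_load_threshold = 0.2,
                             late_stance_sagittal_threshold = 0,
                             liftoff_sagittal_threshold = -0.25,
                             swing_load_threshold = 0.1,
                             landing_sagittal_threshold = 0.15) {
  if (stance_load_threshold < 0 || stance_load_threshold > 2 ||
      swing_load_threshold < 0 || swing_load_threshold > 2) {
    stop("load thresholds must lie in [0, 2]", call. = FALSE)
  }
  if (swing_load_threshold > stance_load_threshold) {
    stop("`swing_load_threshold` must not exceed `stance_load_threshold`",
         call. = FALSE)
  }
  structure(list(stance_load_threshold = stance_load_threshold,
                 late_stance_sagittal_threshold = late_stance_sagittal_threshold,
                 liftoff_sagittal_threshold = liftoff_sagittal_threshold,
                 swing_load_threshold = swing_load_threshold,
                 landing_sagittal_threshold = landing_sagittal_threshold),
            class = "phase_thresholds")
}

#' Instantaneous state of one leg
#'
#' @param sagittal_foot_position Foot position along the walking direction
#'   relative to the whole-body CoM, m, positive forward.
#' @param leg_load Normalized leg load, GRF magnitude / (m g), `>= 0`.
#' @param contralateral_leg_load Normalized load of the other leg, `>= 0`.
#' @return A one-row `data.frame` (class `leg_state` rows are plain columns so
#'   time series are ordinary data frames).
#' @export
leg_state <- function(sagittal_foot_position, leg_load, contralateral_leg_load = 0) {
  stopifnot(all(leg_load >= 0), all(contralateral_leg_load >= 0))
  data.frame(sagittal_foot_position = sagittal_foot_position,
             leg_load = leg_load,
             contralateral_leg_load = contralateral_leg_load)
}

#' One step of the five-phase transition machine
#'
#' Applies exactly one of the five transition rules (or none): Landing -> Early
#' Stance when the leg load exceeds the stance load threshold; Early Stance ->
#' Late Stance when the sagittal foot position falls below the Late Stance
#' threshold; Late Stance -> Lift Off when the contralateral leg load exceeds
#' the stance load threshold or the sagittal position falls below the liftoff
#' threshold; Lift Off -> Swing when the leg load falls below the Swing load
#' threshold; Swing -> Landing when the sagittal position exceeds the landing
#' threshold. At most one transition per call.
#'
#' @param current Current phase, one of [gait_phases()].
#' @param state A one-row [leg_state()] data frame (or list with the fields).
#' @param thr A [phase_thresholds()].
#' @return The next phase identifier.
#' @export
next_phase <- function(current, state, thr = phase_thresholds()) {
  current <- match.arg(current, gait_phases())
  s <- state$sagittal_foot_position
  l <- state$leg_load
  lc <- state$contralateral_leg_load
  switch(current,
    LN = if (l > thr$stance_load_threshold) "ES" else "LN",
    ES = if (s < thr$late_stance_sagittal_threshold) "LS" else "ES",
    LS = if (lc > thr$stance_load_threshold ||
             s < thr$liftoff_sagittal_threshold) "LO" else "LS",
    LO = if (l < thr$swing_load_threshold) "SW" else "LO",
    SW = if (s > thr$landing_sagittal_threshold) "LN" else "SW")
}

#' Label a leg-state time series with gait phases
#'
#' `label[1]` resolves the initial phase against the first state; each later
#' sample applies [next_phase()] to the previous label.
#'
#' @param states Data frame of [leg_state()] rows (uniform time step).
#' @param thr A [phase_thresholds()].
#' @param initial Initial phase, or `NULL` to resolve from the first sample:
#'   Early Stance if loaded above the stance threshold, else Swing.
#' @return Character vector of phase labels, same length as `nrow(states)`.
#' @export
label_phases <- function(states, thr = phase_thresholds(), initial = NULL) {
  n <- nrow(states)
  if (is.null(n) || n == 0L) stop("empty state series", call. = FALSE)
  if (is.null(initial)) {
    initial <- if (states$leg_load[1] > thr$stance_load_threshold) "ES" else "SW"
  }
  labels <- character(n)
  labels[1] <- next_phase(initial, states[1, , drop = FALSE], thr)
  for (t in seq_len(n)[-1]) {
    labels[t] <- next_phase(labels[t - 1], states[t, , drop = FALSE], thr)
  }
  labels
}

# Vectorized labeling used by the simulator: same semantics as label_phases()
# but avoids per-row data.frame subsetting (hot path under CMA-ES).
label_phases_fast <- function(sagittal, load, load_contra, thr, initial = NULL) {
  n <- length(sagittal)
  if (n == 0L) stop("empty state series", call. = FALSE)
  if (is.null(initial)) initial <- if (load[1] > thr$stance_load_threshold) "ES" else "SW"
  ls_fire <- sagittal < thr$late_stance_sagittal_threshold
  lo_fire <- load_contra > thr$stance_load_threshold |
             sagittal < thr$liftoff_sagittal_threshold
  sw_fire <- load < thr$swing_load_threshold
  ln_fire <- sagittal > thr$landing_sagittal_threshold
  es_fire <- load > thr$stance_load_threshold
  labels <- character(n)
  cur <- initial
  for (t in seq_len(n)) {
    cur <- switch(cur,
      LN = if (es_fire[t]) "ES" else "LN",
      ES = if (ls_fire[t]) "LS" else "ES",
      LS = if (lo_fire[t]) "LO" else "LS",
      LO = if (sw_fire[t]) "SW" else "LO",
      SW = if (ln_fire[t]) "LN" else "SW")
    labels[t] <- cur
  }
  labels
}

#' Detect strides (touchdown-to-touchdown intervals)
#'
#' A stride runs from one touchdown of a leg to the next touchdown of the same
#' leg. Touchdowns are Landing -> Early Stance transitions in a phase label
#' series, or, for a raw load series, upward crossings of the stance load
#' threshold.
#'
#' @param labels Character vector of phase labels, or a numeric leg-load series
#'   if `load_threshold` is given.
#' @param load_threshold If non-`NULL`, treat `labels` as a normalized leg-load
#'   series and detect upward crossings of this threshold.
#' @return List with `touchdowns` (indices) and `strides`, a two-column matrix
#'   of half-open index intervals `[start, end)`.
#' @export
detect_strides <- function(labels, load_threshold = NULL) {
  if (!is.null(load_threshold)) {
    x <- as.numeric(labels)
    td <- which(x[-1] > load_threshold & x[-length(x)] <= load_threshold) + 1L
  } else {
    n <- length(labels)
    td <- which(labels[-1] == "ES" & labels[-n] == "LN") + 1L
  }
  if (length(td) < 2L) {
    stop("fewer than 2 touchdowns: no complete stride", call. = FALSE)
  }
  strides <- cbind(start = td[-length(td)], end = td[-1])
  list(touchdowns = td, strides = strides)
}

#' Write / read leg-state time series CSVs
#'
#' Columns `t, sagittal_pos_L, sagittal_pos_R, load_L, load_R`; labeled output
#' appends `phase_L, phase_R`.
#'
#' @param df Data frame with the columns above.
#' @param path CSV path.
#' @return `path` invisibly (write); the data frame (read).
#' @export
write_leg_trace <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_leg_trace
#' @export
read_leg_trace <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)
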