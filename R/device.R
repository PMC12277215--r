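# Damper-clutch device model and the design space it induces.

#' Canonical gait phase identifiers
#'
#' The five phases of the gait cycle used throughout the package, in canonical
#' order: Early Stance (`"ES"`), Late Stance (`"LS"`), Lift Off (`"LO"`),
#' Swing (`"SW"`), Landing (`"LN"`).
#'
#' @return Character vector of length 5.
#' @export
gait_phases <- function() c("ES", "LS", "LO", "SW", "LN")

#' Design parameters of the damper-clutch knee device
#'
#' A design is a damping coefficient `c` (N·m·s/rad) plus a clutch engagement
#' pattern: the nonempty subset of gait phases during which the rotational
#' damper is mechanically engaged. The empty pattern is the no-device baseline
#' and is excluded from the design space.
#'
#' @param damping_coefficient Damping coefficient, N·m·s/rad, `>= 0`.
#' @param clutch_pattern Character vector: nonempty subset of [gait_phases()].
#' @param c_max Upper bound the coefficient must respect.
#' @return An object of class `design_params`.
#' @export
design_params <- function(damping_coefficient, clutch_pattern, c_max = 5) {
  if (!is.numeric(damping_coefficient) || length(damping_coefficient) != 1L ||
      !is.finite(damping_coefficient) || damping_coefficient < 0) {
    stop("`damping_coefficient` must be a single finite number >= 0", call. = FALSE)
  }
  if (damping_coefficient > c_max) {
    stop("`damping_coefficient` exceeds c_max (", c_max, ")", call. = FALSE)
  }
  clutch_pattern <- as.character(clutch_pattern)
  if (length(clutch_pattern) == 0L) {
    stop("`clutch_pattern` must be nonempty (empty pattern = no-device baseline)",
         call. = FALSE)
  }
  if (anyDuplicated(clutch_pattern) || !all(clutch_pattern %in% gait_phases())) {
    stop("`clutch_pattern` must be a duplicate-free subset of ",
         paste(gait_phases(), collapse = ", "), call. = FALSE)
  }
  # store in canonical phase order
  clutch_pattern <- gait_phases()[gait_phases() %in% clutch_pattern]
  structure(list(damping_coefficient = damping_coefficient,
                 clutch_pattern = clutch_pattern),
            class = "design_params")
}

#' @export
print.design_params <- function(x, ...) {
  cat(sprintf("<design_params> c = %g N·m·s/rad, clutch = {%s}\n",
              x$damping_coefficient, paste(x$clutch_pattern, collapse = ",")))
  invisible(x)
}

#' Resisting torque of the linear rotational knee damper
#'
#' When the clutch is engaged the damper applies `-c * omega`, a torque that
#' always opposes knee angular velocity; when disengaged it applies exactly
#' zero. Vectorized over `omega_knee` and `engaged`.
#'
#' @param c Damping coefficient, N·m·s/rad, scalar `>= 0`.
#' @param omega_knee Knee angular velocity, rad/s (flexion positive).
#' @param engaged Logical: clutch engaged at each sample.
#' @return Torque, N·m, same length as `omega_knee`.
#' @export
damper_torque <- function(c, omega_knee, engaged) {
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c < 0) {
    stop("`c` must be a single finite number >= 0", call. = FALSE)
  }
  ifelse(engaged, -c * omega_knee, 0)
}

#' Enumerate all clutch engagement patterns
#'
#' Every nonempty subset of the supplied phases, deterministically ordered by
#' the binary mask over the canonical phase order (bit 1 = first phase).
#'
#' @param phases Character vector of unique phase identifiers.
#' @return List of character vectors; `2^length(phases) - 1` patterns.
#' @export
enumerate_clutch_patterns <- function(phases = gait_phases()) {
  phases <- as.character(phases)
  if (length(phases) == 0L) stop("`phases` must be nonempty", call. = FALSE)
  if (anyDuplicated(phases)) stop("duplicate phase identifiers", call. = FALSE)
  n <- length(phases)
  lapply(seq_len(2^n - 1L), function(mask) {
    phases[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
  })
}

#' Integer mask of a clutch pattern
#'
#' 5-bit mask over the canonical phase order: bit 1 = ES, ..., bit 5 = LN.
#'
#' @param pattern Character vector of phases.
#' @param phases Canonical phase order.
#' @return Integer in `1..31` for nonempty patterns.
#' @export
pattern_mask <- function(pattern, phases = gait_phases()) {
  sum(bitwShiftL(1L, which(phases %in% pattern) - 1L))
}

#' Design space of the damper-clutch device
#'
#' An evenly spaced damping grid (both endpoints inclusive) crossed with a set
#' of clutch patterns (all 31 nonempty subsets unless restricted).
#'
#' @param c_min,c_max Damping bounds, N·m·s/rad.
#' @param n_grid Number of damping grid values.
#' @param patterns List of clutch patterns; default all nonempty subsets.
#' @return An object of class `design_space`.
#' @export
design_space <- function(c_min = 0, c_max = 5, n_grid = 41,
                         patterns = enumerate_clutch_patterns()) {
  if (n_grid < 1L) stop("`n_grid` must be >= 1", call. = FALSE)
  if (!(c_max > c_min)) stop("need c_max > c_min", call. = FALSE)
  if (c_min < 0) stop("`c_min` must be >= 0", call. = FALSE)
  structure(list(c_min = c_min, c_max = c_max, n_grid = as.integer(n_grid),
                 patterns = patterns,
                 c_grid = if (n_grid == 1L) c_min else
                   seq(c_min, c_max, length.out = n_grid)),
            class = "design_space")
}

#' Full-factorial design grid
#'
#' Cross product of the damping grid and the clutch patterns, e.g. 41 damping
#' values x 31 patterns = 1271 unique designs.
#'
#' @param space A [design_space()].
#' @return List of [design_params()] of length `n_grid * length(patterns)`.
#' @export
build_design_grid <- function(space) {
  stopifnot(inherits(space, "design_space"))
  out <- vector("list", space$n_grid * length(space$patterns))
  k <- 0L
  for (p in space$patterns) {
    for (cv in space$c_grid) {
      k <- k + 1L
      out[[k]] <- design_params(cv, p, c_max = space$c_max)
    }
  }
  out
}

#' Derive the damping upper bound from a baseline gait
#'
#' `c_max = max|knee moment| / max|knee angular velocity|` of a baseline
#' (no-device) simulation: at that coefficient the damper could, at peak
#' velocity, supply the full peak biological moment.
#'
#' @param sim A `sim_result` from [simulate_gait()].
#' @return c_max in N·m·s/rad.
#' @export
derive_c_max <- function(sim) {
  stopifnot(inherits(sim, "sim_result"))
  m <- max(abs(sim$series$knee_moment_R), abs(sim$series$knee_moment_L))
  w <- max(abs(sim$series$knee_omega_R), abs(sim$series$knee_omega_L))
  m / w
}

#' Serialize a design grid to CSV
#'
#' Columns `c, pattern_mask, pattern_names`; the mask is the 5-bit integer
#' over canonical phase order.
#'
#' @param designs List of [design_params()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_design_grid <- function(designs, path) {
  df <- data.frame(
    c = vapply(designs, function(d) d$damping_coefficient, numeric(1)),
    pattern_mask = vapply(designs, function(d) pattern_mask(d$clutch_pattern),
                          integer(1)),
    pattern_names = vapply(designs, function(d)
      paste(d$clutch_pattern, collapse = "+"), character(1))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a design grid written by [write_design_grid()]
#'
#' @param path CSV path.
#' @param c_max Bound used to validate coefficients.
#' @return List of [design_params()].
#' @export
read_design_grid <- function(path, c_max = 5) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  phases <- gait_phases()
  lapply(seq_len(nrow(df)), function(i) {
    mask <- df$pattern_mask[i]
    design_params(df$c[i], phases[bitwAnd(mask, bitwShiftL(1L, 0:4)) != 0L],
                  c_max = c_max)
  })
}
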