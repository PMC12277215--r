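# Stride-normalized curve aggregation, peak extraction, and figure-style
# table export.

#' Normalize a time series to the gait cycle
#'
#' Each stride (touchdown to next touchdown of the same leg) is linearly
#' resampled to `n_points` equally spaced points spanning 0-100% of the
#' cycle; the mean and standard deviation are taken across cycles.
#'
#' @param series Numeric series on the simulation time grid.
#' @param strides Stride structure from [detect_strides()].
#' @param n_points Normalization resolution (default 101: 0, 1, ..., 100%).
#' @param name,units Variable metadata carried on the result.
#' @return A `cycle_curves` object: `cycles` (matrix cycles x points),
#'   `mean`, `sd`, `pct`, `name`, `units`.
#' @export
normalize_to_gait_cycle <- function(series, strides, n_points = 101,
                                    name = "", units = "") {
  if (is.null(strides) || nrow(strides$strides) < 1L) {
    stop("no strides to normalize over", call. = FALSE)
  }
  if (n_points < 2L) stop("need n_points >= 2", call. = FALSE)
  pct <- seq(0, 100, length.out = n_points)
  cyc <- t(apply(strides$strides, 1, function(b) {
    idx <- b[1]:b[2]  # include the closing touchdown so 100% is defined
    stats::approx(seq(0, 100, length.out = length(idx)), series[idx],
                  xout = pct)$y
  }))
  if (nrow(strides$strides) == 1L) cyc <- matrix(cyc, nrow = 1L)
  m <- colMeans(cyc)
  s <- if (nrow(cyc) > 1L) apply(cyc, 2, stats::sd) else rep(0, n_points)
  structure(list(cycles = cyc, mean = m, sd = s, pct = pct,
                 name = name, units = units),
            class = "cycle_curves")
}

#' Peak metrics of a cycle-normalized curve
#'
#' Maximum, minimum and their cycle-% locations within the Stance and Swing
#' windows, split at the Toe-Off index (the ipsilateral Lift Off -> Swing
#' transition).
#'
#' @param curves A `cycle_curves` object.
#' @param toe_off_pct Cycle percentage of Toe Off.
#' @return Data frame `window, max, max_pct, min, min_pct`.
#' @export
peak_metrics <- function(curves, toe_off_pct = 60) {
  stopifnot(inherits(curves, "cycle_curves"))
  m <- curves$mean
  pct <- curves$pct
  one <- function(idx, label) {
    data.frame(window = label,
               max = max(m[idx]), max_pct = pct[idx][which.max(m[idx])],
               min = min(m[idx]), min_pct = pct[idx][which.min(m[idx])])
  }
  rbind(one(which(pct <= toe_off_pct), "stance"),
        one(which(pct > toe_off_pct), "swing"))
}

#' Toe-Off location of a simulated gait
#'
#' Mean cycle percentage of the ipsilateral Lift Off -> Swing transition
#' across strides of the right leg.
#'
#' @param sim A `sim_result` with detected strides.
#' @return Cycle percentage in `[0, 100]`.
#' @export
toe_off_pct <- function(sim) {
  ph <- sim$series$phase_R
  st <- sim$strides$strides
  pcts <- apply(st, 1, function(b) {
    idx <- b[1]:(b[2] - 1L)
    k <- which(ph[idx][-1] == "SW" & ph[idx][-length(idx)] == "LO")
    if (length(k) == 0L) return(NA_real_)
    100 * k[1] / length(idx)
  })
  mean(pcts, na.rm = TRUE)
}

#' Export a brute-force cost table as a long-format heat-map CSV
#'
#' Columns `c, pattern_mask, cost`; missing cells are written as explicit
#' `NA`. A round-trip read reproduces the values bit-exactly (full-precision
#' formatting).
#'
#' @param table Data frame from [brute_force()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
export_heatmap_table <- function(table, path) {
  stopifnot(all(c("c", "pattern_mask", "cost") %in% names(table)))
  out <- table[, c("c", "pattern_mask", "cost")]
  out$c <- formatC(out$c, format = "g", digits = 17)
  out$cost <- formatC(out$cost, format = "g", digits = 17)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read back a heat-map table written by [export_heatmap_table()]
#'
#' @param path CSV path.
#' @return Data frame `c, pattern_mask, cost`.
#' @export
read_heatmap_table <- function(path) {
  utils::read.csv(path, colClasses = c("numeric", "integer", "numeric"))
}

#' Export a cycle-normalized curve as CSV
#'
#' Columns `pct, mean, std`.
#'
#' @param curves A `cycle_curves`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cycle_curve <- function(curves, path) {
  utils::write.csv(data.frame(pct = curves$pct, mean = curves$mean,
                              std = curves$sd),
                   path, row.names = FALSE)
  invisible(path)
}
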