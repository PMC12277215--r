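# Inner loop: movement cost and CMA-ES optimization of the controller vector,
# warm-started from a baseline solution with small per-coordinate step sizes
# so the optimized gait stays near the baseline gait.

#' Inner (movement) cost configuration
#'
#' Weights and limits of the four-term movement cost: a squared speed-error
#' penalty, a mass-normalized metabolic effort term, ankle-position and
#' knee-force penalties (mean squared excess beyond limits), and a GRF
#' penalty (mean excess of normalized GRF above a threshold). Weights default
#' to an order-of-magnitude balance at the packaged baseline gait.
#'
#' @param velocity_weight,velocity_target Speed penalty weight and target (m/s).
#' @param effort_weight Weight on metabolic energy / duration / mass (W/kg).
#' @param ankle_weight,ankle_limits Ankle penalty weight and `c(lo, hi)` rad.
#' @param knee_force_weight,knee_force_limit Knee-load penalty weight and
#'   limit (body-weight fraction).
#' @param grf_weight,grf_threshold GRF penalty weight and threshold
#'   (body-weight fraction).
#' @return An object of class `inner_cost_config`.
#' @export
inner_cost_config <- function(velocity_weight = 100, velocity_target = 1.2,
                              effort_weight = 1,
                              ankle_weight = 10, ankle_limits = c(-0.7, 0.7),
                              knee_force_weight = 10, knee_force_limit = 2,
                              grf_weight = 10, grf_threshold = 1.4) {
  w <- c(velocity_weight, effort_weight, ankle_weight, knee_force_weight,
         grf_weight)
  if (any(w < 0) || all(w == 0)) {
    stop("weights must be >= 0 with at least one > 0", call. = FALSE)
  }
  structure(list(velocity_weight = velocity_weight,
                 velocity_target = velocity_target,
                 effort_weight = effort_weight,
                 ankle_weight = ankle_weight, ankle_limits = ankle_limits,
                 knee_force_weight = knee_force_weight,
                 knee_force_limit = knee_force_limit,
                 grf_weight = grf_weight, grf_threshold = grf_threshold),
            class = "inner_cost_config")
}

#' Movement cost of a simulated gait
#'
#' Term structure: `velocity = w (mean_speed - target)^2`;
#' `effort = w metabolic_energy / duration / mass`; ankle and knee-force
#' terms are the weighted mean squared excess beyond their limits (zero
#' inside); the GRF term is the weighted mean excess of normalized GRF
#' magnitude above the threshold. The total is the sum of the five terms.
#'
#' @param sim A `sim_result` with at least one complete stride.
#' @param cfg An [inner_cost_config()].
#' @return A `cost_breakdown`: per-term values and `total`.
#' @export
inner_cost <- function(sim, cfg = inner_cost_config()) {
  stopifnot(inherits(sim, "sim_result"))
  if (is.null(sim$strides)) {
    stop("no complete stride in the simulation result", call. = FALSE)
  }
  s <- sim$series
  vel <- cfg$velocity_weight * (sim$metrics$mean_speed - cfg$velocity_target)^2
  eff <- cfg$effort_weight * sim$metrics$metabolic_energy /
    sim$metrics$duration / sim$metrics$total_mass
  ank <- c(s$ankle_R, s$ankle_L)
  exc_a <- pmax(ank - cfg$ankle_limits[2], 0) + pmax(cfg$ankle_limits[1] - ank, 0)
  ankle_term <- cfg$ankle_weight * mean(exc_a^2)
  kl <- c(s$knee_load_R, s$knee_load_L)
  knee_term <- cfg$knee_force_weight * mean(pmax(kl - cfg$knee_force_limit, 0)^2)
  grf <- c(s$leg_load_R, s$leg_load_L)
  grf_term <- cfg$grf_weight * mean(pmax(grf - cfg$grf_threshold, 0))
  terms <- c(velocity = vel, effort = eff, ankle = ankle_term,
             knee_force = knee_term, grf = grf_term)
  structure(list(terms = terms, total = sum(terms)), class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown> total =", format(x$total), "\n")
  print(round(x$terms, 6))
  invisible(x)
}

#' CMA-ES minimization
#'
#' Covariance Matrix Adaptation Evolution Strategy (rank-mu + rank-one
#' updates, cumulative step-size adaptation) with per-coordinate initial
#' standard deviations: the search distribution starts at
#' `N(theta_mean, diag(theta_std^2))`, so small `theta_std` bounds the
#' deviation from the warm start. The mean is evaluated first, guaranteeing
#' the returned best is never worse than the starting point.
#'
#' @param evaluator Function mapping a numeric vector to a finite cost (may
#'   return `Inf` for invalid candidates).
#' @param theta_mean Numeric start vector.
#' @param theta_std Positive per-coordinate initial standard deviations.
#' @param budget Maximum number of evaluations (`>=` one generation).
#' @param seed Integer seed; identical seeds give identical traces.
#' @param popsize Population size; default `4 + floor(3 log(dim))`.
#' @return List: `par` (best vector), `value` (best cost), `trace`
#'   (data frame `eval, cost, best`), `status` (`"ok"` or `"all_invalid"`).
#' @export
optimize_controller <- function(evaluator, theta_mean, theta_std,
                                budget = 500, seed = 1, popsize = NULL) {
  d <- length(theta_mean)
  stopifnot(length(theta_std) == d, all(theta_std > 0))
  lambda <- if (is.null(popsize)) 4L + floor(3 * log(d)) else as.integer(popsize)
  if (budget < lambda) stop("budget below one CMA-ES generation", call. = FALSE)
  set.seed(as.integer(seed))

  mu <- floor(lambda / 2)
  wts <- log(mu + 0.5) - log(seq_len(mu))
  wts <- wts / sum(wts)
  mueff <- 1 / sum(wts^2)
  cc <- (4 + mueff / d) / (d + 4 + 2 * mueff / d)
  cs <- (mueff + 2) / (d + mueff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((d + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  # work in coordinates scaled by theta_std so sigma is scalar
  scale <- theta_std
  xmean <- theta_mean / scale
  sigma <- 1
  pc <- ps <- numeric(d)
  C <- diag(d)
  ev <- function(x) {
    v <- evaluator(x * scale)
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) Inf else v
  }

  # warm-start reference: evaluate the mean first (not counted against the
  # budget) so the returned best can never be worse than the starting point
  f0 <- ev(xmean)
  best_x <- xmean
  best_f <- f0
  n_eval <- 0L
  trace <- data.frame(eval = integer(0), cost = numeric(0))

  while (n_eval + lambda <= budget) {
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    arz <- matrix(stats::rnorm(d * lambda), d, lambda)
    ary <- B %*% (D * arz)
    arx <- xmean + sigma * ary
    fit <- apply(arx, 2, ev)
    n_eval <- n_eval + lambda
    ord <- order(fit)
    if (fit[ord[1]] < best_f) {
      best_f <- fit[ord[1]]
      best_x <- arx[, ord[1]]
    }
    trace <- rbind(trace, data.frame(eval = seq(n_eval - lambda + 1L, n_eval),
                                     cost = fit))
    sel <- ord[seq_len(mu)]
    if (!is.finite(fit[ord[1]])) next  # whole generation invalid: resample
    ymean <- ary[, sel, drop = FALSE] %*% wts
    xmean <- xmean + sigma * as.numeric(ymean)
    # cumulative step-size adaptation
    Cinvsq_y <- B %*% ((1 / D) * crossprod(B, ymean))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * as.numeric(Cinvsq_y)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * n_eval / lambda)) / chiN < 1.4 + 2 / (d + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * as.numeric(ymean)
    artmp <- ary[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * artmp %*% (wts * t(artmp))
    C <- (C + t(C)) / 2
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    sigma <- min(sigma, 1e4)
  }
  trace$best <- pmin(cummin(trace$cost), f0)
  status <- if (is.finite(best_f)) "ok" else "all_invalid"
  list(par = best_x * scale, value = best_f, trace = trace, status = status,
       f_start = f0, n_eval = n_eval, popsize = lambda)
}

#' Optimize the gait controller for a candidate device design
#'
#' Wraps [optimize_controller()] around [simulate_gait()] + [inner_cost()]:
#' invalid simulations receive an infinite cost so CMA-ES discards them.
#'
#' @param design A [design_params()] or `NULL` (baseline).
#' @param theta0 Warm-start [controller_theta()].
#' @param scenario A [scenario_config()].
#' @param cfg An [inner_cost_config()].
#' @param anthro An [anthropometry()].
#' @param std_frac Initial step size as a fraction of characteristic
#'   coordinate scales (small, to stay near the baseline solution).
#' @param budget,seed,popsize Passed to [optimize_controller()].
#' @return List: `theta` (best [controller_theta()]), `sim` (its simulation),
#'   `cost`, `trace`, `status`.
#' @export
optimize_gait <- function(design, theta0, scenario,
                          cfg = inner_cost_config(
                            velocity_target = scenario$target_speed),
                          anthro = anthropometry(), std_frac = 1,
                          budget = 400, seed = 1, popsize = NULL) {
  x0 <- theta_to_vector(theta0)
  # characteristic scales: stride timing/length a few percent, angles ~0.01 rad
  scales <- c(0.01, 0.02, rep(0.01, 5), rep(0.01, 5), rep(0.01, 3),
              c(0.002, 0.05), 0.01) * std_frac
  evaluator <- function(x) {
    th <- tryCatch(vector_to_theta(x), error = function(e) NULL)
    if (is.null(th)) return(Inf)
    sim <- tryCatch(simulate_gait(th, scenario, design = design,
                                  anthro = anthro),
                    error = function(e) NULL)
    if (is.null(sim) || !sim$valid || is.null(sim$strides)) return(Inf)
    inner_cost(sim, cfg)$total
  }
  res <- optimize_controller(evaluator, x0, scales, budget = budget,
                             seed = seed, popsize = popsize)
  theta_best <- vector_to_theta(res$par)
  sim_best <- simulate_gait(theta_best, scenario, design = design,
                            anthro = anthro)
  list(theta = theta_best, sim = sim_best, cost = res$value,
       trace = res$trace, status = res$status)
}

#' Write an inner-loop evaluation trace to CSV
#'
#' @param trace Data frame from [optimize_controller()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_inner_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
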