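# Inner loop: movement cost and CMA-ES.

make_fake_sim <- function(n = 200, speed = 1.2, energy = 3000, duration = 10,
                          mass = 75, ankle = rep(0, n), knee_load = rep(2, n),
                          leg_load = rep(0.8, n)) {
  structure(list(
    series = data.frame(ankle_R = ankle, ankle_L = ankle,
                        knee_load_R = knee_load, knee_load_L = knee_load,
                        leg_load_R = leg_load, leg_load_L = leg_load),
    metrics = list(mean_speed = speed, metabolic_energy = energy,
                   duration = duration, total_mass = mass),
    valid = TRUE,
    strides = list(strides = cbind(start = 1L, end = as.integer(n)))
  ), class = "sim_result")
}

test_that("inner_cost: only the effort term survives an in-limits gait at target speed", {
  cfg <- inner_cost_config(velocity_target = 1.2)
  cb <- inner_cost(make_fake_sim(), cfg)
  expect_equal(unname(cb$terms["velocity"]), 0)
  expect_equal(unname(cb$terms["ankle"]), 0)
  expect_equal(unname(cb$terms["knee_force"]), 0)
  expect_equal(unname(cb$terms["grf"]), 0)
  expect_equal(unname(cb$terms["effort"]), 3000 / 10 / 75)
  expect_equal(cb$total, sum(cb$terms), tolerance = 1e-12)
})

test_that("inner_cost velocity term: 0.1 m/s off target with weight 100 costs 1.0", {
  cfg <- inner_cost_config(velocity_weight = 100, velocity_target = 1.2,
                           effort_weight = 0, ankle_weight = 0,
                           knee_force_weight = 0, grf_weight = 0)
  cb <- inner_cost(make_fake_sim(speed = 1.3), cfg)
  expect_equal(cb$total, 1.0, tolerance = 1e-12)
})

test_that("inner_cost penalty terms match a brute-force per-sample oracle", {
  set.seed(11)
  n <- 300
  ankle <- stats::rnorm(n, 0, 0.6)
  kl <- stats::runif(n, 4, 8)
  grf <- stats::runif(n, 0.5, 2.0)
  cfg <- inner_cost_config(velocity_target = 1.2, ankle_limits = c(-0.7, 0.7),
                           knee_force_limit = 6, grf_threshold = 1.4)
  cb <- inner_cost(make_fake_sim(n = n, ankle = ankle, knee_load = kl,
                                 leg_load = grf), cfg)
  # oracle: explicit loops over both legs' samples
  a2 <- c(ankle, ankle)
  exc <- numeric(length(a2))
  for (i in seq_along(a2)) {
    if (a2[i] > 0.7) exc[i] <- a2[i] - 0.7
    if (a2[i] < -0.7) exc[i] <- -0.7 - a2[i]
  }
  expect_equal(unname(cb$terms["ankle"]), 10 * mean(exc^2), tolerance = 1e-12)
  k2 <- c(kl, kl)
  expect_equal(unname(cb$terms["knee_force"]),
               10 * mean(pmax(k2 - 6, 0)^2), tolerance = 1e-12)
  g2 <- c(grf, grf)
  expect_equal(unname(cb$terms["grf"]), 10 * mean(pmax(g2 - 1.4, 0)),
               tolerance = 1e-12)
})

test_that("inner_cost requires a complete stride and valid weights", {
  sim <- make_fake_sim()
  sim$strides <- NULL
  expect_error(inner_cost(sim), "stride")
  expect_error(inner_cost_config(velocity_weight = -1), "weights")
  expect_error(inner_cost_config(velocity_weight = 0, effort_weight = 0,
                                 ankle_weight = 0, knee_force_weight = 0,
                                 grf_weight = 0), "weights")
})

test_that("CMA-ES finds the minimum of a 6-d quadratic bowl", {
  target <- c(1.2, -0.5, 0.3, 2.0, -1.1, 0.7)
  f <- function(x) sum((x - target)^2)
  res <- optimize_controller(f, rep(0, 6), rep(0.5, 6), budget = 2000,
                             seed = 5)
  expect_lt(max(abs(res$par - target)), 1e-2)
  expect_equal(res$status, "ok")
})

test_that("CMA-ES budget accounting: one generation fills exactly the population", {
  f <- function(x) sum(x^2)
  res <- optimize_controller(f, rep(1, 4), rep(0.3, 4), budget = 8, seed = 1,
                             popsize = 8)
  expect_equal(nrow(res$trace), 8)
  expect_equal(res$n_eval, 8)
  res2 <- optimize_controller(f, rep(1, 4), rep(0.3, 4), budget = 100,
                              seed = 1, popsize = 8)
  expect_lte(res2$n_eval, 100)
  expect_error(optimize_controller(f, rep(1, 4), rep(0.3, 4), budget = 3,
                                   seed = 1, popsize = 8), "generation")
})

test_that("CMA-ES is deterministic under a fixed seed", {
  f <- function(x) sum((x - 2)^2) + 0.1 * sum(abs(x))
  r1 <- optimize_controller(f, rep(0, 5), rep(0.4, 5), budget = 300, seed = 9)
  r2 <- optimize_controller(f, rep(0, 5), rep(0.4, 5), budget = 300, seed = 9)
  expect_identical(r1$value, r2$value)
  expect_identical(r1$par, r2$par)
  expect_identical(r1$trace, r2$trace)
})

test_that("best-so-far trace is non-increasing and never above the warm start", {
  f <- function(x) sum(x^2) + stats::rnorm(1, 0, 0.01)  # noisy objective
  res <- optimize_controller(f, rep(3, 4), rep(0.5, 4), budget = 200, seed = 2)
  expect_true(all(diff(res$trace$best) <= 0))
  expect_lte(res$value, res$f_start)
})

test_that("warm start: tiny stds keep the solution at the start point", {
  f <- function(x) sum((x - 5)^2)
  res <- optimize_controller(f, rep(0, 4), rep(1e-8, 4), budget = 200,
                             seed = 3)
  expect_lt(max(abs(res$par - 0)), 1e-4)
})

test_that("an always-invalid evaluator reports failure with a full trace", {
  f <- function(x) Inf
  res <- optimize_controller(f, rep(0, 3), rep(0.2, 3), budget = 50, seed = 1)
  expect_equal(res$status, "all_invalid")
  expect_gt(nrow(res$trace), 0)
})

test_that("optimized gait cost never exceeds the warm-start cost (assisted preset)", {
  bl <- cached_optimized_baseline("level")
  d <- design_params(2, c("ES", "LS"))
  base_sim <- simulate_gait(bl$theta_warm, bl$scenario, design = d,
                            anthro = bl$anthro)
  base_cost <- inner_cost(base_sim, inner_cost_config(
    velocity_target = bl$scenario$target_speed))$total
  opt <- optimize_gait(d, bl$theta_warm, bl$scenario, anthro = bl$anthro,
                       budget = 100, seed = 4, std_frac = 0.2)
  expect_lte(opt$cost, base_cost)
})
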