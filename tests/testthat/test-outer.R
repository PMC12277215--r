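# Outer loop: metrics, design cost, GP-guided Bayesian optimization,
# brute force, restarts.

test_that("knee_load_statistic implements top-q% per stride, averaged", {
  st1 <- list(strides = cbind(start = 1L, end = 11L))
  expect_equal(knee_load_statistic(c(1:10, 99), st1, q = 20), 9.5)
  # constant load across strides
  stc <- list(strides = cbind(start = c(1L, 11L), end = c(11L, 21L)))
  expect_equal(knee_load_statistic(rep(2.5, 21), stc, q = 10), 2.5)
  # two strides with known per-stride top-q means a and b -> (a+b)/2
  load <- c(1:10, 21:30, 0)
  a <- mean(c(9, 10)); b <- mean(c(29, 30))
  expect_equal(knee_load_statistic(load, stc, q = 20), (a + b) / 2)
  # both legs: unweighted mean over all strides of both legs
  expect_equal(knee_load_statistic(load, st1, load_L = load, strides_L = stc,
                                   q = 20), mean(c(a, a, b)))
  expect_error(knee_load_statistic(1:10, st1, q = 0), "q")
  expect_error(knee_load_statistic(1:10, NULL), "strides")
})

test_that("cost_of_transport is energy over distance", {
  expect_equal(cost_of_transport(3000, 12), 250)
  expect_equal(cost_of_transport(0, 12), 0)
  expect_equal(cost_of_transport(300 * 10, 12), 250)  # constant power E = P T
  expect_error(cost_of_transport(100, 0), "positive")
})

test_that("outer_cost normalizes against baseline and penalizes invalid runs", {
  cfg <- outer_cost_config(w1 = 0.5, w2 = 0.5, penalty = 10,
                           baseline = list(knee_load = 4, cot = 500))
  expect_equal(outer_cost(list(knee_load = 4, cot = 500), cfg), 1.0)
  expect_equal(outer_cost(list(knee_load = 3.2, cot = 450), cfg),
               0.5 * 0.8 + 0.5 * 0.9)
  expect_equal(outer_cost(list(knee_load = 3.2, cot = 450), cfg,
                          valid = FALSE), 10)
  cfg_bad <- outer_cost_config(baseline = list(knee_load = 0, cot = 500))
  expect_error(outer_cost(list(knee_load = 1, cot = 1), cfg_bad), "baseline")
  expect_error(outer_cost_config(w1 = 0, w2 = 0), "w1")
})

test_that("protocol_config validates its invariants", {
  p <- protocol_config()
  expect_equal(p$n_initial, 10)
  expect_equal(p$window, 15)
  expect_equal(p$max_iter, 100)
  expect_error(protocol_config(n_initial = 0), "n_initial")
  expect_error(protocol_config(max_iter = 20), "max_iter")
})

test_that("surrogate GP recovers structure: BO run obeys the protocol", {
  spec <- surrogate_spec()
  space <- design_space()
  ev <- function(d) surrogate_cost(d, spec)
  tr <- bayes_optimize(space, ev, protocol_config(), seed = 3)
  expect_lte(nrow(tr), 100)
  expect_identical(tr$acquisition[1:10], rep("random", 10))
  expect_true(all(tr$acquisition[-(1:10)] %in% c("LCB", "EI", "PI")))
  expect_true(all(diff(tr$best) <= 0))
  expect_true(attr(tr, "termination") %in% c("converged", "budget"))
})

test_that("BO is deterministic under a fixed seed", {
  spec <- surrogate_spec()
  space <- design_space()
  ev <- function(d) surrogate_cost(d, spec)
  t1 <- bayes_optimize(space, ev, seed = 12)
  t2 <- bayes_optimize(space, ev, seed = 12)
  expect_identical(t1$cost, t2$cost)
  expect_identical(t1$c, t2$c)
  expect_identical(attr(t1, "best_cost"), attr(t2, "best_cost"))
})

test_that("constant objective terminates at exactly n_initial + window evaluations", {
  space <- design_space()
  ev <- function(d) 1.0
  pr <- protocol_config(n_initial = 10, window = 15, eps = 1e-6)
  tr <- bayes_optimize(space, ev, pr, seed = 1)
  expect_equal(nrow(tr), 25)
  expect_identical(attr(tr, "termination"), "converged")
})

test_that("eps = 0 on a noisy objective runs to the iteration budget", {
  space <- design_space()
  set.seed(99)
  ev <- function(d) stats::rnorm(1)
  pr <- protocol_config(eps = 0, max_iter = 40)
  tr <- bayes_optimize(space, ev, pr, seed = 2)
  expect_equal(nrow(tr), 40)
  expect_identical(attr(tr, "termination"), "budget")
})

test_that("an evaluator that always throws yields a penalty trace ending at budget", {
  space <- design_space()
  ev <- function(d) stop("boom")
  pr <- protocol_config(eps = 1e-6, max_iter = 30)
  tr <- bayes_optimize(space, ev, pr, seed = 4)
  expect_true(all(!is.finite(tr$cost)))
  expect_identical(attr(tr, "termination"), "budget")
  expect_equal(nrow(tr), 30)
})

test_that("brute force covers the grid and finds the surrogate's optimum cell", {
  spec <- surrogate_spec(sigma = 0)  # noiseless: analytic oracle applies
  space <- design_space(n_grid = 41)
  ev <- function(d) surrogate_cost(d, spec)
  tab <- brute_force(space, ev)
  expect_equal(nrow(tab), 1271)
  # noiseless values match the closed form everywhere
  want <- vapply(build_design_grid(space), function(d)
    surrogate_mean(d, spec), numeric(1))
  expect_equal(tab$cost, want)
  # the argmin is the analytic optimum's grid neighbor
  best <- tab[which.min(tab$cost), ]
  expect_equal(best$pattern_mask, pattern_mask(spec$p_star))
  expect_lte(abs(best$c - spec$c_star), diff(space$c_grid[1:2]) / 2 + 1e-12)
  # single-cell grid
  sp1 <- design_space(n_grid = 1, patterns = list("ES"))
  expect_equal(nrow(brute_force(sp1, ev)), 1)
})

test_that("run_restarts returns the argmin run and summarize_restarts the summary", {
  space <- design_space()
  spec <- surrogate_spec()
  ev <- function(d) surrogate_cost(d, spec)
  rs <- run_restarts(space, ev, protocol_config(max_iter = 30, eps = 1e-2),
                     seeds = 1:3)
  expect_equal(rs$best_cost, min(rs$best_costs))
  expect_identical(rs$best_run, which.min(rs$best_costs))
  expect_length(rs$traces, 3)
  expect_error(run_restarts(space, ev, seeds = c(1, 1)), "distinct")

  s <- summarize_restarts(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)
  expect_equal(s$q25, 2)
  expect_equal(s$q75, 4)
  # KDE integrates to ~1
  kde <- s$kde
  expect_equal(sum(kde$density[-1] * diff(kde$x)), 1, tolerance = 1e-3)
  s1 <- summarize_restarts(0.9)
  expect_equal(s1$median, 0.9)
  expect_equal(s1$min, s1$max)
  expect_error(summarize_restarts(numeric(0)), "finite")
})

test_that("evaluate_design: zero-damping device reproduces the baseline exactly", {
  bl <- cached_optimized_baseline("level")
  r0 <- evaluate_design(design_params(0, "ES"), bl)
  expect_true(r0$valid)
  expect_equal(r0$cost, 1.0, tolerance = 1e-12)
})

test_that("evaluate_design returns the penalty when the inner loop cannot find a valid gait", {
  bl <- cached_optimized_baseline("level")
  bl$scenario <- scenario_config(target_speed = 3, speed_tolerance = 0.05)
  r <- evaluate_design(design_params(2, "ES"), bl,
                       cfg = outer_cost_config(penalty = 10,
                                               baseline = bl$metrics),
                       inner_budget = 50)
  expect_false(r$valid)
  expect_equal(r$cost, 10)
})
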