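# Reduced gait model: kinematics synthesis, inverse dynamics, knee load,
# metabolic proxy, simulation pipeline.

test_that("Fourier synthesis: zero harmonics give constant posture, amplitudes set range", {
  sc <- scenario_config(duration = 2)
  th <- static_theta(hip0 = 0.1, knee0 = 0.3)
  kin <- generate_kinematics(th, sc)
  expect_equal(kin$knee_R, rep(0.3, kin$n))
  expect_equal(kin$knee_omega_R, rep(0, kin$n))
  expect_equal(kin$hip_R, rep(0.1, kin$n))
  # single harmonic of amplitude A on the knee: range exactly 2A
  th2 <- controller_theta(1, 0, hip = c(0, 0, 0, 0, 0),
                          knee = c(0.6, 0.25, 0, 0, 0))
  kin2 <- generate_kinematics(th2, scenario_config(duration = 2, dt = 0.001))
  expect_equal(diff(range(kin2$knee_R)), 0.5, tolerance = 1e-6)
})

test_that("kinematics are periodic with period T and left = right shifted by T/2", {
  p <- baseline_gait_preset("level")
  sc <- scenario_config(duration = 4, dt = 0.01)
  kin <- generate_kinematics(p$theta, sc, p$anthro)
  Tn <- round(p$theta$T_stride / sc$dt)
  n <- kin$n
  expect_equal(kin$knee_R[1:(n - Tn)], kin$knee_R[(Tn + 1):n],
               tolerance = 1e-9)
  expect_equal(kin$hip_R[1:(n - Tn)], kin$hip_R[(Tn + 1):n],
               tolerance = 1e-9)
  half <- Tn / 2
  expect_equal(kin$knee_L[1:(n - half)], kin$knee_R[(half + 1):n],
               tolerance = 1e-9)
})

test_that("non-finite controller coefficients are rejected", {
  expect_error(controller_theta(1, 1, hip = c(NA, 0, 0, 0, 0),
                                knee = rep(0, 5)), "non-finite")
  expect_error(controller_theta(-1, 1, hip = rep(0, 5), knee = rep(0, 5)),
               "stride period")
})

test_that("static symmetric standing: each leg carries half body weight, no shear", {
  sc <- scenario_config(duration = 2)
  th <- static_theta()
  kin <- generate_kinematics(th, sc)
  dyn <- inverse_dynamics(kin)
  an <- anthropometry()
  bw <- an$total_mass * sc$gravity
  mid <- 50:150  # away from differentiation edges
  expect_equal(dyn$grf_y_R[mid], rep(bw / 2, length(mid)), tolerance = 1e-6)
  expect_equal(dyn$grf_y_L[mid], rep(bw / 2, length(mid)), tolerance = 1e-6)
  expect_equal(dyn$grf_x_R[mid], rep(0, length(mid)), tolerance = 1e-6)
  expect_equal(dyn$leg_load_R[mid], rep(0.5, length(mid)), tolerance = 1e-6)
})

test_that("static single support: stance leg carries full body weight", {
  # quasi-static: stride period far longer than the window, so the posture
  # is frozen with the right knee near straight and the left deeply flexed
  # (the left foot well off the ground)
  sc <- scenario_config(duration = 2, target_speed = 1e-6)
  # ankle harmonic keeps both feet level despite the flexed left knee
  th <- controller_theta(500, 0, hip = c(0, 0, 0, 0, 0),
                         knee = c(0.45, -0.4, 0, 0, 0),
                         ankle = c(0.45, -0.40, 0))
  kin <- generate_kinematics(th, sc)
  dyn <- inverse_dynamics(kin)
  an <- anthropometry()
  bw <- an$total_mass * sc$gravity
  mid <- 50:150
  expect_equal(dyn$grf_y_R[mid] / bw, rep(1, length(mid)), tolerance = 1e-3)
  expect_lt(max(dyn$leg_load_L[mid]), 1e-3)
})

test_that("zero gravity and zero acceleration give zero forces everywhere", {
  sc <- scenario_config(duration = 2, gravity = 0)
  th <- static_theta()
  kin <- generate_kinematics(th, sc)
  dyn <- inverse_dynamics(kin)
  mid <- 50:150
  expect_equal(max(abs(dyn$grf_y_R[mid])), 0, tolerance = 1e-9)
  expect_equal(max(abs(dyn$grf_x_R[mid])), 0, tolerance = 1e-9)
  expect_equal(max(abs(dyn$knee_force_R[mid])), 0, tolerance = 1e-9)
  expect_equal(max(abs(dyn$knee_moment_R[mid])), 0, tolerance = 1e-9)
})

test_that("knee_load is the documented arithmetic and monotone in the moment", {
  expect_equal(knee_load(0, 0, 800), 0)
  expect_equal(knee_load(800, 40, 800, r_eff = 0.04), (800 + 1000) / 800)
  expect_lt(knee_load(800, 20, 800), knee_load(800, 40, 800))
  expect_error(knee_load(1, 1, 800, r_eff = 0), "r_eff")
})

test_that("metabolic_power matches a brute-force per-sample oracle", {
  expect_equal(metabolic_power(matrix(0, 5, 3), basal = 90), rep(90, 5))
  expect_equal(metabolic_power(matrix(100, 1, 1), alpha_pos = 4, basal = 90),
               490)
  set.seed(3)
  P <- matrix(stats::rnorm(300, 0, 60), 100, 3)
  got <- metabolic_power(P, alpha_pos = 4, alpha_neg = 0.8, basal = 90)
  # independent elementwise oracle
  want <- numeric(100)
  for (i in 1:100) {
    acc <- 90
    for (j in 1:3) {
      p <- P[i, j]
      if (p > 0) acc <- acc + 4 * p else acc <- acc + 0.8 * (-p)
    }
    want[i] <- acc
  }
  expect_equal(got, want)
  expect_true(all(got >= 90))
  expect_error(metabolic_power(P, alpha_pos = 0), "alpha_pos")
})

test_that("anthropometry masses sum to total mass", {
  an <- anthropometry(82, 1.80)
  expect_equal(an$m_trunk + 2 * (an$m_thigh + an$m_shank + an$m_foot), 82)
  expect_gt(an$L_thigh, 0)
  expect_error(anthropometry(-1), "total_mass")
})

test_that("simulate_gait: no design and c = 0 design give identical mechanics", {
  p <- baseline_gait_preset("level")
  s0 <- simulate_gait(p$theta, p$scenario, design = NULL, anthro = p$anthro)
  s1 <- simulate_gait(p$theta, p$scenario,
                      design = design_params(0, c("ES", "LS")),
                      anthro = p$anthro)
  num <- vapply(s0$series, is.numeric, logical(1))
  expect_equal(s1$series[num], s0$series[num])
  expect_equal(s1$metrics, s0$metrics)
})

test_that("exo torque is exactly zero outside the clutch pattern and dissipative inside", {
  p <- baseline_gait_preset("level")
  sim <- simulate_gait(p$theta, p$scenario,
                       design = design_params(3, c("ES", "LS")),
                       anthro = p$anthro)
  s <- sim$series
  out_R <- !(s$phase_R %in% c("ES", "LS"))
  expect_identical(unique(s$exo_torque_R[out_R]), 0)
  expect_identical(unique(s$exo_torque_L[!(s$phase_L %in% c("ES", "LS"))]), 0)
  expect_true(all(s$exo_power_R <= 1e-12))
  expect_true(all(s$exo_power_L <= 1e-12))
  # biological knee power >= net knee power pointwise (P_bio = P_net - P_exo)
  expect_true(all(s$knee_power_bio_R - s$knee_power_net_R >= -1e-12))
  # biological moment identity
  expect_equal(s$knee_moment_bio_R, s$knee_moment_R - s$exo_torque_R)
})

test_that("impulse-momentum closure: mean vertical GRF over whole strides equals body weight", {
  for (scen in c("level", "downhill")) {
    sim <- cached_baseline_sim(scen)
    st <- sim$strides$strides
    idx <- st[1, 1]:(st[nrow(st), 2] - 1)
    fy <- sim$series$grf_y_R[idx] + sim$series$grf_y_L[idx]
    expect_equal(mean(fy) / sim$metrics$body_weight, 1, tolerance = 0.01,
                 label = scen)
  }
})

test_that("scalar metrics are stable under time-grid refinement", {
  p <- baseline_gait_preset("level")
  m <- lapply(c(0.01, 0.005), function(dt) {
    sc <- scenario_config(slope_deg = 0, dt = dt)
    sim_outer_metrics(simulate_gait(p$theta, sc, anthro = p$anthro))
  })
  expect_equal(m[[2]]$knee_load / m[[1]]$knee_load, 1, tolerance = 0.005)
  expect_equal(m[[2]]$cot / m[[1]]$cot, 1, tolerance = 0.005)
})

test_that("damper offloads the knee exactly where net power is negative", {
  p <- baseline_gait_preset("level")
  c_d <- 3
  sim <- simulate_gait(p$theta, p$scenario,
                       design = design_params(c_d, c("ES", "LS")),
                       anthro = p$anthro)
  s <- sim$series
  for (leg in c("R", "L")) {
    eng <- s[[paste0("engaged_", leg)]]
    net <- s[[paste0("knee_moment_", leg)]]
    bio <- s[[paste0("knee_moment_bio_", leg)]]
    w <- s[[paste0("knee_omega_", leg)]]
    neg <- eng & (net * w < 0) & (c_d * abs(w) <= abs(net))
    expect_gt(sum(neg), 10)
    expect_equal(abs(bio[neg]), abs(net[neg]) - c_d * abs(w[neg]),
                 tolerance = 1e-12)
  }
})

test_that("validity flags fire on broken gaits", {
  p <- baseline_gait_preset("level")
  # unreachable target speed
  sc_fast <- scenario_config(target_speed = 2.5)
  expect_false(simulate_gait(p$theta, sc_fast, anthro = p$anthro)$valid)
  # knee joint limit violation
  th_bad <- p$theta
  th_bad$knee[1] <- th_bad$knee[1] - 0.5  # drives minimum below 0
  sim_bad <- simulate_gait(th_bad, p$scenario, anthro = p$anthro)
  expect_true("knee_limit" %in% sim_bad$invalid_reasons)
})

test_that("sim_result serializes to CSV + JSON sidecar", {
  sim <- cached_baseline_sim("level")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sim_result(sim, path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(sim$series))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_true(meta$valid)
  expect_equal(meta$mean_speed, sim$metrics$mean_speed, tolerance = 1e-9)
})
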