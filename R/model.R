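# Reduced-order planar gait model: prescribed periodic joint kinematics
# (Fourier synthesis) + Newton-Euler inverse dynamics on a trunk/thigh/shank/
# foot linkage, with ground-slope support and knee exo torque injection.
#
# The pelvis vertical trajectory is not a free parameter: it is the soft
# maximum of the two legs' downward reach (leg extension + heel/toe drop),
# low-pass filtered, which pins the stance foot to the ground for any
# controller vector and keeps ground contact consistent across the whole
# inner-optimizer search space.
# Ground reaction force comes from whole-body CoM dynamics
# (m a_com = F_grf + m g), shared between the feet by a logistic weight on
# foot clearance, so the impulse-momentum closure (mean vertical GRF = body
# weight over whole strides) holds by construction.

#' Body segment parameters
#'
#' Planar trunk (head-arms-trunk lumped), thigh, shank, foot segment masses,
#' lengths, CoM offsets and moments of inertia from standard anthropometric
#' tables (fractions of total mass / stature).
#'
#' @param total_mass Body mass, kg.
#' @param height Stature, m.
#' @return An object of class `anthropometry`.
#' @export
anthropometry <- function(total_mass = 75, height = 1.75) {
  stopifnot(total_mass > 0, height > 0)
  m_thigh <- 0.100 * total_mass
  m_shank <- 0.0465 * total_mass
  m_foot  <- 0.0145 * total_mass
  m_trunk <- total_mass - 2 * (m_thigh + m_shank + m_foot)  # HAT, 0.678 M
  L_thigh <- 0.245 * height
  L_shank <- 0.246 * height
  L_foot  <- 0.152 * height
  structure(list(
    total_mass = total_mass, height = height,
    m_trunk = m_trunk, m_thigh = m_thigh, m_shank = m_shank, m_foot = m_foot,
    L_thigh = L_thigh, L_shank = L_shank, L_foot = L_foot,
    r_thigh = 0.433 * L_thigh,   # CoM distance from hip
    r_shank = 0.433 * L_shank,   # CoM distance from knee
    trunk_com_up = 0.30,         # HAT CoM height above hip joint
    I_thigh = m_thigh * (0.323 * L_thigh)^2,
    I_shank = m_shank * (0.302 * L_shank)^2,
    I_foot  = m_foot  * (0.475 * L_foot)^2,
    heel_len = 0.25 * L_foot,    # ankle -> heel (backward along foot)
    toe_len  = 0.60 * L_foot,    # ankle -> toe (forward along foot)
    sole_height = 0.04           # ankle joint height above sole at flat foot
  ), class = "anthropometry")
}

#' Gait scenario configuration
#'
#' @param slope_deg Ground slope in degrees; 0 = level, -5 = the downhill
#'   scenario (ground tilted 5 degrees, walking downhill). Gravity stays
#'   vertical; the model works in the ground frame (x along the surface,
#'   y surface-normal), so gravity acquires an along-slope component.
#' @param target_speed Prescribed walking speed, m/s.
#' @param duration Simulated time, s (default 10; must cover >= 3 strides).
#' @param dt Time step, s.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param speed_tolerance Validity band around `target_speed`, m/s.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(slope_deg = 0, target_speed = 1.2, duration = 10,
                            dt = 0.01, gravity = 9.81, speed_tolerance = 0.15) {
  stopifnot(duration > 0, dt > 0, gravity >= 0, target_speed > 0)
  structure(list(slope_deg = slope_deg, target_speed = target_speed,
                 duration = duration, dt = dt, gravity = gravity,
                 speed_tolerance = speed_tolerance),
            class = "scenario_config")
}

# Gravity vector in the ground frame (x along slope, y ground-normal).
gravity_vec <- function(scenario) {
  b <- scenario$slope_deg * pi / 180
  scenario$gravity * c(-sin(b), -cos(b))
}

#' Controller vector parameterizing the gait
#'
#' The reduced-order analogue of the neuromuscular controller parameters: a
#' truncated Fourier series (fundamental + 2nd harmonic) per joint, a stride
#' period, a stride length, a fore-aft pelvis speed fluctuation, and the
#' stance load threshold used by the phase machine (optimized along with the
#' rest, mirroring the full platform).
#'
#' @param T_stride Stride period, s, `> 0`.
#' @param stride_length Pelvis advance per stride, m.
#' @param hip,knee Length-5 Fourier coefficients `(a0, a1, b1, a2, b2)` for
#'   the hip / knee flexion angle (rad) over cycle fraction `u`:
#'   `a0 + a1 cos(2 pi u) + b1 sin(2 pi u) + a2 cos(4 pi u) + b2 sin(4 pi u)`.
#' @param ankle Length-3 coefficients `(a0, a1, b1)` for foot pitch relative
#'   to the shank (rad).
#' @param pelvis_fluct Length-2 `(amplitude m, phase rad)` of the fore-aft
#'   pelvis position fluctuation at twice the stride frequency.
#' @param stance_load_threshold Body-weight fraction for the phase machine.
#' @return An object of class `controller_theta`.
#' @export
controller_theta <- function(T_stride, stride_length, hip, knee,
                             ankle = c(0, 0, 0), pelvis_fluct = c(0, 0),
                             stance_load_threshold = 0.2) {
  v <- c(T_stride, stride_length, hip, knee, ankle, pelvis_fluct,
         stance_load_threshold)
  if (!all(is.finite(v))) stop("non-finite controller coefficients", call. = FALSE)
  if (T_stride <= 0) stop("stride period must be > 0", call. = FALSE)
  stopifnot(length(hip) == 5, length(knee) == 5, length(ankle) == 3,
            length(pelvis_fluct) == 2)
  structure(list(T_stride = T_stride, stride_length = stride_length,
                 hip = as.numeric(hip), knee = as.numeric(knee),
                 ankle = as.numeric(ankle),
                 pelvis_fluct = as.numeric(pelvis_fluct),
                 stance_load_threshold = stance_load_threshold),
            class = "controller_theta")
}

#' Flatten / rebuild a controller vector
#'
#' Fixed packing order used by the inner optimizer:
#' `T, stride_length, hip(5), knee(5), ankle(3), fluct(2), stance_thr` (18).
#'
#' @param theta A [controller_theta()].
#' @return Numeric vector of length 18.
#' @export
theta_to_vector <- function(theta) {
  c(theta$T_stride, theta$stride_length, theta$hip, theta$knee, theta$ankle,
    theta$pelvis_fluct, theta$stance_load_threshold)
}

#' @rdname theta_to_vector
#' @param x Numeric vector of length 18.
#' @export
vector_to_theta <- function(x) {
  stopifnot(length(x) == 18)
  controller_theta(T_stride = x[1], stride_length = x[2], hip = x[3:7],
                   knee = x[8:12], ankle = x[13:15], pelvis_fluct = x[16:17],
                   stance_load_threshold = x[18])
}

# Fourier synthesis: value and time derivatives at cycle fraction u = t/T + u0
fourier_eval <- function(coef, t, T_stride, u0 = 0, nderiv = 0) {
  w <- 2 * pi / T_stride
  ph1 <- w * t + 2 * pi * u0
  ph2 <- 2 * ph1
  a <- coef
  if (length(a) == 3) a <- c(a, 0, 0)
  if (nderiv == 0) {
    a[1] + a[2] * cos(ph1) + a[3] * sin(ph1) + a[4] * cos(ph2) + a[5] * sin(ph2)
  } else if (nderiv == 1) {
    w * (-a[2] * sin(ph1) + a[3] * cos(ph1)) +
      2 * w * (-a[4] * sin(ph2) + a[5] * cos(ph2))
  } else {
    -w^2 * (a[2] * cos(ph1) + a[3] * sin(ph1)) -
      4 * w^2 * (a[4] * cos(ph2) + a[5] * sin(ph2))
  }
}

# First/second time derivative of a sampled series (central differences,
# second-order one-sided at the ends).
deriv_t <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (-3 * x[1] + 4 * x[2] - x[3]) / (2 * dt)
  d[n] <- (3 * x[n] - 4 * x[n - 1] + x[n - 2]) / (2 * dt)
  d
}

#' Synthesize gait kinematics from a controller vector
#'
#' Analytic Fourier joint trajectories for both legs (left = right shifted by
#' half a stride), pelvis trajectory (forward: linear + fluctuation; vertical:
#' smoothed soft maximum of the legs' downward reach, pinning the stance foot
#' to the ground), and all joint/segment positions.
#'
#' @param theta A [controller_theta()].
#' @param scenario A [scenario_config()].
#' @param anthro An [anthropometry()].
#' @return A list (`gait_kinematics`) of time grid, per-leg angle series and
#'   derivatives, and segment position/acceleration matrices.
#' @export
generate_kinematics <- function(theta, scenario, anthro = anthropometry()) {
  stopifnot(inherits(theta, "controller_theta"),
            inherits(scenario, "scenario_config"))
  t <- seq(0, scenario$duration, by = scenario$dt)
  n <- length(t)
  Ts <- theta$T_stride
  dt <- scenario$dt
  legs <- list(R = 0, L = 0.5)

  kin <- list(t = t, n = n, dt = dt, theta = theta, scenario = scenario,
              anthro = anthro)

  # joint angles and analytic derivatives
  for (leg in names(legs)) {
    u0 <- legs[[leg]]
    hip   <- fourier_eval(theta$hip,   t, Ts, u0)
    knee  <- fourier_eval(theta$knee,  t, Ts, u0)
    ankle <- fourier_eval(theta$ankle, t, Ts, u0)
    kin[[paste0("hip_", leg)]]   <- hip
    kin[[paste0("knee_", leg)]]  <- knee
    kin[[paste0("ankle_", leg)]] <- ankle
    kin[[paste0("hip_omega_", leg)]]   <- fourier_eval(theta$hip, t, Ts, u0, 1)
    kin[[paste0("knee_omega_", leg)]]  <- fourier_eval(theta$knee, t, Ts, u0, 1)
    kin[[paste0("ankle_omega_", leg)]] <- fourier_eval(theta$ankle, t, Ts, u0, 1)
    kin[[paste0("hip_alpha_", leg)]]   <- fourier_eval(theta$hip, t, Ts, u0, 2)
    kin[[paste0("knee_alpha_", leg)]]  <- fourier_eval(theta$knee, t, Ts, u0, 2)
    kin[[paste0("ankle_alpha_", leg)]] <- fourier_eval(theta$ankle, t, Ts, u0, 2)
  }

  # pelvis trajectory: forward linear + fluctuation; vertical pins the most
  # downward-reaching foot (leg extension + heel/toe drop below the ankle)
  # to the ground via a soft maximum, so the stance foot touches the ground
  # for any controller vector
  v <- theta$stride_length / Ts
  fl_a <- theta$pelvis_fluct[1]
  fl_p <- theta$pelvis_fluct[2]
  w2 <- 4 * pi / Ts
  hip_x <- v * t + fl_a * sin(w2 * t + fl_p)
  softmax2 <- function(a, b, s) {
    m0 <- pmax(a, b)
    s * log(exp((a - m0) / s) + exp((b - m0) / s)) + m0
  }
  reach <- sapply(c("R", "L"), function(leg) {
    phi_t <- kin[[paste0("hip_", leg)]]
    phi_s <- phi_t - kin[[paste0("knee_", leg)]]
    delta <- phi_s + kin[[paste0("ankle_", leg)]]
    anthro$L_thigh * cos(phi_t) + anthro$L_shank * cos(phi_s) +
      anthro$sole_height +
      softmax2(anthro$heel_len * sin(delta), -anthro$toe_len * sin(delta),
               0.006)
  })
  s_soft <- 0.012  # soft-max scale, m
  hip_y <- softmax2(reach[, 1], reach[, 2], s_soft)
  # low-pass (Gaussian, sigma 20 ms) to keep pelvis accelerations, and hence
  # ground reaction forces, physiological; contact clearance is recomputed
  # from the smoothed trajectory so kinematic consistency is preserved
  sigma <- 0.05
  half <- max(1L, ceiling(3 * sigma / dt))
  kern <- stats::dnorm(seq(-half, half) * dt, sd = sigma)
  kern <- kern / sum(kern)
  padded <- c(rep(hip_y[1], half), hip_y, rep(hip_y[n], half))
  hip_y <- stats::filter(padded, kern, sides = 2)[(half + 1):(half + n)]
  kin$hip_x <- hip_x
  kin$hip_y <- hip_y

  # joint and segment positions per leg
  for (leg in c("R", "L")) {
    phi_t <- kin[[paste0("hip_", leg)]]
    phi_s <- phi_t - kin[[paste0("knee_", leg)]]
    delta <- phi_s + kin[[paste0("ankle_", leg)]]  # foot pitch vs ground
    knee_x <- hip_x + anthro$L_thigh * sin(phi_t)
    knee_y <- hip_y - anthro$L_thigh * cos(phi_t)
    ank_x <- knee_x + anthro$L_shank * sin(phi_s)
    ank_y <- knee_y - anthro$L_shank * cos(phi_s)
    toe_x <- ank_x + anthro$toe_len * cos(delta)
    toe_y <- ank_y - anthro$sole_height + anthro$toe_len * sin(delta)
    heel_x <- ank_x - anthro$heel_len * cos(delta)
    heel_y <- ank_y - anthro$sole_height - anthro$heel_len * sin(delta)
    kin[[paste0("phi_shank_", leg)]] <- phi_s
    kin[[paste0("foot_pitch_", leg)]] <- delta
    kin[[paste0("knee_x_", leg)]] <- knee_x
    kin[[paste0("knee_y_", leg)]] <- knee_y
    kin[[paste0("ankle_x_", leg)]] <- ank_x
    kin[[paste0("ankle_y_", leg)]] <- ank_y
    kin[[paste0("toe_x_", leg)]] <- toe_x
    kin[[paste0("heel_x_", leg)]] <- heel_x
    # ground clearance of the lower of heel/toe contact points
    kin[[paste0("clearance_", leg)]] <- pmin(heel_y, toe_y)
    # smooth heel->toe blend for the center of pressure
    wt <- stats::plogis((heel_y - toe_y) / 0.01)
    kin[[paste0("cop_x_", leg)]] <- wt * toe_x + (1 - wt) * heel_x
    # segment CoMs
    kin[[paste0("thigh_cx_", leg)]] <- hip_x + anthro$r_thigh * sin(phi_t)
    kin[[paste0("thigh_cy_", leg)]] <- hip_y - anthro$r_thigh * cos(phi_t)
    kin[[paste0("shank_cx_", leg)]] <- knee_x + anthro$r_shank * sin(phi_s)
    kin[[paste0("shank_cy_", leg)]] <- knee_y - anthro$r_shank * cos(phi_s)
    fc <- 0.5 * (anthro$toe_len - anthro$heel_len)
    kin[[paste0("foot_cx_", leg)]] <- ank_x + fc * cos(delta)
    kin[[paste0("foot_cy_", leg)]] <- ank_y - 0.5 * anthro$sole_height +
      fc * sin(delta)
  }

  # whole-body CoM
  M <- anthro$total_mass
  kin$com_x <- (anthro$m_trunk * hip_x +
    anthro$m_thigh * (kin$thigh_cx_R + kin$thigh_cx_L) +
    anthro$m_shank * (kin$shank_cx_R + kin$shank_cx_L) +
    anthro$m_foot * (kin$foot_cx_R + kin$foot_cx_L)) / M
  kin$com_y <- (anthro$m_trunk * (hip_y + anthro$trunk_com_up) +
    anthro$m_thigh * (kin$thigh_cy_R + kin$thigh_cy_L) +
    anthro$m_shank * (kin$shank_cy_R + kin$shank_cy_L) +
    anthro$m_foot * (kin$foot_cy_R + kin$foot_cy_L)) / M

  class(kin) <- "gait_kinematics"
  kin
}

#' Newton-Euler inverse dynamics over the planar linkage
#'
#' Total GRF from whole-body CoM dynamics (`m a_com = F + m g`), shared
#' between the feet by a logistic weight on foot clearance (width 5 mm), then
#' a bottom-up (foot -> shank -> thigh) Newton-Euler recursion per leg giving
#' net joint moments and intersegmental forces. The biological knee moment is
#' the net moment minus the injected exo torque.
#'
#' @param kin A `gait_kinematics` from [generate_kinematics()].
#' @param exo_torque Two-column matrix (`R`, `L`) of knee exo torque, N·m
#'   (flexion-positive), or `NULL` for none.
#' @return A list (`gait_dynamics`) of GRF, normalized leg loads, net and
#'   biological joint moments, intersegmental knee force and joint powers.
#' @export
inverse_dynamics <- function(kin, exo_torque = NULL) {
  stopifnot(inherits(kin, "gait_kinematics"))
  an <- kin$anthro
  sc <- kin$scenario
  n <- kin$n
  dt <- kin$dt
  g <- gravity_vec(sc)
  M <- an$total_mass
  bw <- M * sc$gravity
  if (is.null(exo_torque)) exo_torque <- matrix(0, n, 2,
                                                dimnames = list(NULL, c("R", "L")))

  acc2 <- function(x) deriv_t(deriv_t(x, dt), dt)

  # total GRF from CoM dynamics
  a_com_x <- acc2(kin$com_x)
  a_com_y <- acc2(kin$com_y)
  F_tot_x <- M * (a_com_x - g[1])
  F_tot_y <- M * (a_com_y - g[2])

  # logistic contact weights on clearance (width 5 mm)
  width <- 0.005
  cR <- stats::plogis(-(kin$clearance_R - 0.005) / width)
  cL <- stats::plogis(-(kin$clearance_L - 0.005) / width)
  shareR <- cR / (cR + cL + 1e-12)
  shareL <- 1 - shareR

  dyn <- list(t = kin$t, n = n, body_weight = bw,
              F_tot_x = F_tot_x, F_tot_y = F_tot_y)

  for (leg in c("R", "L")) {
    sh <- if (leg == "R") shareR else shareL
    grf_x <- sh * F_tot_x
    grf_y <- sh * F_tot_y
    load <- sqrt(grf_x^2 + grf_y^2) / bw

    # foot segment
    a_fx <- acc2(kin[[paste0("foot_cx_", leg)]])
    a_fy <- acc2(kin[[paste0("foot_cy_", leg)]])
    alpha_f <- kin[[paste0("hip_alpha_", leg)]] -
      kin[[paste0("knee_alpha_", leg)]] + kin[[paste0("ankle_alpha_", leg)]]
    F_ank_x <- an$m_foot * a_fx - grf_x - an$m_foot * g[1]
    F_ank_y <- an$m_foot * a_fy - grf_y - an$m_foot * g[2]
    r_cop_x <- kin[[paste0("cop_x_", leg)]] - kin[[paste0("foot_cx_", leg)]]
    r_cop_y <- -kin[[paste0("foot_cy_", leg)]]  # CoP on the ground plane
    r_ank_x <- kin[[paste0("ankle_x_", leg)]] - kin[[paste0("foot_cx_", leg)]]
    r_ank_y <- kin[[paste0("ankle_y_", leg)]] - kin[[paste0("foot_cy_", leg)]]
    M_ank <- an$I_foot * alpha_f -
      (r_cop_x * grf_y - r_cop_y * grf_x) -
      (r_ank_x * F_ank_y - r_ank_y * F_ank_x)

    # shank segment
    a_sx <- acc2(kin[[paste0("shank_cx_", leg)]])
    a_sy <- acc2(kin[[paste0("shank_cy_", leg)]])
    alpha_s <- kin[[paste0("hip_alpha_", leg)]] - kin[[paste0("knee_alpha_", leg)]]
    F_knee_x <- an$m_shank * a_sx + F_ank_x - an$m_shank * g[1]
    F_knee_y <- an$m_shank * a_sy + F_ank_y - an$m_shank * g[2]
    r_a_x <- kin[[paste0("ankle_x_", leg)]] - kin[[paste0("shank_cx_", leg)]]
    r_a_y <- kin[[paste0("ankle_y_", leg)]] - kin[[paste0("shank_cy_", leg)]]
    r_k_x <- kin[[paste0("knee_x_", leg)]] - kin[[paste0("shank_cx_", leg)]]
    r_k_y <- kin[[paste0("knee_y_", leg)]] - kin[[paste0("shank_cy_", leg)]]
    M_knee_z <- an$I_shank * alpha_s + M_ank -
      (r_a_x * (-F_ank_y) - r_a_y * (-F_ank_x)) -
      (r_k_x * F_knee_y - r_k_y * F_knee_x)

    # thigh segment
    a_tx <- acc2(kin[[paste0("thigh_cx_", leg)]])
    a_ty <- acc2(kin[[paste0("thigh_cy_", leg)]])
    alpha_t <- kin[[paste0("hip_alpha_", leg)]]
    F_hip_x <- an$m_thigh * a_tx + F_knee_x - an$m_thigh * g[1]
    F_hip_y <- an$m_thigh * a_ty + F_knee_y - an$m_thigh * g[2]
    r_kk_x <- kin[[paste0("knee_x_", leg)]] - kin[[paste0("thigh_cx_", leg)]]
    r_kk_y <- kin[[paste0("knee_y_", leg)]] - kin[[paste0("thigh_cy_", leg)]]
    r_h_x <- kin$hip_x - kin[[paste0("thigh_cx_", leg)]]
    r_h_y <- kin$hip_y - kin[[paste0("thigh_cy_", leg)]]
    M_hip_z <- an$I_thigh * alpha_t + M_knee_z -
      (r_kk_x * (-F_knee_y) - r_kk_y * (-F_knee_x)) -
      (r_h_x * F_hip_y - r_h_y * F_hip_x)

    # joint-coordinate (flexion-positive) moments:
    # knee flexion theta_k enters phi_shank with a minus sign
    knee_net <- -M_knee_z
    hip_mom <- M_hip_z
    ankle_mom <- M_ank
    exo <- exo_torque[, leg]
    knee_bio <- knee_net - exo
    w_h <- kin[[paste0("hip_omega_", leg)]]
    w_k <- kin[[paste0("knee_omega_", leg)]]
    w_a <- kin[[paste0("ankle_omega_", leg)]]

    dyn[[paste0("grf_x_", leg)]] <- grf_x
    dyn[[paste0("grf_y_", leg)]] <- grf_y
    dyn[[paste0("leg_load_", leg)]] <- load
    dyn[[paste0("hip_moment_", leg)]] <- hip_mom
    dyn[[paste0("knee_moment_", leg)]] <- knee_net
    dyn[[paste0("knee_moment_bio_", leg)]] <- knee_bio
    dyn[[paste0("ankle_moment_", leg)]] <- ankle_mom
    dyn[[paste0("knee_force_", leg)]] <- sqrt(F_knee_x^2 + F_knee_y^2)
    dyn[[paste0("hip_power_", leg)]] <- hip_mom * w_h
    dyn[[paste0("knee_power_net_", leg)]] <- knee_net * w_k
    dyn[[paste0("knee_power_bio_", leg)]] <- knee_bio * w_k
    dyn[[paste0("exo_power_", leg)]] <- exo * w_k
    dyn[[paste0("ankle_power_", leg)]] <- ankle_mom * w_a
  }
  class(dyn) <- "gait_dynamics"
  dyn
}

#' Biological knee load proxy
#'
#' `(|intersegmental knee force| + |biological knee moment| / r_eff) / (m g)`:
#' the intersegmental force plus a muscle-compression term proportional to the
#' biological moment the muscles must supply, normalized to body weight. The
#' moment term is what makes the metric sensitive to the damper's offloading.
#'
#' @param knee_force Intersegmental knee force magnitude, N (vectorized).
#' @param knee_moment_bio Biological knee moment, N·m.
#' @param body_weight Body weight `m g`, N.
#' @param r_eff Effective extensor moment arm, m (`> 0`).
#' @return Knee load in body-weight fractions.
#' @export
knee_load <- function(knee_force, knee_moment_bio, body_weight, r_eff = 0.04) {
  if (r_eff <= 0) stop("`r_eff` must be > 0", call. = FALSE)
  (abs(knee_force) + abs(knee_moment_bio) / r_eff) / body_weight
}

#' Metabolic power proxy from joint powers
#'
#' `basal + sum_joints [alpha_pos max(P, 0) + alpha_neg max(-P, 0)]`: positive
#' and negative mechanical joint work weighted by the reciprocal efficiencies
#' of concentric / eccentric muscle work, on top of a basal rate.
#'
#' @param powers Matrix (samples x joints) of biological joint powers, W.
#' @param alpha_pos Cost per unit positive mechanical power (`> 0`).
#' @param alpha_neg Cost per unit negative mechanical power (`>= 0`).
#' @param basal Basal metabolic rate, W.
#' @return Metabolic power series, W; never below `basal`.
#' @export
metabolic_power <- function(powers, alpha_pos = 4.0, alpha_neg = 0.8,
                            basal = 0) {
  if (alpha_pos <= 0 || alpha_neg < 0) {
    stop("need alpha_pos > 0 and alpha_neg >= 0", call. = FALSE)
  }
  powers <- as.matrix(powers)
  basal + rowSums(alpha_pos * pmax(powers, 0) + alpha_neg * pmax(-powers, 0))
}

#' Simulate one gait trial, with or without the device
#'
#' Pipeline: kinematics -> GRF + leg loads -> phase labeling (using the
#' controller's stance load threshold) -> clutch engagement per design ->
#' damper torque -> inverse dynamics -> knee load, metabolic series, speed,
#' distance, validity.
#'
#' @param theta A [controller_theta()].
#' @param scenario A [scenario_config()].
#' @param design A [design_params()] or `NULL` for the no-device baseline.
#' @param anthro An [anthropometry()].
#' @param thresholds A [phase_thresholds()]; its stance load threshold is
#'   overridden by `theta$stance_load_threshold`.
#' @param r_eff Effective knee extensor moment arm, m.
#' @param basal_per_kg Basal metabolic rate, W/kg.
#' @return An object of class `sim_result`: `$series` (one row per time step),
#'   `$metrics` (scalars), `$valid`, `$invalid_reasons`, `$strides`.
#' @export
simulate_gait <- function(theta, scenario, design = NULL,
                          anthro = anthropometry(),
                          thresholds = phase_thresholds(),
                          r_eff = 0.04, basal_per_kg = 1.2) {
  thr <- thresholds
  thr$stance_load_threshold <- theta$stance_load_threshold
  kin <- generate_kinematics(theta, scenario, anthro)
  n <- kin$n

  # pass 1: GRF and net moments without device (GRF does not depend on the
  # exo torque, which only re-splits the knee moment)
  dyn <- inverse_dynamics(kin, exo_torque = NULL)

  # phase labeling per leg
  sag_R <- kin$foot_cx_R - kin$com_x
  sag_L <- kin$foot_cx_L - kin$com_x
  ph_R <- label_phases_fast(sag_R, dyn$leg_load_R, dyn$leg_load_L, thr)
  ph_L <- label_phases_fast(sag_L, dyn$leg_load_L, dyn$leg_load_R, thr)

  # clutch engagement and damper torque
  c_damp <- if (is.null(design)) 0 else design$damping_coefficient
  pattern <- if (is.null(design)) character(0) else design$clutch_pattern
  eng_R <- ph_R %in% pattern
  eng_L <- ph_L %in% pattern
  exo <- cbind(R = damper_torque(c_damp, kin$knee_omega_R, eng_R),
               L = damper_torque(c_damp, kin$knee_omega_L, eng_L))
  dyn$knee_moment_bio_R <- dyn$knee_moment_R - exo[, "R"]
  dyn$knee_moment_bio_L <- dyn$knee_moment_L - exo[, "L"]
  dyn$knee_power_bio_R <- dyn$knee_moment_bio_R * kin$knee_omega_R
  dyn$knee_power_bio_L <- dyn$knee_moment_bio_L * kin$knee_omega_L
  dyn$exo_power_R <- exo[, "R"] * kin$knee_omega_R
  dyn$exo_power_L <- exo[, "L"] * kin$knee_omega_L

  bw <- dyn$body_weight
  kl_R <- knee_load(dyn$knee_force_R, dyn$knee_moment_bio_R, bw, r_eff)
  kl_L <- knee_load(dyn$knee_force_L, dyn$knee_moment_bio_L, bw, r_eff)

  powers <- cbind(dyn$hip_power_R, dyn$knee_power_bio_R, dyn$ankle_power_R,
                  dyn$hip_power_L, dyn$knee_power_bio_L, dyn$ankle_power_L)
  met <- metabolic_power(powers, basal = basal_per_kg * anthro$total_mass)
  dt <- scenario$dt
  energy <- sum((met[-1] + met[-n]) / 2) * dt  # trapezoid, J
  distance <- kin$hip_x[n] - kin$hip_x[1]
  mean_speed <- distance / (kin$t[n] - kin$t[1])

  # validity
  reasons <- character(0)
  if (abs(mean_speed - scenario$target_speed) > scenario$speed_tolerance) {
    reasons <- c(reasons, "speed_deviation")
  }
  if (min(dyn$grf_y_R, dyn$grf_y_L) < -1e-6 * bw) {
    reasons <- c(reasons, "negative_vertical_grf")
  }
  rng_k <- range(kin$knee_R, kin$knee_L)
  if (rng_k[1] < 0 || rng_k[2] > 2.5) reasons <- c(reasons, "knee_limit")
  loaded_R <- dyn$leg_load_R > 0.3
  loaded_L <- dyn$leg_load_L > 0.3
  if (any(kin$clearance_R[loaded_R] > 0.05) ||
      any(kin$clearance_L[loaded_L] > 0.05)) {
    reasons <- c(reasons, "loaded_foot_airborne")
  }
  strides <- tryCatch(detect_strides(ph_R), error = function(e) NULL)
  if (is.null(strides)) reasons <- c(reasons, "no_complete_stride")
  strides_L <- tryCatch(detect_strides(ph_L), error = function(e) NULL)

  series <- data.frame(
    t = kin$t,
    hip_R = kin$hip_R, knee_R = kin$knee_R, ankle_R = kin$ankle_R,
    hip_L = kin$hip_L, knee_L = kin$knee_L, ankle_L = kin$ankle_L,
    knee_omega_R = kin$knee_omega_R, knee_omega_L = kin$knee_omega_L,
    knee_moment_R = dyn$knee_moment_R, knee_moment_L = dyn$knee_moment_L,
    knee_moment_bio_R = dyn$knee_moment_bio_R,
    knee_moment_bio_L = dyn$knee_moment_bio_L,
    exo_torque_R = exo[, "R"], exo_torque_L = exo[, "L"],
    knee_power_net_R = dyn$knee_power_net_R,
    knee_power_net_L = dyn$knee_power_net_L,
    knee_power_bio_R = dyn$knee_power_bio_R,
    knee_power_bio_L = dyn$knee_power_bio_L,
    exo_power_R = dyn$exo_power_R, exo_power_L = dyn$exo_power_L,
    hip_power_R = dyn$hip_power_R, hip_power_L = dyn$hip_power_L,
    ankle_power_R = dyn$ankle_power_R, ankle_power_L = dyn$ankle_power_L,
    grf_x_R = dyn$grf_x_R, grf_y_R = dyn$grf_y_R,
    grf_x_L = dyn$grf_x_L, grf_y_L = dyn$grf_y_L,
    leg_load_R = dyn$leg_load_R, leg_load_L = dyn$leg_load_L,
    knee_load_R = kl_R, knee_load_L = kl_L,
    sagittal_pos_R = sag_R, sagittal_pos_L = sag_L,
    metabolic_power = met,
    phase_R = ph_R, phase_L = ph_L,
    engaged_R = eng_R, engaged_L = eng_L,
    stringsAsFactors = FALSE
  )

  structure(list(
    series = series,
    metrics = list(mean_speed = mean_speed, distance = distance,
                   metabolic_energy = energy, duration = scenario$duration,
                   body_weight = bw, total_mass = anthro$total_mass),
    valid = length(reasons) == 0L,
    invalid_reasons = reasons,
    strides = strides, strides_L = strides_L,
    design = design, theta = theta, scenario = scenario, anthro = anthro
  ), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.1f s, speed %.3f m/s, %s%s\n",
              x$metrics$duration, x$metrics$mean_speed,
              if (x$valid) "valid" else "INVALID",
              if (x$valid) "" else paste0(" (",
                paste(x$invalid_reasons, collapse = ", "), ")")))
  invisible(x)
}

#' Serialize a simulation result
#'
#' Time series to CSV (one row per step) plus a JSON sidecar of scalar
#' metrics and validity reasons.
#'
#' @param sim A `sim_result`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_sim_result <- function(sim, path) {
  utils::write.csv(sim$series, path, row.names = FALSE)
  meta <- c(sim$metrics, list(valid = sim$valid,
                              invalid_reasons = sim$invalid_reasons))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
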