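# Recursive Newton-Euler inverse dynamics over the foot-shank-thigh-
# pelvis chain, plus moment normalization and peak extraction.
#
# The pelvis+HAT segment (which aggregates trunk, head, arms and the
# contralateral limb) and the barbell enter with `weight_share` of their
# mass, routing half of the supported load to the modeled force-plate
# leg; the leg's own segments enter in full.

# Per-frame chain kinematics for an angle time series (frames x 8, deg).
# Returns rotations, joint centers, segment COMs and the barbell point.
chain_kinematics <- function(model, angles) {
  n <- nrow(angles)
  segs <- c("foot", "calcaneus", "shank", "thigh", "pelvis")
  R <- lapply(segs, function(s) array(0, c(3, 3, n)))
  names(R) <- segs
  joints <- list(ankle = matrix(0, n, 3), knee = matrix(0, n, 3),
                 hip = matrix(0, n, 3))
  com <- lapply(segs, function(s) matrix(0, n, 3))
  names(com) <- segs
  barbell <- matrix(0, n, 3)
  for (f in seq_len(n)) {
    fk <- fk_pose(model, angles[f, ])
    for (s in segs) R[[s]][, , f] <- fk$R[[s]]
    joints$ankle[f, ] <- fk$joints$ankle
    joints$knee[f, ] <- fk$joints$knee
    joints$hip[f, ] <- fk$joints$hip
    for (s in rownames(fk$com)) com[[s]][f, ] <- fk$com[s, ]
    barbell[f, ] <- fk$barbell
  }
  list(n = n, R = R, joints = joints, com = com, barbell = barbell)
}

# Numerical time derivatives of an n x 3 trajectory.
.traj_deriv <- function(x, dt) apply(x, 2, finite_diff, dt = dt)

# Angular velocity (global frame) of a rotation-matrix trajectory:
# omega from the skew part of Rdot R^T; alpha by differentiating omega.
.angular_kinematics <- function(Rarr, dt) {
  n <- dim(Rarr)[3]
  Rd <- array(0, dim(Rarr))
  for (i in 1:3) for (j in 1:3) {
    Rd[i, j, ] <- finite_diff(Rarr[i, j, ], dt)
  }
  omega <- matrix(0, n, 3)
  for (f in seq_len(n)) {
    W <- Rd[, , f] %*% t(Rarr[, , f])
    omega[f, ] <- c(W[3, 2], W[1, 3], W[2, 1])
  }
  alpha <- apply(omega, 2, finite_diff, dt = dt)
  list(omega = omega, alpha = alpha)
}

#' Newton-Euler balance of a single rigid segment
#'
#' Given the segment's inertial state and the distal load, returns the
#' force and moment the superior body must apply at the proximal joint.
#' Exposed so single-segment closed-form cases can be checked directly.
#'
#' @param mass Segment mass (kg).
#' @param inertia_global 3x3 inertia tensor about the COM, global frame.
#' @param a_com COM acceleration (global, m/s^2).
#' @param omega,alpha Angular velocity/acceleration (global, rad/s(^2)).
#' @param com COM position (global, m).
#' @param p_prox Proximal joint position (m).
#' @param loads List of distal loads, each `list(F=, M=, p=)`: force (N),
#'   couple (N m) and point of application (m) of a load applied to the
#'   segment.
#' @param g Gravitational acceleration magnitude (m/s^2).
#' @return List `F_prox`, `M_prox` (applied on the segment at `p_prox`).
#' @export
newton_euler_segment <- function(mass, inertia_global, a_com, omega, alpha,
                                 com, p_prox, loads = list(), g = 9.81) {
  gvec <- c(0, -g, 0)
  Fsum <- c(0, 0, 0)
  Msum <- c(0, 0, 0)
  for (ld in loads) {
    Fsum <- Fsum + ld$F
    Msum <- Msum + (ld$M %||% c(0, 0, 0)) + cross3(ld$p - com, ld$F)
  }
  F_prox <- mass * a_com - mass * gvec - Fsum
  M_prox <- as.numeric(inertia_global %*% alpha) +
    cross3(omega, as.numeric(inertia_global %*% omega)) -
    Msum - cross3(p_prox - com, F_prox)
  list(F_prox = F_prox, M_prox = M_prox)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Inverse dynamics: net joint moments from motion and ground reaction
#'
#' Bottom-up recursion foot -> shank -> thigh -> pelvis.  Segment
#' kinematics are differentiated numerically (central differences) after
#' zero-lag low-pass filtering of the joint angles; the ground reaction
#' force acts on the foot at the center of pressure.  Joint moments are
#' the moments applied by the superior segment on the inferior one,
#' projected on the joint axes and signed per [sign_convention()].
#'
#' @param model A scaled `squat_model`.
#' @param angles Frames x 8 matrix of joint angles (degrees) with
#'   attribute `rate_hz` (or pass `rate_hz`).
#' @param grf Data frame with columns `fx, fy, fz, copx, copy, copz`
#'   sampled at the same rate and length as `angles`.
#' @param barbell_kg Barbell mass (kg).
#' @param filter_cutoff_hz Angle filter cutoff; `NA` disables filtering.
#' @param rate_hz Sampling rate; defaults to `attr(angles, "rate_hz")`.
#' @return A `squat_id` list: `moments` (frames x 8, N m, convention
#'   signs), `joint_forces` (force applied by the superior segment at
#'   ankle/knee/hip, global N), `shank_axis` (tibia long axis per frame),
#'   `rate_hz`.
#' @export
inverse_dynamics <- function(model, angles, grf, barbell_kg = 0,
                             filter_cutoff_hz = 6, rate_hz = NULL) {
  rate <- rate_hz %||% attr(angles, "rate_hz")
  if (is.null(rate)) {
    stop_squatmech("angles must carry a rate_hz attribute", "rate_mismatch")
  }
  if (nrow(grf) != nrow(angles)) {
    stop_squatmech("angles and GRF streams have mismatched lengths/rates",
                   "rate_mismatch")
  }
  if (!is.na(filter_cutoff_hz) && nrow(angles) > 12) {
    angles <- apply(angles, 2, lowpass_filtfilt,
                    cutoff_hz = filter_cutoff_hz, rate_hz = rate)
  }
  dt <- 1 / rate
  ck <- chain_kinematics(model, angles)
  n <- ck$n
  g <- model$gravity
  share <- model$weight_share
  segs <- model$segments
  masses <- c(foot = segs$foot$mass, shank = segs$shank$mass,
              thigh = segs$thigh$mass, pelvis = share * segs$pelvis$mass)
  m_bar <- share * barbell_kg

  acc <- lapply(ck$com, function(x) {
    .traj_deriv(.traj_deriv(x, dt), dt)
  })
  a_bar <- .traj_deriv(.traj_deriv(ck$barbell, dt), dt)
  ang <- lapply(ck$R, .angular_kinematics, dt = dt)

  moments <- matrix(0, n, length(model$dofs),
                    dimnames = list(NULL, model$dofs))
  jf <- list(ankle = matrix(0, n, 3), knee = matrix(0, n, 3),
             hip = matrix(0, n, 3))
  shank_axis <- matrix(0, n, 3)
  gvec <- c(0, -g, 0)

  for (f in seq_len(n)) {
    Rl <- lapply(ck$R, function(a) a[, , f])
    Ig <- lapply(names(segs), function(s) {
      Rl[[s]] %*% diag(segs[[s]]$inertia) %*% t(Rl[[s]])
    })
    names(Ig) <- names(segs)
    Ig$pelvis <- share * Ig$pelvis

    grf_F <- c(grf$fx[f], grf$fy[f], grf$fz[f])
    cop <- c(grf$copx[f], grf$copy[f], grf$copz[f])

    foot <- newton_euler_segment(masses["foot"], Ig$foot,
                                 acc$foot[f, ], ang$foot$omega[f, ],
                                 ang$foot$alpha[f, ], ck$com$foot[f, ],
                                 ck$joints$ankle[f, ],
                                 list(list(F = grf_F, p = cop)), g)
    shank <- newton_euler_segment(masses["shank"], Ig$shank,
                                  acc$shank[f, ], ang$shank$omega[f, ],
                                  ang$shank$alpha[f, ], ck$com$shank[f, ],
                                  ck$joints$knee[f, ],
                                  list(list(F = -foot$F_prox,
                                            M = -foot$M_prox,
                                            p = ck$joints$ankle[f, ])), g)
    thigh <- newton_euler_segment(masses["thigh"], Ig$thigh,
                                  acc$thigh[f, ], ang$thigh$omega[f, ],
                                  ang$thigh$alpha[f, ], ck$com$thigh[f, ],
                                  ck$joints$hip[f, ],
                                  list(list(F = -shank$F_prox,
                                            M = -shank$M_prox,
                                            p = ck$joints$knee[f, ])), g)

    jf$ankle[f, ] <- foot$F_prox
    jf$knee[f, ] <- shank$F_prox
    jf$hip[f, ] <- thigh$F_prox
    shank_axis[f, ] <- Rl$shank[, 2]

    # project joint moments on each rotation's own axis (generalized
    # force of the Euler sequence), then apply mechanical signs
    m5 <- deg2rad(angles[f, "knee_rotation"] *
                    model$dof_mech_sign[["knee_rotation"]])
    m8 <- deg2rad(angles[f, "hip_rotation"] *
                    model$dof_mech_sign[["hip_rotation"]])
    ax <- list(
      subtalar_supination = c(1, 0, 0),
      ankle_dorsiflexion = c(0, 0, 1),
      knee_rotation = as.numeric(Rl$shank %*% c(0, 1, 0)),
      knee_adduction = as.numeric(Rl$shank %*% rot_y(m5) %*% c(1, 0, 0)),
      knee_flexion = as.numeric(Rl$thigh %*% c(0, 0, 1)),
      hip_rotation = as.numeric(Rl$thigh %*% c(0, 1, 0)),
      hip_adduction = as.numeric(Rl$thigh %*% rot_y(m8) %*% c(1, 0, 0)),
      hip_flexion = as.numeric(Rl$pelvis %*% c(0, 0, 1))
    )
    Mvec <- list(
      subtalar_supination = foot$M_prox, ankle_dorsiflexion = foot$M_prox,
      knee_flexion = shank$M_prox, knee_adduction = shank$M_prox,
      knee_rotation = shank$M_prox,
      hip_flexion = thigh$M_prox, hip_adduction = thigh$M_prox,
      hip_rotation = thigh$M_prox
    )
    # the generalized force conjugate to each joint angle: +dq rotates
    # the anatomically distal segment by -axis*mech_sign in this
    # foot-rooted chain, so the internal moment on the distal segment
    # projects with a minus sign (extensors come out extension-negative)
    for (d in model$dofs) {
      moments[f, d] <- -sum(Mvec[[d]] * ax[[d]]) * model$dof_mech_sign[[d]]
    }
  }
  structure(list(moments = moments, joint_forces = jf,
                 shank_axis = shank_axis, rate_hz = rate,
                 angles_filtered = angles),
            class = "squat_id")
}

#' Normalize a load-dependent quantity by system mass
#'
#' Joint moments and contact forces are expressed per kilogram of
#' (body mass + barbell mass).
#'
#' @param value Raw value(s), N m or N.
#' @param body_mass_kg Body mass (> 0).
#' @param barbell_kg Barbell mass (>= 0).
#' @return `value / (body_mass_kg + barbell_kg)`.
#' @export
normalize_load <- function(value, body_mass_kg, barbell_kg = 0) {
  total <- body_mass_kg + barbell_kg
  if (!is.finite(total) || total <= 0) {
    stop_squatmech("total mass must be positive", "invalid_mass")
  }
  value / total
}

# Peak-moment row definitions (Table-3-style): `mode` is "min" for rows
# reported as signed internal extensor/abductor-direction extrema, and
# "magneg" for rows reported as positive external-direction magnitudes
# (the external knee adduction moment, plantarflexion, valgus), i.e.
# max(-internal curve).
.moment_metric_defs <- function() {
  data.frame(
    metric = c("hip_flexion_moment_peak", "hip_adduction_moment_peak",
               "hip_rotation_moment_peak", "knee_flexion_moment_peak",
               "knee_rotation_moment_peak", "knee_adduction_moment_peak",
               "ankle_extension_moment_peak", "foot_valgus_moment_peak"),
    dof = c("hip_flexion", "hip_adduction", "hip_rotation", "knee_flexion",
            "knee_rotation", "knee_adduction", "ankle_dorsiflexion",
            "subtalar_supination"),
    mode = c("min", "min", "min", "min", "min", "magneg", "magneg", "magneg"),
    stringsAsFactors = FALSE
  )
}

#' Peak joint moments over the cycle
#'
#' Signed extrema per DOF matching the peak-moment table semantics:
#' extensor-direction rows are the most-negative values, the knee
#' adduction row is the most-positive value, and plantarflexion/valgus
#' rows are magnitudes in the negative-convention direction.
#'
#' @param curves A `cycle_curves` matrix of joint moments (N m/kg or
#'   N m) with DOF column names.
#' @return Named numeric vector of peak moments.
#' @export
peak_moments <- function(curves) {
  defs <- .moment_metric_defs()
  out <- stats::setNames(numeric(nrow(defs)), defs$metric)
  for (i in seq_len(nrow(defs))) {
    v <- curves[, defs$dof[i]]
    out[i] <- switch(defs$mode[i],
                     min = min(v), max = max(v), magneg = max(-v))
  }
  out
}
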