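test_that("single-segment Newton-Euler matches the hand pendulum oracle", {
  # rigid segment pinned at the knee, held static horizontal:
  # mass 4 kg, COM 0.2 m from the joint -> |M| = 4 * 9.81 * 0.2 = 7.848
  ne <- newton_euler_segment(mass = 4, inertia_global = diag(0, 3),
                             a_com = c(0, 0, 0), omega = c(0, 0, 0),
                             alpha = c(0, 0, 0), com = c(0.2, 0, 0),
                             p_prox = c(0, 0, 0))
  expect_lt(abs(sqrt(sum(ne$M_prox^2)) - 7.848) / 7.848, 1e-12)
  expect_equal(ne$F_prox, c(0, 4 * 9.81, 0))
})

test_that("static upright stance with a balanced GRF gives near-zero moments", {
  p <- default_participant()
  m <- build_true_model(p)
  n <- 60
  angles <- matrix(0, n, 8, dimnames = list(NULL, m$dofs))
  attr(angles, "rate_hz") <- 100
  fk <- fk_pose(m, angles[1, ])
  segs <- m$segments
  ms <- c(foot = segs$foot$mass, shank = segs$shank$mass,
          thigh = segs$thigh$mass,
          pelvis = m$weight_share * segs$pelvis$mass)
  w <- sum(ms) * m$gravity
  # COP at the supported mass-weighted COM: the GRF line of action then
  # passes so that every joint is in pure force balance
  copx <- sum(ms * fk$com[, 1]) / sum(ms)
  grf <- data.frame(time = seq_len(n) / 100, fx = 0, fy = w, fz = 0,
                    copx = copx, copy = 0, copz = 0)
  id <- inverse_dynamics(m, angles, grf, filter_cutoff_hz = NA)
  expect_lt(max(abs(id$moments)), 0.5)
})

test_that("quasi-static inverse dynamics matches an independent lever-arm oracle", {
  p <- default_participant()
  m <- build_true_model(p)
  n <- 40
  pose <- stats::setNames(c(0, 25, 80, 0, 0, 60, 0, 0), m$dofs)
  angles <- matrix(rep(pose, each = n), n, 8, dimnames = list(NULL, m$dofs))
  attr(angles, "rate_hz") <- 100
  grf <- data.frame(time = seq_len(n) / 100, fx = 0, fy = 500, fz = 0,
                    copx = 0.05, copy = 0, copz = 0)
  id <- inverse_dynamics(m, angles, grf, filter_cutoff_hz = NA)

  # independent oracle: moment about the knee of GRF + gravity of the
  # distal segments (foot + shank), projected on the femoral flexion
  # axis, reported as the conjugate generalized force
  fk <- fk_pose(m, pose)
  g <- c(0, -m$gravity, 0)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  M_ext <- cross3(c(0.05, 0, 0) - fk$joints$knee, c(0, 500, 0)) +
    cross3(fk$com["foot", ] - fk$joints$knee, m$segments$foot$mass * g) +
    cross3(fk$com["shank", ] - fk$joints$knee, m$segments$shank$mass * g)
  axis_flex <- as.numeric(squatmech:::joint_rotations(m, pose)$thigh %*%
                            c(0, 0, 1))
  expected <- sum(M_ext * axis_flex) *
    m$dof_mech_sign[["knee_flexion"]]  # internal = -(-external) projection
  expect_lt(abs(id$moments[20, "knee_flexion"] - expected), 1e-6)
})

test_that("inverse dynamics recovers the generating torques on noise-free trials", {
  cs <- zero_noise_case()
  ang <- inverse_kinematics(cs$model, cs$trial)
  id <- inverse_dynamics(cs$model, ang, cs$trial$grf, cs$load$barbell_kg)
  truth <- cs$trial$ground_truth$moments
  rel <- sqrt(mean((id$moments - truth)^2)) / sqrt(mean(truth^2))
  expect_lt(rel, 0.02)
})

test_that("stream length mismatches raise a rate error", {
  cs <- zero_noise_case()
  ang <- cs$trial$ground_truth$angles
  expect_error(inverse_dynamics(cs$model, ang, cs$trial$grf[1:10, ]),
               class = "rate_mismatch")
})

test_that("load normalization divides by body plus barbell mass", {
  expect_equal(normalize_load(102, 65, 20), 1.2)
  expect_equal(normalize_load(130, 65, 0), 2)
  expect_equal(normalize_load(2 * 102, 2 * 65, 2 * 20),
               normalize_load(102, 65, 20))
  expect_error(normalize_load(1, 0, 0), class = "invalid_mass")
})

test_that("peak moments follow the table row semantics", {
  curves <- matrix(0, 101, 8,
                   dimnames = list(NULL,
                                   build_default_model(default_participant())$dofs))
  curves[, "knee_flexion"] <- 0.5
  pk <- peak_moments(curves)
  expect_equal(unname(pk["knee_flexion_moment_peak"]), 0.5)
  curves[, "hip_flexion"] <- 0.3 * sin(seq(0, 2 * pi, length.out = 101))
  curves[, "ankle_dorsiflexion"] <- -0.4 * sin(seq(0, pi, length.out = 101))
  curves[, "knee_adduction"] <- -0.25  # internal; external peak = +0.25
  pk <- peak_moments(curves)
  expect_equal(unname(pk["hip_flexion_moment_peak"]), -0.3, tolerance = 1e-3)
  expect_equal(unname(pk["ankle_extension_moment_peak"]), 0.4)
  expect_equal(unname(pk["knee_adduction_moment_peak"]), 0.25)
})
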