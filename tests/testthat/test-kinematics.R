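test_that("scaling recovers identity and known segment scale factors", {
  spec <- quiet_spec()
  p <- default_participant()
  p$seed <- 1L
  m_true <- build_true_model(p)  # scales all 1
  st <- generate_static_trial(p, m_true, spec, seed = 2)
  sc <- scale_model(build_default_model(p), st)
  expect_lt(max(abs(sc$report$factors - 1)), 1e-6)
  expect_lt(sc$report$marker_rms_m, 1e-6)

  p2 <- participant("P2", 65.67, 1.72, 3, 80,
                    segment_scales = c(foot = 1.1, shank = 1.1,
                                       thigh = 1.1, pelvis = 1.1))
  p2$seed <- 1L
  st2 <- generate_static_trial(p2, build_true_model(p2), spec, seed = 2)
  sc2 <- scale_model(build_default_model(p2), st2)
  expect_lt(max(abs(sc2$report$factors - 1.1)), 0.01)
})

test_that("scaling reports name missing markers and enforce the residual gates", {
  spec <- cohort_spec()
  p <- generate_participant("normal", 5, spec = spec)
  m <- build_true_model(p)
  st <- generate_static_trial(p, m, spec, seed = 2)
  st$markers$RKNE <- NULL
  expect_error(scale_model(build_default_model(p), st), "RKNE",
               class = "missing_marker")

  # a misplaced marker (constant 8 cm offset) violates the max-error gate
  st_bad <- generate_static_trial(p, m, spec, seed = 2)
  st_bad$markers$RTHI <- st_bad$markers$RTHI + 0.08
  expect_error(scale_model(build_default_model(p), st_bad),
               class = "scaling_gate")
  rep_bad <- scale_model(build_default_model(p), st_bad,
                         enforce_gates = FALSE)$report
  expect_false(rep_bad$pass)
})

test_that("inverse kinematics recovers a neutral pose and constructed rotations", {
  p <- default_participant()
  m <- build_true_model(p)
  # neutral upright pose -> all angles ~ 0
  neutral <- fk_pose(m, stats::setNames(numeric(8), m$dofs))$markers
  trial <- list(markers = lapply(rownames(neutral), function(nm) {
    matrix(neutral[nm, ], 3, 3, byrow = TRUE)
  }), marker_rate = 100, markers_filtered = TRUE)
  names(trial$markers) <- rownames(neutral)
  q <- inverse_kinematics(m, structure(trial, class = "squat_trial"))
  expect_lt(max(abs(q)), 1e-4)

  # rigid extra rotation of 10 deg about the knee flexion axis shows up
  # as a 10 deg knee flexion increase
  q0 <- stats::setNames(c(-3, 15, 40, 2, -4, 30, -5, 3), m$dofs)
  q1 <- q0; q1["knee_flexion"] <- q1["knee_flexion"] + 10
  mk <- rbind(fk_pose(m, q0)$markers, fk_pose(m, q1)$markers)
  trial2 <- list(markers = lapply(rownames(neutral), function(nm) {
    rbind(fk_pose(m, q0)$markers[nm, ], fk_pose(m, q1)$markers[nm, ],
          fk_pose(m, q1)$markers[nm, ])
  }), marker_rate = 100, markers_filtered = TRUE)
  names(trial2$markers) <- rownames(neutral)
  q_est <- inverse_kinematics(m, structure(trial2, class = "squat_trial"))
  expect_lt(abs((q_est[2, "knee_flexion"] - q_est[1, "knee_flexion"]) - 10),
            0.1)
})

test_that("the per-frame IK objective is non-increasing across iterations", {
  cs <- zero_noise_case()
  set.seed(1)
  target <- squatmech:::fk_marker_vec(cs$model,
                                      cs$trial$ground_truth$angles[200, ]) +
    rnorm(3 * length(cs$model$markers), 0, 0.005)
  fit <- squatmech:::ik_solve_frame(cs$model, target,
                                    stats::setNames(numeric(8),
                                                    cs$model$dofs))
  expect_true(all(diff(fit$costs) <= 1e-12))
  expect_true(fit$converged)
})

test_that("cycle segmentation finds the deepest point and rejects non-squats", {
  tri <- c(seq(0, 140, length.out = 71), seq(138, 0, length.out = 70))
  seg <- segment_cycle(tri)
  expect_equal(seg$deepest, 71)
  expect_error(segment_cycle(rep(5, 100)), class = "no_squat")
  # ties broken by the earliest frame
  flat_top <- c(seq(0, 100, length.out = 50), rep(100, 5),
                seq(100, 0, length.out = 50))
  expect_equal(segment_cycle(flat_top)$deepest, 50)
})

test_that("time normalization maps descent to 0-50% and preserves extrema", {
  # asymmetric: slow descent, fast ascent -> both phases still get 50 samples
  slow_fast <- c(seq(0, 140, length.out = 120), seq(139, 0, length.out = 40))
  seg <- segment_cycle(slow_fast)
  expect_gt(seg$deepest - seg$start, length(slow_fast) - seg$deepest)
  cyc <- time_normalize(slow_fast, seg)
  expect_equal(nrow(cyc), 101)
  expect_equal(which.max(cyc[, 1]), 51)  # deepest lands exactly at 50%
  expect_equal(cyc[51, 1], 140)          # extremum value preserved exactly

  # identity on a series already sampled on the phase grid
  grid_series <- c(seq(0, 140, length.out = 51), seq(140, 0, length.out = 51)[-1])
  seg2 <- structure(list(start = 1L, deepest = 51L, end = 101L),
                    class = "phase_segmentation")
  expect_equal(as.numeric(time_normalize(grid_series, seg2)), grid_series)

  expect_error(time_normalize(slow_fast,
                              structure(list(start = 0L, deepest = 10L,
                                             end = 200L),
                                        class = "phase_segmentation")),
               class = "invalid_segmentation")
})

test_that("peak angles and ROM follow the table conventions", {
  curves <- matrix(0, 101, 8,
                   dimnames = list(NULL,
                                   build_default_model(default_participant())$dofs))
  curves[, "knee_flexion"] <- seq(10, 100, length.out = 101)
  curves[, "hip_adduction"] <- -25 * sin(seq(0, pi, length.out = 101))
  curves[, "subtalar_supination"] <- -seq(5, 20, length.out = 101)
  pk <- peak_angles(curves)
  expect_equal(unname(pk["knee_flexion_peak"]), 100)
  expect_equal(unname(pk["hip_abduction_peak"]), 25)
  expect_equal(unname(pk["foot_valgus_peak"]), 20)
  rom <- range_of_motion(curves)
  expect_equal(unname(rom["knee_sagittal"]), 90)
  expect_equal(unname(rom["hip_transverse"]), 0)
})
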