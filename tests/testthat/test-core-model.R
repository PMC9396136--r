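test_that("default model conserves participant mass and scales with height", {
  p <- default_participant()
  m <- build_default_model(p)
  expect_lt(abs(model_total_mass(m) - 65.67) / 65.67, 0.01)

  p2 <- participant("P2", 65.67, 2 * 1.72, 3, 80)
  m2 <- build_default_model(p2)
  for (s in names(m$segments)) {
    expect_equal(m2$segments[[s]]$length, 2 * m$segments[[s]]$length)
  }

  expect_error(participant("bad", 0, 1.72, 3, 80),
               class = "invalid_participant")
  expect_error(participant("bad", 65, -1, 3, 80),
               class = "invalid_participant")
  expect_error(participant("bad", 65, 1.72, 35, 80),
               class = "invalid_participant")
  expect_error(participant("bad", 65, 1.72, 3, 0),
               class = "invalid_participant")
})

test_that("load conditions enumerate the three study loads", {
  expect_equal(load_condition(0.7, 100)$barbell_kg, 70)
  expect_equal(load_condition(0, 100)$barbell_kg, 0)
  expect_error(load_condition(0.5, 100), class = "invalid_load")
})

test_that("moment arms evaluate their polynomials and signs", {
  m <- build_default_model(default_participant())
  # constant-arm muscle returns its constant at any pose
  m$muscles$const_test <- list(fmax = 1000,
                               arms = list(knee_flexion = c(0.05)))
  expect_equal(moment_arm(m, "const_test", "knee_flexion",
                          c(knee_flexion = 77)), 0.05)
  # no action on a dof -> 0
  expect_equal(moment_arm(m, "const_test", "hip_flexion"), 0)
  # polynomial arm r(theta) = 0.04 + 0.0001 * theta at 100 deg -> 0.05
  m$muscles$poly_test <- list(fmax = 1000,
                              arms = list(knee_flexion = c(0.04, 1e-4)))
  expect_equal(moment_arm(m, "poly_test", "knee_flexion",
                          c(knee_flexion = 100)), 0.05)
  expect_error(moment_arm(m, "nope", "knee_flexion"), class = "lookup_error")
  expect_error(moment_arm(m, "vasti", "elbow"), class = "lookup_error")
})

test_that("moment arms are consistent with musculotendon length (tendon excursion)", {
  m <- build_default_model(default_participant())
  h <- 1e-4  # degrees
  for (mus in c("rectus_femoris", "gastrocnemius", "gluteus")) {
    for (dof in names(m$muscles[[mus]]$arms)) {
      for (theta in c(-20, 0, 45, 110)) {
        pose_hi <- stats::setNames(theta + h, dof)
        pose_lo <- stats::setNames(theta - h, dof)
        dL <- (muscle_length(m, mus, pose_hi) -
                 muscle_length(m, mus, pose_lo)) / squatmech:::deg2rad(2 * h)
        r <- moment_arm(m, mus, dof, stats::setNames(theta, dof))
        expect_lt(abs(-dL - r), 1e-6)
      }
    }
  }
})

test_that("sign conventions are fixed unit factors that round-trip", {
  sc <- sign_convention()
  expect_equal(sc$dof, build_default_model(default_participant())$dofs)
  m <- build_default_model(default_participant())
  expect_true(all(m$dof_mech_sign %in% c(-1, 1)))
  q <- c(subtalar_supination = -7, ankle_dorsiflexion = 12,
         knee_flexion = 93, knee_adduction = 4, knee_rotation = -9,
         hip_flexion = 55, hip_adduction = -11, hip_rotation = 6)
  expect_equal((q * m$dof_mech_sign) * m$dof_mech_sign, q)
})

test_that("model config serialization round-trips geometry and muscles", {
  p <- participant("P1", 65.67, 1.72, 3, 80,
                   segment_scales = c(foot = 1.05, shank = 0.97,
                                      thigh = 1.02, pelvis = 0.99))
  m <- build_true_model(p)
  path <- tempfile(fileext = ".yml")
  model_to_config(m, path)
  m2 <- model_from_config(path)
  expect_equal(model_total_mass(m2), model_total_mass(m))
  q <- stats::setNames(c(-5, 20, 100, 3, -8, 70, -10, 12), m$dofs)
  # YAML stores floats at limited precision
  expect_equal(fk_pose(m2, q)$markers, fk_pose(m, q)$markers,
               tolerance = 1e-6)
  expect_equal(moment_arm(m2, "vasti", "knee_flexion", q),
               moment_arm(m, "vasti", "knee_flexion", q))
})

test_that("classification by static valgus angle uses a strict 5-degree cutoff", {
  expect_equal(classify_foot_posture(7), "valgus")
  expect_equal(classify_foot_posture(3), "normal")
  expect_equal(classify_foot_posture(5.0), "normal")
  expect_error(classify_foot_posture(-1), class = "invalid_angle")
  expect_error(classify_foot_posture(NaN), class = "invalid_angle")
  # monotone: increasing angle never flips valgus -> normal
  labels <- vapply(seq(0, 30, by = 0.5), classify_foot_posture, character(1))
  expect_false(any(labels == "normal" & c(labels[-1], "valgus") == "valgus" &
                     FALSE))
  first_valgus <- match("valgus", labels)
  expect_true(all(labels[first_valgus:length(labels)] == "valgus"))
})
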