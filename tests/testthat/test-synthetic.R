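test_that("generated participants honor the group angle ranges and seeding", {
  spec <- cohort_spec()
  for (s in 1:15) {
    expect_gt(generate_participant("valgus", s, spec = spec)$valgus_deg, 5)
    expect_lt(generate_participant("normal", s, spec = spec)$valgus_deg, 5)
  }
  a <- generate_participant("valgus", 42, spec = spec)
  b <- generate_participant("valgus", 42, spec = spec)
  expect_identical(a, b)
  expect_error(generate_participant("flatfoot", 1), class = "invalid_group")
})

test_that("zero-noise markers lie exactly on the forward kinematics", {
  cs <- zero_noise_case()
  gt <- cs$trial$ground_truth$angles
  for (f in c(1, 150, 401)) {
    fk <- fk_pose(cs$model, gt[f, ])
    for (nm in rownames(fk$markers)) {
      expect_equal(unname(cs$trial$markers[[nm]][f, ]),
                   unname(fk$markers[nm, ]), tolerance = 1e-10)
    }
  }
})

test_that("vertical GRF matches the routed quasi-static weight share", {
  spec <- quiet_spec()
  p <- generate_participant("normal", 11, spec = spec)
  m <- build_true_model(p)
  trial <- generate_squat_trial(p, load_condition(0, p$onerm_kg), m, spec,
                                seed = 4)
  segs <- m$segments
  share_w <- (m$weight_share * segs$pelvis$mass + segs$foot$mass +
                segs$shank$mass + segs$thigh$mass) * m$gravity
  # quasi-static: mean vertical force within 2% of the routed share
  expect_lt(abs(mean(trial$grf$fy) - share_w) / share_w, 0.02)
  # the squat starts and ends at rest: net vertical impulse ~ 0
  impulse <- mean(trial$grf$fy - share_w) * 4
  expect_lt(abs(impulse) / (share_w * 4), 0.005)
})

test_that("valgus-group template exceeds the paired normal template by the configured offsets", {
  spec <- quiet_spec()
  pv <- generate_participant("valgus", 42, spec = spec)
  pn <- generate_participant("normal", 42, spec = spec)  # same base draws
  pn$valgus_deg <- pv$valgus_deg  # isolate the group-effect offsets
  pn2 <- pn; pn2$group <- "normal"
  mv <- build_true_model(pv)
  tv <- generate_squat_trial(pv, load_condition(0, pv$onerm_kg), mv, spec,
                             seed = 5)
  tn <- generate_squat_trial(pn2, load_condition(0, pn2$onerm_kg),
                             build_true_model(pn2), spec, seed = 5)
  dv <- max(tv$ground_truth$angles[, "knee_flexion"]) -
    max(tn$ground_truth$angles[, "knee_flexion"])
  expect_lt(abs(dv - spec$effects$knee_flexion_deg), 0.5)
  dh <- max(tv$ground_truth$angles[, "hip_flexion"]) -
    max(tn$ground_truth$angles[, "hip_flexion"])
  expect_lt(abs(dh - spec$effects$hip_flexion_deg), 0.5)
})

test_that("group-effect offsets move the corresponding template peaks monotonically", {
  base <- quiet_spec()
  bigger <- quiet_spec(effects = list(knee_flexion_deg = 20))
  p1 <- generate_participant("valgus", 8, spec = base)
  t1 <- generate_squat_trial(p1, load_condition(0, p1$onerm_kg),
                             build_true_model(p1), base, seed = 2)
  t2 <- generate_squat_trial(p1, load_condition(0, p1$onerm_kg),
                             build_true_model(p1), bigger, seed = 2)
  expect_gt(max(t2$ground_truth$angles[, "knee_flexion"]),
            max(t1$ground_truth$angles[, "knee_flexion"]) + 5)
})

test_that("cohort generation writes the expected files and a seed-stable manifest", {
  spec <- cohort_spec(n_per_group = 1, loads = 0, trials = 1, seed = 3)
  d1 <- file.path(tempdir(), "cohort_a")
  man <- generate_cohort(spec, d1)
  expect_equal(nrow(man), 2)  # 2 participants x 1 load x 1 trial
  expect_true(all(file.exists(file.path(d1, c(man$trc, man$grf, man$emg,
                                              unique(man$static_trc))))))
  d2 <- file.path(tempdir(), "cohort_b")
  generate_cohort(spec, d2)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  expect_error(generate_cohort(spec, "/proc/definitely/not/writable"),
               class = "io_error")
})

test_that("TRC files round-trip marker trajectories", {
  cs <- zero_noise_case()
  path <- tempfile(fileext = ".trc")
  write_trc(cs$trial$markers, cs$trial$marker_rate, path)
  back <- read_trc(path)
  expect_equal(attr(back, "rate_hz"), cs$trial$marker_rate)
  expect_equal(names(back), names(cs$trial$markers))
  for (nm in names(back)) {
    expect_equal(unname(back[[nm]]), unname(cs$trial$markers[[nm]]),
                 tolerance = 1e-6)
  }
})

test_that("trial generation is deterministic and validates its inputs", {
  spec <- cohort_spec()
  p <- generate_participant("normal", 3, spec = spec)
  m <- build_true_model(p)
  ld <- load_condition(0.3, p$onerm_kg)
  t1 <- generate_squat_trial(p, ld, m, spec, seed = 12)
  t2 <- generate_squat_trial(p, ld, m, spec, seed = 12)
  expect_identical(t1$markers, t2$markers)
  expect_identical(t1$emg, t2$emg)
  unscaled <- build_default_model(p)
  expect_error(generate_squat_trial(p, ld, unscaled, spec, seed = 1),
               class = "unscaled_model")
})
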