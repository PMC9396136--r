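# Minimal one-DOF model builders for the optimization oracles.
so_toy_model <- function(arms, fmax) {
  m <- build_default_model(default_participant())
  m$muscles <- lapply(seq_along(arms), function(j) {
    list(fmax = fmax[j], arms = list(knee_flexion = arms[j]))
  })
  names(m$muscles) <- paste0("mus", seq_along(arms))
  m$muscle_balance_dofs <- "knee_flexion"
  m
}

so_frame <- function(model, M) {
  moments <- matrix(0, 1, 8, dimnames = list(NULL, model$dofs))
  moments[1, "knee_flexion"] <- M
  static_optimization(model, moments,
                      matrix(0, 1, 8, dimnames = list(NULL, model$dofs)),
                      reserves = FALSE)
}

test_that("static optimization matches the closed-form KKT solution", {
  # two muscles, arms 0.05/0.025 m, Fmax 1000 N each, M = 50 N m:
  # a_j = M c_j / sum(c^2) -> (0.8, 0.4)
  sol <- so_frame(so_toy_model(c(0.05, 0.025), c(1000, 1000)), 50)
  expect_lt(abs(sol$activations[1, 1] - 0.8), 1e-9 * 0.8)
  expect_lt(abs(sol$activations[1, 2] - 0.4), 1e-9 * 0.4)
  expect_equal(50 * 0.8 + 25 * 0.4, 50)  # balance of the hand solution
  expect_lt(sol$residual[1], 1e-9)

  # identical muscles split symmetrically
  sym <- so_frame(so_toy_model(c(0.05, 0.05), c(1000, 1000)), 50)
  expect_equal(unname(sym$activations[1, ]), c(0.5, 0.5), tolerance = 1e-9)

  # zero moment -> zero activation
  z <- so_frame(so_toy_model(c(0.05, 0.025), c(1000, 1000)), 0)
  expect_equal(max(abs(z$activations)), 0)
})

test_that("infeasible frames without reserves raise an error naming the DOF", {
  m <- so_toy_model(c(0.05), c(1000))
  m$muscle_balance_dofs <- c("knee_flexion", "hip_flexion")
  moments <- matrix(0, 1, 8, dimnames = list(NULL, m$dofs))
  moments[1, "hip_flexion"] <- -40  # no muscle spans the hip here
  expect_error(
    static_optimization(m, moments,
                        matrix(0, 1, 8, dimnames = list(NULL, m$dofs)),
                        reserves = FALSE),
    "hip_flexion", class = "so_infeasible")
})

test_that("activations scale as 1/k when all Fmax scale by k (forces unchanged)", {
  m1 <- so_toy_model(c(0.05, 0.03), c(1000, 2000))
  m2 <- so_toy_model(c(0.05, 0.03), 2 * c(1000, 2000))
  s1 <- so_frame(m1, 40)
  s2 <- so_frame(m2, 40)
  expect_equal(unname(s2$activations[1, ]), unname(s1$activations[1, ]) / 2,
               tolerance = 1e-9)
  expect_equal(unname(s2$forces[1, ]), unname(s1$forces[1, ]),
               tolerance = 1e-9)
})

test_that("the balance residual stays below 1e-6 N m on a full trial", {
  pc <- processed_case()
  act <- pc$result$raw$act
  expect_lt(max(act$residual), 1e-6)
  expect_true(all(act$activations >= 0 & act$activations <= 1))
})

test_that("the QP solution is optimal against an independent solver", {
  skip_if_not_installed("pracma")
  set.seed(31)
  for (k in 1:25) {
    nd <- sample(2:4, 1); nm <- sample(2:6, 1)
    C <- matrix(rnorm(nd * nm, 0, 50), nd, nm,
                dimnames = list(paste0("d", 1:nd), paste0("m", 1:nm)))
    M <- rnorm(nd, 0, 40)
    sol <- squatmech:::.so_solve_frame(C, M, TRUE, 1000)
    H <- diag(c(rep(1, nm), rep(1000, nd)))
    ref <- pracma::quadprog(H, rep(0, nm + nd),
                            Aeq = cbind(C, diag(nd)), beq = M,
                            lb = c(rep(0, nm), rep(-1e6, nd)),
                            ub = c(rep(1, nm), rep(1e6, nd)))
    obj <- sum(sol$a^2) + 1000 * sum(sol$reserve^2)
    obj_ref <- sum(ref$xmin[1:nm]^2) +
      1000 * sum(ref$xmin[(nm + 1):(nm + nd)]^2)
    expect_lt(abs(obj - obj_ref), 1e-6 * (1 + obj_ref))
  }
})

test_that("EMG band-pass attenuates out-of-band and passes in-band tones", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  db <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    y <- emg_bandpass(x, fs)
    mid <- seq(round(0.25 * length(t)), round(0.75 * length(t)))
    20 * log10(stats::sd(y[mid]) / stats::sd(x[mid]))
  }
  expect_lt(db(50), -40)            # 50 Hz tone attenuated > 40 dB
  expect_gt(db(200), -1)            # 200 Hz tone passed within 1 dB
  expect_equal(emg_bandpass(rep(0, 500), fs), rep(0, 500))
  expect_error(emg_bandpass(rnorm(100), fs, strict = TRUE),
               class = "band_edge")
  # a genuinely realizable band still uses the band-pass design
  y <- emg_bandpass(sin(2 * pi * 200 * t), 2000, band_hz = c(100, 500))
  expect_gt(stats::sd(y), 0.5)
})

test_that("RMS envelopes and MVC normalization follow the 0-1 activation scale", {
  expect_equal(emg_rms_envelope(rep(0.3, 1000), 1000),
               rep(0.3, 1000), tolerance = 1e-12)
  # pointwise larger |signal| never yields a smaller envelope
  set.seed(2)
  x <- rnorm(2000)
  e1 <- emg_rms_envelope(x, 1000)
  e2 <- emg_rms_envelope(2 * x, 1000)
  expect_true(all(e2 - e1 >= -1e-12))

  expect_equal(unname(normalize_mvc(c(0.5), 0.5)[1]), 1)   # test RMS == MVC
  expect_equal(unname(normalize_mvc(c(0), 0.5)[1]), 0)
  expect_equal(unname(normalize_mvc(c(2), 0.5)[1]), 1)     # clamped
  expect_error(normalize_mvc(c(0.1), 0), class = "bad_mvc")
  expect_error(emg_rms_envelope(x, 1000, window_ms = -5),
               class = "bad_window")
})

test_that("activation validation reports r/RMSE and handles constant series", {
  a <- matrix(sin(seq(0, pi, length.out = 101)), 101, 1,
              dimnames = list(NULL, "rectus_femoris"))
  same <- validate_activations(a, a)
  expect_equal(same$r, 1)
  expect_equal(same$rmse, 0)
  neg <- validate_activations(a, -a)
  expect_equal(neg$r, -1)
  const <- matrix(0.5, 101, 1, dimnames = list(NULL, "rectus_femoris"))
  res <- validate_activations(const, a)
  expect_true(is.na(res$r))
  expect_match(res$note, "constant")
  expect_error(validate_activations(a, matrix(0, 101, 1,
                                              dimnames = list(NULL, "x"))),
               class = "lookup_error")
})

test_that("optimized activations track the EMG built from the generating activations", {
  pc <- processed_case()
  v <- pc$result$validation
  expect_true(all(!is.na(v$r)))
  expect_true(all(v$r >= 0.7))       # documented pass threshold
  expect_gte(stats::median(v$r), 0.9)
  expect_true(attr(v, "pass"))
})
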