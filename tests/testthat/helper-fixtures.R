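# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

quiet_spec <- function(...) {
  cohort_spec(noise = list(marker_sd_m = 0, grf_sd_n = 0, emg_noise = 0),
              ...)
}

# One noise-free valgus trial with its generating model, shared by the
# recovery tests.
zero_noise_case <- function() {
  fixture("zero_noise_case", function() {
    spec <- quiet_spec()
    p <- generate_participant("valgus", 42, spec = spec)
    m <- build_true_model(p)
    load <- load_condition(0.3, p$onerm_kg)
    trial <- generate_squat_trial(p, load, m, spec, seed = 7)
    list(spec = spec, p = p, model = m, load = load, trial = trial)
  })
}

# One default-noise trial processed through the full chain.
processed_case <- function() {
  fixture("processed_case", function() {
    spec <- cohort_spec()
    p <- generate_participant("normal", 42, spec = spec)
    m <- build_true_model(p)
    load <- load_condition(0.3, p$onerm_kg)
    trial <- generate_squat_trial(p, load, m, spec, seed = 9)
    st <- generate_static_trial(p, m, spec, seed = 3)
    sc <- scale_model(build_default_model(p), st)
    model <- sc$model
    model$participant <- p
    list(spec = spec, p = p, true_model = m, model = model,
         scaling = sc$report, load = load, trial = trial,
         result = process_trial(model, trial))
  })
}

# Smooth Gaussian null curves (unit variance, FWHM in samples).
smooth_curves <- function(n, L = 101, fwhm = 15) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  pad <- 30
  k <- dnorm(seq(-3 * sigma, 3 * sigma), 0, sigma)
  k <- k / sqrt(sum(k^2))
  t(vapply(seq_len(n), function(i) {
    x <- rnorm(L + 2 * pad)
    as.numeric(stats::filter(x, k, circular = TRUE))[pad + (1:L)]
  }, numeric(L)))
}

default_participant <- function() {
  participant("P1", 65.67, 1.72, 3, 1.2 * 65.67)
}
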