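# Small numeric helpers shared across the pipeline.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
rot_x <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(1, 0, 0,
           0, c1, s1,
           0, -s1, c1), 3, 3)
}

#' @noRd
rot_y <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, 0, -s1,
           0, 1, 0,
           s1, 0, c1), 3, 3)
}

#' @noRd
rot_z <- function(a) {
  c1 <- cos(a); s1 <- sin(a)
  matrix(c(c1, s1, 0,
           -s1, c1, 0,
           0, 0, 1), 3, 3)
}

# Deterministic child seed derivation; keeps results < 2^31 so they are
# valid R integer seeds whatever the parent seed is.
derive_seed <- function(seed, ...) {
  ks <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ks) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Central differences with one-sided ends; x is a vector sampled at dt.
finite_diff <- function(x, dt) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# Zero-phase Butterworth low-pass (order-2 design applied forward and
# backward, i.e. 4th-order zero-lag magnitude response).
lowpass_filtfilt <- function(x, cutoff_hz, rate_hz) {
  if (cutoff_hz >= rate_hz / 2) return(x)
  bf <- signal::butter(2, cutoff_hz / (rate_hz / 2), type = "low")
  pad <- min(length(x) - 1L, 3L * max(30L, round(rate_hz / cutoff_hz)))
  # reflect-pad to suppress filtfilt end transients
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[length(x)] - rev(x)[2:(pad + 1)])
  yp <- signal::filtfilt(bf, xp)
  yp[(pad + 1):(pad + length(x))]
}

# Evaluate polynomial with coefficients c(c0, c1, c2, ...) at x:
# c0 + c1*x + c2*x^2 + ...
polyval_asc <- function(coefs, x) {
  y <- 0
  for (k in rev(seq_along(coefs))) y <- y * x + coefs[[k]]
  y
}

stop_squatmech <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "squatmech_error")))
}
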