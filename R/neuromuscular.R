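# Static optimization of muscle activations and EMG processing
# (band-pass, RMS envelope, MVC normalization) for model validation.
#
# Muscles are rigid-tendon, activation-proportional actuators
# (F = a * Fmax), which keeps the per-frame problem a quadratic program:
#   minimize  sum(a^2) [+ w * sum(reserve^2)]
#   s.t.      sum_j r_ij(pose) * Fmax_j * a_j [+ reserve_i] = M_i,
#             0 <= a_j <= 1.

# Solve one frame.  C: ndof x nmus matrix of arm*Fmax; M: ndof moments.
# Box-constrained weighted least-norm QP solved exactly by the dual
# active-set method of Goldfarb-Idnani (quadprog).  With reserves the
# problem is always feasible; without them an inconsistent equality
# system raises an infeasibility error naming the DOFs.
.so_solve_frame <- function(C, M, reserves, reserve_weight) {
  nm <- ncol(C)
  nd <- nrow(C)
  nx <- nm + if (reserves) nd else 0L
  D <- diag(c(rep(2, nm), rep(2 * reserve_weight, nd))[seq_len(nx)],
            nx)
  Aeq <- if (reserves) cbind(C, diag(nd)) else C
  # equality rows first (meq), then a >= 0 and a <= 1
  Amat <- t(rbind(Aeq,
                  cbind(diag(nm), matrix(0, nm, nx - nm)),
                  cbind(-diag(nm), matrix(0, nm, nx - nm))))
  bvec <- c(M, rep(0, nm), rep(-1, nm))
  sol <- tryCatch(
    quadprog::solve.QP(D, rep(0, nx), Amat, bvec, meq = nd),
    error = function(e) NULL)
  if (is.null(sol)) {
    bad <- rownames(C)[abs(M) > 1e-9]
    stop_squatmech(paste("static optimization infeasible without",
                         "reserves for DOF(s):",
                         paste(bad, collapse = ", ")), "so_infeasible")
  }
  a <- pmin(pmax(sol$solution[seq_len(nm)], 0), 1)
  b <- if (reserves) sol$solution[(nm + 1):nx] else numeric(nd)
  list(a = a, reserve = b)
}

#' Static optimization of muscle activations
#'
#' Per frame, distributes the net joint moments among the model's
#' muscles by minimizing the sum of squared activations subject to
#' moment balance at every DOF and activation bounds \[0, 1\].
#' High-cost reserve actuators (enabled by default, mirroring common
#' musculoskeletal practice) guarantee feasibility and absorb moments no
#' muscle can produce; with `reserves = FALSE` the equality-constrained
#' problem is solved exactly and infeasible frames raise an error.
#'
#' @param model A `squat_model`.
#' @param moments Frames x 8 matrix of raw joint moments (N m).
#' @param poses Frames x 8 matrix of joint angles (degrees) used to
#'   evaluate pose-dependent moment arms.
#' @param reserves Enable reserve actuators.
#' @param reserve_weight Quadratic cost weight on reserve moments
#'   (per N m); default 1000.
#' @param dofs DOFs whose moments the muscles must balance; defaults to
#'   the model's `muscle_balance_dofs` (the knee frontal/transverse
#'   moments are carried by articular contact, not recruitment).
#' @return An `activation_solution`: `activations` and `forces`
#'   (frames x muscles), `reserves` (frames x 8, N m), `objective`
#'   (sum of squared activations per frame) and `residual` (max DOF
#'   balance error per frame, N m).
#' @export
static_optimization <- function(model, moments, poses,
                                reserves = TRUE, reserve_weight = 1000,
                                dofs = NULL) {
  dofs <- dofs %||% model$muscle_balance_dofs %||% model$dofs
  mus <- names(model$muscles)
  fmax <- vapply(model$muscles, function(m) m$fmax, numeric(1))
  n <- nrow(moments)
  stopifnot(nrow(poses) == n)
  A <- matrix(0, n, length(mus), dimnames = list(NULL, mus))
  B <- matrix(0, n, length(dofs), dimnames = list(NULL, dofs))
  resid <- numeric(n)
  for (f in seq_len(n)) {
    pose <- poses[f, ]
    C <- matrix(0, length(dofs), length(mus),
                dimnames = list(dofs, mus))
    for (j in seq_along(mus)) {
      for (d in intersect(names(model$muscles[[j]]$arms), dofs)) {
        C[d, j] <- moment_arm(model, mus[j], d, pose) * fmax[j]
      }
    }
    M <- as.numeric(moments[f, dofs])
    sol <- .so_solve_frame(C, M, reserves, reserve_weight)
    A[f, ] <- sol$a
    B[f, ] <- sol$reserve
    resid[f] <- max(abs(as.numeric(C %*% sol$a) + sol$reserve - M))
  }
  structure(list(activations = A,
                 forces = sweep(A, 2, fmax, `*`),
                 reserves = B,
                 objective = rowSums(A^2),
                 residual = resid),
            class = "activation_solution")
}

#' Band-pass filter a raw EMG channel
#'
#' Zero-phase Butterworth band-pass of the stated design order.  When the
#' upper band edge reaches the Nyquist frequency (as with a 100-500 Hz
#' band at a 1,000 Hz sampling rate) the band-pass is not realizable and
#' the filter degenerates to the corresponding high-pass at the lower
#' edge; `strict = TRUE` raises an error instead.
#'
#' @param x Raw EMG samples.
#' @param rate_hz Sampling rate, default 1000.
#' @param band_hz Pass band in Hz, default c(100, 500).
#' @param order Filter design order, default 4.
#' @param strict Error if the upper edge is at/above Nyquist.
#' @return Filtered samples.
#' @export
emg_bandpass <- function(x, rate_hz = 1000, band_hz = c(100, 500),
                         order = 4, strict = FALSE) {
  nyq <- rate_hz / 2
  if (band_hz[2] >= nyq) {
    if (strict) {
      stop_squatmech("band upper edge at or above Nyquist frequency",
                     "band_edge")
    }
    bf <- signal::butter(order, band_hz[1] / nyq, type = "high")
  } else {
    bf <- signal::butter(max(1L, order %/% 2L), band_hz / nyq, type = "pass")
  }
  as.numeric(signal::filtfilt(bf, x))
}

#' Moving-window RMS envelope
#'
#' Window RMS values computed at 50%-overlap hops and linearly
#' interpolated back to the sample grid.
#'
#' @param x Filtered EMG samples.
#' @param rate_hz Sampling rate (Hz).
#' @param window_ms Window length in ms (> 0), default 100.
#' @param overlap Fractional window overlap, default 0.5.
#' @return RMS series, same length as `x`.
#' @export
emg_rms_envelope <- function(x, rate_hz = 1000, window_ms = 100,
                             overlap = 0.5) {
  if (window_ms <= 0) stop_squatmech("window must be positive", "bad_window")
  w <- max(2L, round(window_ms / 1000 * rate_hz))
  hop <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, max(1L, length(x) - w + 1L), by = hop)
  centers <- starts + (w - 1) / 2
  rms <- vapply(starts, function(s) {
    sqrt(mean(x[s:min(length(x), s + w - 1L)]^2))
  }, numeric(1))
  if (length(rms) == 1L) return(rep(rms, length(x)))
  stats::approx(centers, rms, xout = seq_along(x), rule = 2)$y
}

#' Normalize an EMG RMS series to MVC
#'
#' Activation scale: 0 is complete inactivation, 1 full activation
#' (test RMS equal to the MVC reference RMS); values above 1 are clamped.
#'
#' @param test_rms RMS series from the test bout.
#' @param mvc_rms Scalar MVC reference RMS (> 0).
#' @return Normalized activation series in \[0, 1\] with attribute
#'   `mvc_rms`.
#' @export
normalize_mvc <- function(test_rms, mvc_rms) {
  if (!is.finite(mvc_rms) || mvc_rms <= 0) {
    stop_squatmech("MVC reference RMS must be positive", "bad_mvc")
  }
  out <- pmin(pmax(test_rms / mvc_rms, 0), 1)
  attr(out, "mvc_rms") <- mvc_rms
  out
}

#' Compare measured EMG activation with static-optimization activation
#'
#' Per-muscle Pearson correlation and RMSE between the normalized EMG
#' envelope and the optimized activation, both on the 101-point cycle.
#'
#' @param emg_curves 101 x k matrix of normalized EMG envelopes, columns
#'   named by muscle.
#' @param so_curves 101 x m matrix of optimized activations (must contain
#'   the EMG muscles among its columns).
#' @param r_threshold Per-muscle pass threshold on r, default 0.7.
#' @return Data frame (muscle, r, rmse, note) with attribute `pass`.
#' @export
validate_activations <- function(emg_curves, so_curves, r_threshold = 0.7) {
  mus <- colnames(emg_curves)
  missing <- setdiff(mus, colnames(so_curves))
  if (length(missing)) {
    stop_squatmech(paste("no optimized activation for muscle(s):",
                         paste(missing, collapse = ", ")), "lookup_error")
  }
  res <- data.frame(muscle = mus, r = NA_real_, rmse = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_along(mus)) {
    a <- emg_curves[, mus[i]]
    b <- so_curves[, mus[i]]
    res$rmse[i] <- sqrt(mean((a - b)^2))
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      res$note[i] <- "correlation undefined for constant series"
    } else {
      res$r[i] <- stats::cor(a, b)
    }
  }
  attr(res, "pass") <- all(!is.na(res$r)) && all(res$r >= r_threshold)
  res
}
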