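# Model scaling, per-frame inverse kinematics, squat-cycle segmentation,
# 101-point time normalization, and angle metrics.

#' Classify foot posture from the static rearfoot valgus angle
#'
#' The group cutoff is a standing rearfoot valgus angle strictly greater
#' than 5 degrees.
#'
#' @param valgus_deg Static valgus angle in degrees (finite, >= 0).
#' @return `"valgus"` or `"normal"`.
#' @export
classify_foot_posture <- function(valgus_deg) {
  if (length(valgus_deg) != 1L || !is.finite(valgus_deg) || valgus_deg < 0) {
    stop_squatmech("valgus angle must be a finite non-negative scalar",
                   "invalid_angle")
  }
  if (valgus_deg > 5) "valgus" else "normal"
}

#' Zero-lag low-pass filter marker trajectories
#'
#' 4th-order zero-phase Butterworth (order-2 design run forward and
#' backward), default 6 Hz cutoff, applied per marker per axis.
#'
#' @param trial A `squat_trial`.
#' @param cutoff_hz Cutoff frequency in Hz.
#' @return The trial with filtered marker trajectories.
#' @export
filter_markers <- function(trial, cutoff_hz = 6) {
  trial$markers <- lapply(trial$markers, function(mk) {
    apply(mk, 2, lowpass_filtfilt, cutoff_hz = cutoff_hz,
          rate_hz = trial$marker_rate)
  })
  trial$markers_filtered <- TRUE
  trial
}

#' Scale a model to a static trial and report marker residuals
#'
#' Per-segment scale factors are ratios of mean experimental to model
#' inter-marker distances within each segment.  After scaling, the static
#' pose is solved by inverse kinematics on the time-averaged marker frame
#' and the per-marker residuals are reported.  The scale gates (RMS
#' < 0.02 m and max < 0.04 m) fail loudly unless `enforce_gates = FALSE`.
#'
#' @param model An unscaled `squat_model`.
#' @param static_trial A `squat_trial` of quiet upright standing.
#' @param enforce_gates Error if the marker-residual gates are violated.
#' @return List with `model` (scaled) and `report` (a `scaling_report`
#'   with `factors`, `marker_rms_m`, `marker_max_m`, `pass`).
#' @export
scale_model <- function(model, static_trial, enforce_gates = TRUE) {
  need <- names(model$markers)
  have <- names(static_trial$markers)
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop_squatmech(paste("static trial is missing marker(s):",
                         paste(missing, collapse = ", ")),
                   "missing_marker")
  }
  mean_pos <- t(vapply(need, function(m) colMeans(static_trial$markers[[m]]),
                       numeric(3)))
  neutral <- fk_pose(model, stats::setNames(numeric(8), model$dofs))$markers
  seg_of <- vapply(model$markers, function(m) m$segment, character(1))
  factors <- c(foot = 1, shank = 1, thigh = 1, pelvis = 1)
  for (s in names(factors)) {
    # the calcaneus sub-frame scales with the foot, but only pairs within
    # one rigid (sub-)frame are pose-invariant, so ratios are pooled per
    # sub-frame and averaged into the segment factor
    frames <- if (s == "foot") c("foot", "calcaneus") else s
    ratio <- unlist(lapply(frames, function(fr) {
      mks <- need[seg_of == fr]
      if (length(mks) < 2) return(NULL)
      pairs <- utils::combn(mks, 2)
      apply(pairs, 2, function(pr) {
        de <- sqrt(sum((mean_pos[pr[1], ] - mean_pos[pr[2], ])^2))
        dm <- sqrt(sum((neutral[pr[1], ] - neutral[pr[2], ])^2))
        de / dm
      })
    }))
    if (length(ratio)) factors[[s]] <- mean(ratio)
  }
  scaled <- apply_segment_scales(model, as.list(factors))
  scaled$scaled <- TRUE
  # static-pose IK on the averaged frame, then marker residuals
  q0 <- stats::setNames(numeric(8), model$dofs)
  fit <- ik_solve_frame(scaled, as.vector(t(mean_pos)), q0,
                        max_iter = 400, tol = 1e-12)
  pred <- matrix(fit$pred, ncol = 3, byrow = TRUE)
  res <- sqrt(rowSums((mean_pos - pred)^2))
  report <- structure(list(
    factors = factors,
    static_pose = fit$q,
    marker_rms_m = sqrt(mean(res^2)),
    marker_max_m = max(res),
    per_marker_m = stats::setNames(res, need),
    pass = sqrt(mean(res^2)) < 0.02 && max(res) < 0.04
  ), class = "scaling_report")
  if (enforce_gates && !report$pass) {
    stop_squatmech(sprintf(
      "scaling gates violated: marker RMS %.4f m (gate 0.02), max %.4f m (gate 0.04)",
      report$marker_rms_m, report$marker_max_m), "scaling_gate")
  }
  list(model = scaled, report = report)
}

# Damped Gauss-Newton (Levenberg-Marquardt) marker fit for one frame.
# target: length-3n vector of experimental marker coordinates (row-major
# by marker, in the model's marker order); q0: start pose in degrees.
ik_solve_frame <- function(model, target, q0, max_iter = 200, tol = 1e-8,
                           weights = NULL) {
  q <- q0
  w <- if (is.null(weights)) rep(1, length(target)) else weights
  pred <- fk_marker_vec(model, q)
  r <- target - pred
  cost <- sum(w * r^2)
  lambda <- 1e-3
  step_deg <- 1e-3
  nq <- length(q)
  costs <- cost
  for (it in seq_len(max_iter)) {
    J <- matrix(0, length(target), nq)
    for (j in seq_len(nq)) {
      qj <- q
      qj[j] <- qj[j] + step_deg
      J[, j] <- (fk_marker_vec(model, qj) - pred) / step_deg
    }
    g <- crossprod(J, w * r)
    H <- crossprod(J, w * J)
    improved <- FALSE
    for (k in 1:30) {
      delta <- tryCatch(solve(H + lambda * diag(nq), g),
                        error = function(e) NULL)
      if (!is.null(delta)) {
        qn <- q + as.numeric(delta)
        predn <- fk_marker_vec(model, qn)
        rn <- target - predn
        costn <- sum(w * rn^2)
        if (costn <= cost) {
          q <- qn; pred <- predn; r <- rn
          dcost <- cost - costn
          cost <- costn
          lambda <- max(lambda / 3, 1e-10)
          improved <- TRUE
          costs <- c(costs, cost)
          if (dcost < tol * max(cost, 1e-12) ||
              sqrt(sum(delta^2)) < 1e-8) {
            return(list(q = q, pred = pred, cost = cost, costs = costs,
                        iterations = it, converged = TRUE))
          }
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) {
      return(list(q = q, pred = pred, cost = cost, costs = costs,
                  iterations = it, converged = TRUE))
    }
  }
  list(q = q, pred = pred, cost = cost, costs = costs,
       iterations = max_iter, converged = FALSE)
}

#' Marker-driven inverse kinematics
#'
#' Per frame, finds the joint angles minimizing the (weighted) sum of
#' squared distances between experimental and model-predicted markers,
#' warm-starting each frame from the previous solution for continuity.
#'
#' @param model A scaled `squat_model`.
#' @param trial A `squat_trial` (markers are low-pass filtered first
#'   unless already filtered).
#' @param filter_cutoff_hz Marker filter cutoff (Hz).
#' @return Matrix (frames x 8 DOFs) of joint angles in degrees under the
#'   package sign conventions, with attribute `rate_hz`.
#' @export
inverse_kinematics <- function(model, trial, filter_cutoff_hz = 6) {
  if (!isTRUE(model$scaled)) {
    stop_squatmech("model must be scaled before inverse kinematics",
                   "unscaled_model")
  }
  if (!isTRUE(trial$markers_filtered)) {
    trial <- filter_markers(trial, filter_cutoff_hz)
  }
  need <- names(model$markers)
  missing <- setdiff(need, names(trial$markers))
  if (length(missing)) {
    stop_squatmech(paste("trial is missing marker(s):",
                         paste(missing, collapse = ", ")), "missing_marker")
  }
  nfr <- nrow(trial$markers[[1]])
  targets <- matrix(0, nfr, 3L * length(need))
  for (i in seq_along(need)) {
    targets[, (3 * i - 2):(3 * i)] <- trial$markers[[need[i]]]
  }
  Q <- matrix(0, nfr, length(model$dofs),
              dimnames = list(NULL, model$dofs))
  q <- stats::setNames(numeric(length(model$dofs)), model$dofs)
  for (f in seq_len(nfr)) {
    fit <- ik_solve_frame(model, targets[f, ], q)
    if (!fit$converged) {
      stop_squatmech(sprintf("inverse kinematics failed to converge at frame %d", f),
                     "ik_nonconvergence")
    }
    q <- fit$q
    Q[f, ] <- q
  }
  attr(Q, "rate_hz") <- trial$marker_rate
  Q
}

#' Segment one squat cycle from the knee-flexion trace
#'
#' The deepest point is the global knee-flexion maximum (earliest frame
#' on ties); the cycle starts at the last crossing of the upright
#' threshold before it and ends at the first crossing after it.
#'
#' @param knee_flexion Numeric vector of knee flexion angles (degrees).
#' @param threshold_deg Upright threshold (degrees), default 10.
#' @return A `phase_segmentation` list: `start`, `deepest`, `end` (frame
#'   indices).
#' @export
segment_cycle <- function(knee_flexion, threshold_deg = 10) {
  if (max(knee_flexion) <= threshold_deg) {
    stop_squatmech("no squat detected: knee flexion never exceeds threshold",
                   "no_squat")
  }
  deepest <- which.max(knee_flexion)  # which.max takes the earliest tie
  before <- which(knee_flexion[seq_len(deepest)] <= threshold_deg)
  start <- if (length(before)) max(before) else 1L
  after <- which(knee_flexion[deepest:length(knee_flexion)] <= threshold_deg)
  end <- if (length(after)) deepest + min(after) - 1L else length(knee_flexion)
  structure(list(start = start, deepest = deepest, end = end),
            class = "phase_segmentation")
}

#' Time-normalize a cycle to 101 samples (0-100% of the squat)
#'
#' Descent (start to deepest) is resampled to samples 0-50 and ascent
#' (deepest to end) to samples 50-100 by piecewise-linear interpolation,
#' so the deepest frame always lands exactly at 50%.
#'
#' @param series Numeric vector or matrix (frames x k).
#' @param seg A `phase_segmentation` from [segment_cycle()].
#' @param units Unit string stored on the result.
#' @param quantity Quantity label stored on the result.
#' @return A `cycle_curves` matrix of 101 rows.
#' @export
time_normalize <- function(series, seg, units = "", quantity = "") {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  n <- nrow(series)
  if (seg$start < 1 || seg$end > n || seg$start >= seg$deepest ||
      seg$deepest >= seg$end) {
    stop_squatmech("segmentation is outside the series bounds",
                   "invalid_segmentation")
  }
  resample <- function(idx, npts) {
    s <- seq(idx[1], idx[length(idx)], length.out = npts)
    apply(series, 2, function(col) {
      stats::approx(seq_len(n), col, xout = s)$y
    })
  }
  descent <- resample(seg$start:seg$deepest, 51L)
  ascent <- resample(seg$deepest:seg$end, 51L)
  out <- rbind(descent, ascent[-1, , drop = FALSE])
  dimnames(out) <- list(NULL, colnames(series))
  structure(out, class = c("cycle_curves", class(out)),
            units = units, quantity = quantity,
            pct = 0:100)
}

# Signed-peak metric definitions for joint angles (Table-1-style rows):
# value = max(direction * curve), i.e. the extremum in the printed
# anatomical direction, reported as a positive magnitude in that
# direction.
.angle_metric_defs <- function() {
  data.frame(
    metric = c("hip_flexion_peak", "hip_abduction_peak", "knee_flexion_peak",
               "knee_adduction_peak", "knee_abduction_peak",
               "ankle_dorsiflexion_peak", "foot_valgus_peak"),
    dof = c("hip_flexion", "hip_adduction", "knee_flexion",
            "knee_adduction", "knee_adduction", "ankle_dorsiflexion",
            "subtalar_supination"),
    direction = c(1, -1, 1, 1, -1, 1, -1),
    stringsAsFactors = FALSE
  )
}

#' Peak joint angles over the cycle
#'
#' Signed extrema per DOF in the direction each row of the peak-angle
#' table is reported (e.g. hip abduction and foot valgus peaks are
#' magnitudes in the negative-convention direction).
#'
#' @param curves A `cycle_curves` matrix of joint angles (degrees) with
#'   DOF column names.
#' @return Named numeric vector of peak angles (degrees).
#' @export
peak_angles <- function(curves) {
  defs <- .angle_metric_defs()
  out <- stats::setNames(numeric(nrow(defs)), defs$metric)
  for (i in seq_len(nrow(defs))) {
    out[i] <- max(defs$direction[i] * curves[, defs$dof[i]])
  }
  out
}

#' Range of motion per joint and anatomical plane
#'
#' @param curves A `cycle_curves` matrix of joint angles (degrees).
#' @return Named numeric vector (max minus min, degrees) for hip, knee
#'   (sagittal/coronal/transverse), ankle sagittal and subtalar.
#' @export
range_of_motion <- function(curves) {
  rom <- function(d) max(curves[, d]) - min(curves[, d])
  c(hip_sagittal = rom("hip_flexion"),
    hip_coronal = rom("hip_adduction"),
    hip_transverse = rom("hip_rotation"),
    knee_sagittal = rom("knee_flexion"),
    knee_coronal = rom("knee_adduction"),
    knee_transverse = rom("knee_rotation"),
    ankle_sagittal = rom("ankle_dorsiflexion"),
    subtalar = rom("subtalar_supination"))
}
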