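# Synthetic squat-cohort generator: participants, joint-angle templates,
# forward-kinematic marker trajectories, dynamically consistent ground
# reaction forces, and activation-modulated surface EMG, with the full
# ground truth retained so every downstream stage can be checked by
# parameter recovery.

#' Specify a synthetic cohort
#'
#' Defaults encode the study conditions: two groups (static rearfoot
#' valgus > 5 degrees vs < 5 degrees), loads of 0/30/70% 1RM, three
#' trials per condition, 4 s squats sampled at 100 Hz (markers/GRF) and
#' 1,000 Hz (EMG), and group effects in the directions of the cohort's
#' result tables (larger peak knee flexion, hip flexion, dorsiflexion,
#' knee adduction, external knee adduction moment -- and through the
#' latter, medial contact force -- in the valgus group).
#'
#' @param n_per_group Participants per group (>= 1).
#' @param loads Load conditions as fractions of 1RM.
#' @param trials Trials per condition (>= 1).
#' @param effects Named list of valgus-group offsets: `hip_flexion_deg`,
#'   `knee_flexion_deg`, `dorsiflexion_deg`, `knee_adduction_deg`,
#'   `knee_adduction_moment_nm_kg` (drives the external frontal moment
#'   via a medial center-of-pressure shift, and with it the medial
#'   contact-force share).
#' @param noise Named list: `marker_sd_m` (default 0.003),
#'   `grf_sd_n` (default 5), `emg_noise` (relative EMG noise floor,
#'   default 0.05).
#' @param seed Integer seed; the same spec generates a bit-identical
#'   cohort.
#' @param duration_s,marker_rate_hz,emg_rate_hz Trial timing.
#' @param onerm_factor 1RM as a multiple of body mass (default 1.2).
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        loads = c(0, 0.3, 0.7),
                        trials = 3,
                        effects = list(),
                        noise = list(),
                        seed = 1,
                        duration_s = 4,
                        marker_rate_hz = 100,
                        emg_rate_hz = 1000,
                        onerm_factor = 1.2) {
  if (n_per_group < 1 || trials < 1) {
    stop_squatmech("n_per_group and trials must be >= 1", "invalid_spec")
  }
  eff <- list(hip_flexion_deg = 8, knee_flexion_deg = 10,
              dorsiflexion_deg = 4, knee_adduction_deg = 4,
              knee_adduction_moment_nm_kg = 0.12)
  eff[names(effects)] <- effects
  nz <- list(marker_sd_m = 0.003, grf_sd_n = 5, emg_noise = 0.05)
  nz[names(noise)] <- noise
  if (any(unlist(nz) < 0)) {
    stop_squatmech("noise SDs must be non-negative", "invalid_spec")
  }
  structure(list(n_per_group = n_per_group, loads = loads, trials = trials,
                 effects = eff, noise = nz, seed = as.integer(seed),
                 duration_s = duration_s, marker_rate_hz = marker_rate_hz,
                 emg_rate_hz = emg_rate_hz, onerm_factor = onerm_factor),
            class = "cohort_spec")
}

.rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  for (k in 1:20) {
    bad <- x < lo | x > hi
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

#' Draw a synthetic participant
#'
#' Mass and height are drawn around the cohort means (65.67 kg, 1.72 m);
#' the static valgus angle is uniform on (6, 30) degrees for the valgus
#' group and on (0, 5) for the normal group; 1RM defaults to 1.2 x body
#' mass.  Hidden per-segment length multipliers (SD 3%) are the
#' anthropometric ground truth the scaling step must recover.
#'
#' @param group `"valgus"` or `"normal"`.
#' @param seed Integer seed (same group and seed give an identical
#'   participant).
#' @param id Participant id string.
#' @param spec A `cohort_spec` (for the 1RM factor).
#' @return A `squat_participant`.
#' @export
generate_participant <- function(group, seed, id = NULL,
                                 spec = cohort_spec()) {
  if (!group %in% c("valgus", "normal")) {
    stop_squatmech(sprintf("unknown group label '%s'", group),
                   "invalid_group")
  }
  with_seed(derive_seed(seed, 101L), {
    mass <- .rnorm_trunc(1, 65.67, 11.38, 42, 95)
    height <- .rnorm_trunc(1, 1.72, 0.07, 1.52, 1.92)
    valgus <- if (group == "valgus") stats::runif(1, 6, 30) else
      stats::runif(1, 0, 5)
    scales <- .rnorm_trunc(4, 1, 0.03, 0.92, 1.08)
    p <- participant(id %||% sprintf("%s_%d", group, seed %% 1000L),
                     mass, height, valgus,
                     spec$onerm_factor * mass,
                     segment_scales = stats::setNames(
                       scales, c("foot", "shank", "thigh", "pelvis")))
    p$seed <- as.integer(seed)
    p
  })
}

#' Build the participant's true (generating) model
#'
#' The default anthropometric model with the participant's hidden
#' per-segment scale multipliers applied; marked scaled.  This is the
#' model the generator uses for forward kinematics and ground truth.
#'
#' @param p A `squat_participant`.
#' @return A scaled `squat_model`.
#' @export
build_true_model <- function(p) {
  m <- build_default_model(p)
  m <- apply_segment_scales(m, as.list(p$segment_scales))
  m$scaled <- TRUE
  m
}

# Per-participant kinematic template parameters: base peaks for the
# normal group plus between-participant variability; valgus-group
# effects are added on top.  Drawn once per participant (stable across
# loads and trials).
.template_params <- function(p, spec) {
  eff <- spec$effects
  with_seed(derive_seed(p$seed %||% 0L, 202L), {
    v <- p$group == "valgus"
    list(
      knee_flexion = stats::rnorm(1, 134, 5) +
        if (v) eff$knee_flexion_deg else 0,
      hip_flexion = stats::rnorm(1, 92, 6) +
        if (v) eff$hip_flexion_deg else 0,
      ankle_dorsiflexion = stats::rnorm(1, 34, 2) +
        if (v) eff$dorsiflexion_deg else 0,
      hip_adduction = stats::rnorm(1, -12, 2),
      knee_adduction = stats::rnorm(1, 3, 2) +
        if (v) eff$knee_adduction_deg else 0,
      knee_add_wobble = stats::rnorm(1, 6, 1.5),
      knee_rotation = stats::rnorm(1, -12, 4),
      hip_rotation = stats::rnorm(1, 18, 6),
      subtalar_amp = stats::rnorm(1, 8, 3),
      kam_nm_kg = stats::rnorm(1, 0.21, 0.04) +
        if (v) eff$knee_adduction_moment_nm_kg else 0
    )
  })
}

# Joint-angle template for one trial: raised-cosine profile (smooth,
# zero end velocity) from upright to deepest and back, with small
# per-trial peak jitter.  Returns frames x 8 degrees with rate attr.
squat_angle_template <- function(p, spec, trial_seed) {
  tp <- .template_params(p, spec)
  n <- round(spec$duration_s * spec$marker_rate_hz) + 1L
  t <- seq(0, spec$duration_s, length.out = n)
  phi <- (1 - cos(2 * pi * t / spec$duration_s)) / 2
  jit <- with_seed(derive_seed(trial_seed, 303L),
                   stats::rnorm(8, 0, c(1, 1, 1, 0.5, 1, 0.5, 1, 0.5)))
  Q <- cbind(
    subtalar_supination = -(p$valgus_deg + (tp$subtalar_amp + jit[1]) * phi),
    ankle_dorsiflexion = (tp$ankle_dorsiflexion + jit[2]) * phi,
    knee_flexion = (tp$knee_flexion + jit[3]) * phi,
    knee_adduction = (tp$knee_adduction + jit[4]) * phi +
      tp$knee_add_wobble * sin(2 * pi * t / spec$duration_s),
    knee_rotation = (tp$knee_rotation + jit[5]) * phi,
    hip_flexion = (tp$hip_flexion + jit[6]) * phi,
    hip_adduction = (tp$hip_adduction + jit[7]) * phi,
    hip_rotation = (tp$hip_rotation + jit[8]) * phi
  )
  attr(Q, "rate_hz") <- spec$marker_rate_hz
  attr(Q, "kam_nm_kg") <- tp$kam_nm_kg
  Q
}

# Ground reaction for a template.  Forces are the routed share of
# whole-system momentum (so the vertical impulse balances over the
# cycle); the anterior COP follows the zero-moment point clamped inside
# the foot support; the lateral COP starts on the foot midline (the
# contralateral leg, not modeled, balances the frontal plane) and is
# shifted afterwards to inject the target external knee adduction
# moment.
.grf_from_template <- function(model, angles, barbell_kg) {
  rate <- attr(angles, "rate_hz")
  dt <- 1 / rate
  ck <- chain_kinematics(model, angles)
  share <- model$weight_share
  segs <- model$segments
  g <- model$gravity
  pts <- list(foot = ck$com$foot, shank = ck$com$shank,
              thigh = ck$com$thigh, pelvis = ck$com$pelvis,
              barbell = ck$barbell)
  ms <- c(foot = segs$foot$mass, shank = segs$shank$mass,
          thigh = segs$thigh$mass, pelvis = share * segs$pelvis$mass,
          barbell = share * barbell_kg)
  n <- ck$n
  F <- matrix(0, n, 3)
  for (s in names(pts)) {
    a <- .traj_deriv(.traj_deriv(pts[[s]], dt), dt)
    fi <- ms[[s]] * sweep(a, 2, c(0, -g, 0), `-`)
    F <- F + fi
  }
  lf <- segs$foot$length
  # anterior COP progression: weight sits slightly behind the ankle near
  # upright (dorsiflexor demand) and rolls onto the forefoot at depth
  phi_x <- (1 - cos(2 * pi * seq(0, 1, length.out = n))) / 2
  copx <- lf * (-0.08 + 0.30 * phi_x)
  data.frame(time = seq(0, by = dt, length.out = n),
             fx = F[, 1], fy = F[, 2], fz = 0,
             copx = copx, copy = 0, copz = 0)
}

# Set the lateral COP so the trial's external knee adduction moment
# curve equals kam * phi (raised-cosine profile).  The moment is linear
# in copz, so one baseline inverse-dynamics pass plus one perturbed pass
# (finite-difference sensitivity) places it exactly.
.inject_kam <- function(model, angles, grf, barbell_kg, kam_nm_kg) {
  n <- nrow(grf)
  id0 <- inverse_dynamics(model, angles, grf, barbell_kg,
                          filter_cutoff_hz = NA)
  grf1 <- grf
  grf1$copz <- 0.01
  id1 <- inverse_dynamics(model, angles, grf1, barbell_kg,
                          filter_cutoff_hz = NA)
  m0 <- -id0$moments[, "knee_adduction"]
  sens <- (-id1$moments[, "knee_adduction"] - m0) / 0.01
  phi <- (1 - cos(2 * pi * seq(0, 1, length.out = n))) / 2
  m_sys <- model$participant$mass_kg + barbell_kg
  grf$copz <- (kam_nm_kg * m_sys * phi - m0) / sens
  grf
}

# Band-limited (100-450 Hz) unit-variance carrier used for EMG synthesis.
.emg_carrier <- function(n, rate) {
  x <- stats::rnorm(n + 400)
  bf <- signal::butter(2, c(100, 450) / (rate / 2), type = "pass")
  y <- as.numeric(signal::filtfilt(bf, x))[201:(200 + n)]
  y / stats::sd(y)
}

#' Generate one synthetic squat trial with ground truth
#'
#' Markers are forward kinematics of a smooth upright-deepest-upright
#' joint-angle template plus Gaussian noise; the ground reaction is the
#' routed share of body+barbell weight plus the inertial term implied by
#' the template (so inverse dynamics can recover the generating
#' torques); EMG channels are band-limited noise amplitude-modulated by
#' the generating activations, with an MVC reference bout attached.
#'
#' @param p A `squat_participant`.
#' @param load A load condition from [load_condition()].
#' @param model The participant's true scaled model
#'   ([build_true_model()]).
#' @param spec A `cohort_spec`.
#' @param seed Integer trial seed.
#' @return A `squat_trial`: `markers` (named list of frames x 3), `grf`,
#'   `emg`, `mvc`, rates, `load`, `participant_id`, and `ground_truth`
#'   (true angles, raw moments, activations, clean GRF).
#' @export
generate_squat_trial <- function(p, load, model, spec = cohort_spec(),
                                 seed = 1) {
  if (!isTRUE(model$scaled)) {
    stop_squatmech("generating model must be scaled to the participant",
                   "unscaled_model")
  }
  angles <- squat_angle_template(p, spec, seed)
  grf <- .grf_from_template(model, angles, load$barbell_kg)
  grf <- .inject_kam(model, angles, grf, load$barbell_kg,
                     attr(angles, "kam_nm_kg"))
  id_true <- inverse_dynamics(model, angles, grf, load$barbell_kg,
                              filter_cutoff_hz = NA)
  so_true <- static_optimization(model, id_true$moments, angles)

  n <- nrow(angles)
  rate <- spec$marker_rate_hz
  ck <- chain_kinematics(model, angles)
  marker_names <- names(model$markers)
  trial_rng <- derive_seed(seed, 404L)
  markers <- with_seed(trial_rng, {
    mk <- lapply(marker_names, function(nm) matrix(0, n, 3))
    names(mk) <- marker_names
    for (f in seq_len(n)) {
      Rl <- lapply(ck$R, function(a) a[, , f])
      origins <- list(foot = c(0, 0, 0), calcaneus = c(0, 0, 0),
                      shank = ck$joints$ankle[f, ],
                      thigh = ck$joints$knee[f, ],
                      pelvis = ck$joints$hip[f, ])
      pm <- predict_markers(model, Rl, origins)
      for (nm in marker_names) mk[[nm]][f, ] <- pm[nm, ]
    }
    if (spec$noise$marker_sd_m > 0) {
      for (nm in marker_names) {
        mk[[nm]] <- mk[[nm]] +
          matrix(stats::rnorm(3 * n, 0, spec$noise$marker_sd_m), n, 3)
      }
    }
    mk
  })

  grf_noisy <- grf
  if (spec$noise$grf_sd_n > 0) {
    grf_noisy[, c("fx", "fy", "fz")] <- grf[, c("fx", "fy", "fz")] +
      with_seed(derive_seed(seed, 505L),
                matrix(stats::rnorm(3 * n, 0, spec$noise$grf_sd_n), n, 3))
  }

  emg_muscles <- c("rectus_femoris", "biceps_femoris",
                   "tibialis_anterior", "gastrocnemius")
  n_emg <- round(spec$duration_s * spec$emg_rate_hz) + 1L
  t_emg <- seq(0, spec$duration_s, length.out = n_emg)
  t_mk <- seq(0, spec$duration_s, length.out = n)
  emg <- with_seed(derive_seed(seed, 606L), {
    out <- data.frame(time = t_emg)
    for (mu in emg_muscles) {
      act <- stats::approx(t_mk, so_true$activations[, mu], xout = t_emg)$y
      carrier <- .emg_carrier(n_emg, spec$emg_rate_hz)
      floorn <- .emg_carrier(n_emg, spec$emg_rate_hz)
      out[[mu]] <- act * carrier + spec$noise$emg_noise * floorn
    }
    out
  })
  mvc <- with_seed(derive_seed(seed, 707L), {
    v <- lapply(emg_muscles, function(mu) .emg_carrier(spec$emg_rate_hz,
                                                       spec$emg_rate_hz))
    names(v) <- emg_muscles
    v
  })

  structure(list(
    markers = markers, marker_rate = rate,
    grf = grf_noisy, grf_rate = rate,
    emg = emg, emg_rate = spec$emg_rate_hz,
    mvc = mvc,
    load = load, participant_id = p$id,
    ground_truth = list(angles = angles, moments = id_true$moments,
                        activations = so_true$activations,
                        grf = grf)
  ), class = "squat_trial")
}

#' Generate a static (upright standing) trial
#'
#' Used for model scaling: the participant stands with all joints
#' neutral except the subtalar, which holds the static valgus angle.
#'
#' @inheritParams generate_squat_trial
#' @param duration_s Trial length, default 1 s.
#' @return A `squat_trial` with markers only (plus a quasi-static GRF).
#' @export
generate_static_trial <- function(p, model, spec = cohort_spec(),
                                  seed = 1, duration_s = 1) {
  n <- round(duration_s * spec$marker_rate_hz) + 1L
  q0 <- stats::setNames(numeric(8), model$dofs)
  q0["subtalar_supination"] <- -p$valgus_deg
  fk <- fk_pose(model, q0)
  marker_names <- rownames(fk$markers)
  markers <- with_seed(derive_seed(seed, 808L), {
    mk <- lapply(marker_names, function(nm) {
      base <- matrix(fk$markers[nm, ], n, 3, byrow = TRUE)
      if (spec$noise$marker_sd_m > 0) {
        base <- base + matrix(stats::rnorm(3 * n, 0, spec$noise$marker_sd_m),
                              n, 3)
      }
      base
    })
    names(mk) <- marker_names
    mk
  })
  share_w <- model$weight_share *
    model$segments$pelvis$mass + model$segments$foot$mass +
    model$segments$shank$mass + model$segments$thigh$mass
  grf <- data.frame(time = seq(0, by = 1 / spec$marker_rate_hz,
                               length.out = n),
                    fx = 0, fy = share_w * model$gravity, fz = 0,
                    copx = 0, copy = 0, copz = 0)
  structure(list(markers = markers, marker_rate = spec$marker_rate_hz,
                 grf = grf, grf_rate = spec$marker_rate_hz,
                 emg = NULL, emg_rate = NA, mvc = NULL,
                 load = load_condition(0, p$onerm_kg),
                 participant_id = p$id,
                 ground_truth = list(pose = q0)),
            class = "squat_trial")
}

#' Generate a synthetic cohort on disk
#'
#' Writes one TRC marker file, one GRF CSV and one EMG CSV per dynamic
#' trial, a static TRC per participant, and a JSON manifest.  The same
#' spec (including seed) produces a byte-identical manifest.
#'
#' @param spec A `cohort_spec`.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
generate_cohort <- function(spec, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE,
                                      showWarnings = FALSE)
  if (!ok || file.access(dir, 2) != 0) {
    stop_squatmech(sprintf("cannot write to directory '%s'", dir),
                   "io_error")
  }
  rows <- list()
  for (gi in seq_along(c("valgus", "normal"))) {
    group <- c("valgus", "normal")[gi]
    for (i in seq_len(spec$n_per_group)) {
      pseed <- derive_seed(spec$seed, gi, i)
      p <- generate_participant(group, pseed,
                                id = sprintf("%s%02d", toupper(substr(group, 1, 1)), i),
                                spec = spec)
      model <- build_true_model(p)
      st <- generate_static_trial(p, model, spec,
                                  seed = derive_seed(pseed, 9L))
      static_file <- sprintf("%s_static.trc", p$id)
      write_trc(st$markers, st$marker_rate, file.path(dir, static_file))
      for (li in seq_along(spec$loads)) {
        load <- load_condition(spec$loads[li], p$onerm_kg)
        for (tr in seq_len(spec$trials)) {
          trial <- generate_squat_trial(p, load, model, spec,
                                        seed = derive_seed(pseed, li, tr))
          stem <- sprintf("%s_L%02.0f_T%d", p$id, 100 * load$fraction, tr)
          write_trc(trial$markers, trial$marker_rate,
                    file.path(dir, paste0(stem, ".trc")))
          utils::write.csv(trial$grf, file.path(dir, paste0(stem, "_grf.csv")),
                           row.names = FALSE)
          utils::write.csv(trial$emg, file.path(dir, paste0(stem, "_emg.csv")),
                           row.names = FALSE)
          rows[[length(rows) + 1L]] <- data.frame(
            participant = p$id, group = group, mass_kg = p$mass_kg,
            height_m = p$height_m, valgus_deg = p$valgus_deg,
            onerm_kg = p$onerm_kg, load = load$fraction, trial = tr,
            trc = paste0(stem, ".trc"), grf = paste0(stem, "_grf.csv"),
            emg = paste0(stem, "_emg.csv"), static_trc = static_file,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(list(seed = spec$seed,
                            n_per_group = spec$n_per_group,
                            loads = spec$loads, trials = spec$trials,
                            trials_table = manifest),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Write marker trajectories as TRC
#'
#' @param markers Named list of frames x 3 matrices (meters).
#' @param rate_hz Capture rate.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trc <- function(markers, rate_hz, path) {
  nm <- names(markers)
  n <- nrow(markers[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    sprintf("%g\t%g\t%d\t%d\tm\t%g\t1\t%d", rate_hz, rate_hz, n,
            length(nm), rate_hz, n),
    paste(c("Frame#", "Time", as.vector(rbind(nm, "", ""))), collapse = "\t"),
    paste(c("", "", paste0(rep(c("X", "Y", "Z"), length(nm)),
                           rep(seq_along(nm), each = 3))), collapse = "\t")
  ), con)
  dat <- do.call(cbind, markers)
  tm <- seq(0, by = 1 / rate_hz, length.out = n)
  body <- cbind(seq_len(n), format(tm, trim = TRUE),
                format(dat, trim = TRUE, digits = 8))
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a TRC marker file
#'
#' @param path TRC file path.
#' @return Named list of frames x 3 marker matrices with attribute
#'   `rate_hz`.
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  meta <- strsplit(lines[3], "\t")[[1]]
  rate <- as.numeric(meta[1])
  nmk <- as.integer(meta[4])
  header <- strsplit(lines[4], "\t")[[1]]
  nm <- header[seq(3, by = 3, length.out = nmk)]
  dat <- utils::read.table(text = lines[-(1:5)], sep = "\t")
  out <- lapply(seq_len(nmk), function(i) {
    as.matrix(dat[, (3 * i):(3 * i + 2)])
  })
  names(out) <- nm
  out <- lapply(out, function(m) {
    dimnames(m) <- list(NULL, c("x", "y", "z")); m
  })
  attr(out, "rate_hz") <- rate
  out
}
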