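# Tibiofemoral compressive contact force and its medial/lateral split by
# frontal-plane static moment balance at contact points located 25% of
# the tibial plateau width either side of the knee center.

#' Total tibiofemoral compressive force
#'
#' Axial (tibia long-axis) joint reaction: the compressive component of
#' the intersegmental knee force from inverse dynamics plus the axial
#' pull of every muscle crossing the knee (rigid-tendon forces from the
#' static-optimization solution, assumed to act along the tibial axis).
#' Reported compressive-positive.
#'
#' @param model A `squat_model`.
#' @param id A `squat_id` from [inverse_dynamics()].
#' @param activations An `activation_solution` from
#'   [static_optimization()].
#' @return Numeric vector (frames) of total compressive force, N.
#' @export
total_knee_contact <- function(model, id, activations) {
  if (!inherits(activations, "activation_solution")) {
    stop_squatmech("an activation_solution is required", "missing_activations")
  }
  axial <- -rowSums(id$joint_forces$knee * id$shank_axis)
  crossing <- names(model$muscles)[vapply(model$muscles,
                                          function(m) isTRUE(m$crosses_knee),
                                          logical(1))]
  # per-muscle axial factor: fraction of the muscle force aligned with
  # the tibial long axis (line-of-action obliquity), default 1
  fac <- vapply(crossing,
                function(mu) model$muscles[[mu]]$knee_axial %||% 1,
                numeric(1))
  muscle <- as.numeric(activations$forces[, crossing, drop = FALSE] %*% fac)
  pmax(axial + muscle, 0)
}

#' Net frontal-plane moment about the knee center
#'
#' Aggregates the external knee ab/adduction moment (the negative of the
#' internal inverse-dynamics moment) and the frontal moments of all
#' knee-spanning muscles (force times frontal moment arm),
#' adduction-positive.  This is the moment the contact-force asymmetry
#' must balance.
#'
#' @inheritParams total_knee_contact
#' @param poses Frames x 8 matrix of joint angles (degrees).
#' @return Numeric vector (frames) of frontal moment, N m.
#' @export
knee_frontal_moment <- function(model, id, activations, poses) {
  M <- -id$moments[, "knee_adduction"]
  for (mus in names(model$muscles)) {
    if (is.null(model$muscles[[mus]]$arms[["knee_adduction"]])) next
    arms <- vapply(seq_len(nrow(poses)), function(f) {
      moment_arm(model, mus, "knee_adduction", poses[f, ])
    }, numeric(1))
    M <- M + activations$forces[, mus] * arms
  }
  M
}

#' Split total knee contact force into medial and lateral components
#'
#' Contact points sit at +/- d from the knee center with d = 25% of the
#' tibial plateau width.  Per sample, solves the 2 x 2 static balance
#' F_med + F_lat = F_tot and (F_med - F_lat) d = M_frontal.  A negative
#' solution (condylar lift-off) is clamped to zero with the other side
#' carrying the whole load and a lift-off flag raised.
#'
#' @param f_total Total compressive force, N (>= 0), vectorized.
#' @param m_frontal Net frontal-plane moment about the knee center, N m,
#'   adduction-positive.
#' @param width_m Tibial plateau width, m (> 0).
#' @return List: `medial`, `lateral` (N), `liftoff` (logical), `d_m`.
#' @export
decompose_medial_lateral <- function(f_total, m_frontal, width_m) {
  if (!is.finite(width_m) || width_m <= 0) {
    stop_squatmech("tibial width must be positive", "invalid_width")
  }
  d <- 0.25 * width_m
  med <- f_total / 2 + m_frontal / (2 * d)
  lat <- f_total - med
  liftoff <- med < 0 | lat < 0
  med_c <- pmin(pmax(med, 0), f_total)
  lat_c <- f_total - med_c
  list(medial = med_c, lateral = lat_c, liftoff = liftoff, d_m = d)
}

#' Contact-force curves for one trial
#'
#' Convenience wrapper producing total/medial/lateral series in raw N and
#' normalized N/kg (per kg of body + barbell mass).
#'
#' @inheritParams knee_frontal_moment
#' @param barbell_kg Barbell mass (kg) for normalization.
#' @return Matrix (frames x 3: total, medial, lateral) in N with
#'   attributes `normalized` (same, N/kg), `liftoff`, `d_m`.
#' @export
contact_force_curves <- function(model, id, activations, poses,
                                 barbell_kg = 0) {
  f_tot <- total_knee_contact(model, id, activations)
  m_fr <- knee_frontal_moment(model, id, activations, poses)
  dec <- decompose_medial_lateral(f_tot, m_fr, model$tibial_plateau_width)
  raw <- cbind(total = f_tot, medial = dec$medial, lateral = dec$lateral)
  norm <- normalize_load(raw, model$participant$mass_kg, barbell_kg)
  attr(raw, "normalized") <- norm
  attr(raw, "liftoff") <- dec$liftoff
  attr(raw, "d_m") <- dec$d_m
  raw
}

#' Peak knee contact forces
#'
#' @param curves 101 x k matrix of normalized contact forces (N/kg) with
#'   columns including `total` and `medial`.
#' @return Named vector: `total_contact_peak`, `medial_contact_peak`.
#' @export
peak_contact_forces <- function(curves) {
  c(total_contact_peak = max(curves[, "total"]),
    medial_contact_peak = max(curves[, "medial"]))
}
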