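# Reduced right-leg rigid-body model: segments, joints, sign conventions,
# muscle elements and the marker placement map.  Everything downstream
# (IK, ID, static optimization, contact decomposition) consumes this.

# Degree-of-freedom order used throughout the package.  Values are stored
# in *convention-positive* degrees: flexion (+) / extension (-),
# adduction (+) / abduction (-), dorsiflexion (+) / plantarflexion (-),
# supination (+) / valgus (-).
.squat_dofs <- c("subtalar_supination", "ankle_dorsiflexion",
                 "knee_flexion", "knee_adduction", "knee_rotation",
                 "hip_flexion", "hip_adduction", "hip_rotation")

# Mechanical realization of each DOF in the kinematic chain rooted at the
# planted foot: rotation axis (x anterior, y up, z lateral-right) and the
# sign multiplier mapping convention-positive angles to rotations about
# that axis for the right leg.
.dof_axis <- c(subtalar_supination = "x", ankle_dorsiflexion = "z",
               knee_flexion = "z", knee_adduction = "x", knee_rotation = "y",
               hip_flexion = "z", hip_adduction = "x", hip_rotation = "y")
.dof_mech_sign <- c(subtalar_supination = 1, ankle_dorsiflexion = -1,
                    knee_flexion = 1, knee_adduction = 1, knee_rotation = 1,
                    hip_flexion = -1, hip_adduction = 1, hip_rotation = 1)

#' Joint sign conventions
#'
#' Returns the fixed per-DOF sign map used by every stage of the
#' pipeline: flexion (+)/extension (-), adduction (+)/abduction (-),
#' dorsiflexion (+)/plantarflexion (-), supination (+)/valgus (-).
#'
#' @return A data.frame with columns `dof`, `positive`, `negative`.
#' @export
sign_convention <- function() {
  data.frame(
    dof = .squat_dofs,
    positive = c("supination", "dorsiflexion", "flexion", "adduction",
                 "internal rotation", "flexion", "adduction",
                 "internal rotation"),
    negative = c("valgus", "plantarflexion", "extension", "abduction",
                 "external rotation", "extension", "abduction",
                 "external rotation"),
    stringsAsFactors = FALSE
  )
}

#' Create a participant record
#'
#' @param id Character id.
#' @param mass_kg Body mass in kg (> 0).
#' @param height_m Standing height in m (> 0).
#' @param valgus_deg Static rearfoot valgus angle in degrees, in
#'   \[0, 30\] (the cohort is restricted to mild valgus).
#' @param onerm_kg Back-squat one-repetition maximum in kg (> 0).
#' @param segment_scales Optional named numeric vector of per-segment
#'   length multipliers (`foot`, `shank`, `thigh`, `pelvis`).  Used by the
#'   synthetic generator as the ground-truth anthropometric deviation the
#'   scaling step must recover; defaults to all 1.
#' @return An object of class `squat_participant`.  The group label is
#'   derived from the 5 degree static-valgus cutoff.
#' @export
participant <- function(id, mass_kg, height_m, valgus_deg, onerm_kg,
                        segment_scales = NULL) {
  if (!is.finite(mass_kg) || mass_kg <= 0 ||
      !is.finite(height_m) || height_m <= 0) {
    stop_squatmech("participant mass and height must be positive",
                   "invalid_participant")
  }
  if (!is.finite(onerm_kg) || onerm_kg <= 0) {
    stop_squatmech("participant 1RM must be positive", "invalid_participant")
  }
  if (!is.finite(valgus_deg) || valgus_deg < 0 || valgus_deg > 30) {
    stop_squatmech("static rearfoot valgus angle must lie in [0, 30] degrees",
                   "invalid_participant")
  }
  scales <- c(foot = 1, shank = 1, thigh = 1, pelvis = 1)
  if (!is.null(segment_scales)) scales[names(segment_scales)] <- segment_scales
  structure(list(id = as.character(id), mass_kg = mass_kg,
                 height_m = height_m, valgus_deg = valgus_deg,
                 onerm_kg = onerm_kg,
                 group = classify_foot_posture(valgus_deg),
                 segment_scales = scales),
            class = "squat_participant")
}

#' Enumerate a study load condition
#'
#' @param fraction Fraction of the 1RM on the bar; one of 0, 0.3, 0.7.
#' @param onerm_kg The participant's 1RM in kg.
#' @return List with `fraction` and `barbell_kg`.
#' @export
load_condition <- function(fraction, onerm_kg) {
  if (!fraction %in% c(0, 0.3, 0.7)) {
    stop_squatmech("load fraction must be one of 0, 0.3, 0.7",
                   "invalid_load")
  }
  list(fraction = fraction, barbell_kg = fraction * onerm_kg)
}

# Default muscle set.  Moment arms are explicit signed polynomials in the
# spanned DOF's convention angle in degrees (meters); coefficient order is
# ascending (c0 + c1*theta + ...).  Fmax in N.  `crosses_knee` marks
# elements whose force contributes axial tibiofemoral compression.
.default_muscles <- function() {
  list(
    rectus_femoris = list(
      fmax = 1200, crosses_knee = TRUE, knee_axial = 0.45,
      arms = list(knee_flexion = c(-0.040, -5e-5),
                  knee_adduction = c(-0.004))),
    vasti = list(
      fmax = 7000, crosses_knee = TRUE, knee_axial = 0.45,
      # the frontal arm is an effective lateral-structure arm (vasti +
      # iliotibial tract) giving the lateral compartment its deep-squat
      # dominance in the contact decomposition
      arms = list(knee_flexion = c(-0.042), knee_adduction = c(-0.012))),
    biceps_femoris = list(
      fmax = 800, crosses_knee = TRUE, knee_axial = 0.45,
      arms = list(knee_flexion = c(0.035), hip_flexion = c(-0.055),
                  knee_adduction = c(-0.006))),
    gluteus = list(
      fmax = 3000, crosses_knee = FALSE,
      arms = list(hip_flexion = c(-0.060), hip_adduction = c(-0.045),
                  hip_rotation = c(-0.020))),
    adductors = list(
      fmax = 1200, crosses_knee = FALSE,
      arms = list(hip_adduction = c(0.035), hip_flexion = c(0.010))),
    tibialis_anterior = list(
      fmax = 900, crosses_knee = FALSE,
      arms = list(ankle_dorsiflexion = c(0.033))),
    gastrocnemius = list(
      fmax = 1500, crosses_knee = TRUE, knee_axial = 0.45,
      arms = list(ankle_dorsiflexion = c(-0.048),
                  knee_adduction = c(-0.008))),
    soleus = list(
      fmax = 3500, crosses_knee = FALSE,
      arms = list(ankle_dorsiflexion = c(-0.038))),
    peroneus = list(
      fmax = 1200, crosses_knee = FALSE,
      arms = list(subtalar_supination = c(-0.035))),
    hip_rotators = list(
      fmax = 400, crosses_knee = FALSE,
      arms = list(hip_rotation = c(0.025)))
  )
}

# Marker placement map as a function of segment dimensions.  Offsets are
# local coordinates (m) in each segment frame: foot origin on the ground
# under the ankle, shank origin at the ankle center, thigh origin at the
# knee center, pelvis origin at the right hip center.  The heel markers
# sit on the calcaneus sub-frame, which rolls with the subtalar angle
# about the anterior axis while the forefoot stays planted -- that roll
# is what the rearfoot valgus angle measures.
.default_markers <- function(lf, ls, lt, height) {
  h <- height / 1.72  # transverse offsets scale mildly with stature
  list(
    RHEE = list(segment = "calcaneus", offset = c(-0.25 * lf, 0.03, 0)),
    RCAL = list(segment = "calcaneus", offset = c(-0.27 * lf, 0.09, 0.01)),
    RTOE = list(segment = "foot",  offset = c(0.72 * lf, 0.02, 0.01)),
    RMT5 = list(segment = "foot",  offset = c(0.45 * lf, 0.02, 0.05 * h)),
    RANK = list(segment = "shank", offset = c(0.00, 0.02, 0.045 * h)),
    RMMA = list(segment = "shank", offset = c(0.00, 0.03, -0.040 * h)),
    RTIB = list(segment = "shank", offset = c(0.02, 0.42 * ls, 0.040 * h)),
    RSHN = list(segment = "shank", offset = c(0.03, 0.66 * ls, 0.010 * h)),
    RKNE = list(segment = "thigh", offset = c(0.00, 0.02 * lt, 0.055 * h)),
    RMKN = list(segment = "thigh", offset = c(0.00, 0.03 * lt, -0.050 * h)),
    RTHI = list(segment = "thigh", offset = c(0.02, 0.45 * lt, 0.050 * h)),
    RTHF = list(segment = "thigh", offset = c(0.05, 0.70 * lt, 0.000)),
    RASI = list(segment = "pelvis", offset = c(0.06, 0.10, 0.02)),
    LASI = list(segment = "pelvis", offset = c(0.06, 0.10, -0.20 * h)),
    SACR = list(segment = "pelvis", offset = c(-0.10, 0.12, -0.09 * h)),
    TRNK = list(segment = "pelvis", offset = c(-0.04, 0.40 * height * 0.3,
                                               -0.09 * h))
  )
}

#' Build the default scaled-to-participant body model
#'
#' Segment masses, lengths and inertial parameters follow published
#' anthropometric fractions of body mass and stature (de Leva-style).
#' The pelvis+HAT segment aggregates pelvis, trunk, head, arms and the
#' contralateral limb; its gravity (and the barbell's) is routed to the
#' modeled leg through `weight_share`.
#'
#' @param p A `squat_participant`.
#' @param tibial_width_m Tibial plateau width in m; default 0.08 scaled
#'   with stature.  Sets the contact-point offset (25% of width) used by
#'   the medial/lateral decomposition.
#' @param weight_share Fraction of HAT+barbell weight carried by the
#'   modeled (force-plate) leg; default 0.5 by bilateral symmetry.
#' @return An object of class `squat_model` (unscaled: `scaled = FALSE`).
#' @export
build_default_model <- function(p, tibial_width_m = NULL,
                                weight_share = 0.5) {
  if (!inherits(p, "squat_participant")) {
    stop_squatmech("p must be a squat_participant", "invalid_participant")
  }
  H <- p$height_m
  M <- p$mass_kg
  lf <- 0.152 * H
  ls <- 0.246 * H
  lt <- 0.245 * H
  hat_len <- 0.47 * H
  segs <- list(
    foot = list(mass = 0.0137 * M, length = lf, com_frac = 0.5,
                ankle_height = 0.039 * H,
                com_local = c(0.19 * lf, 0.5 * 0.039 * H, 0)),
    shank = list(mass = 0.0433 * M, length = ls, com_frac = 0.433,
                 com_local = c(0, (1 - 0.433) * ls, 0)),
    thigh = list(mass = 0.1416 * M, length = lt, com_frac = 0.433,
                 com_local = c(0, (1 - 0.433) * lt, 0)),
    pelvis = list(mass = (1 - 0.0137 - 0.0433 - 0.1416) * M,
                  length = hat_len, com_frac = 0.36,
                  com_local = c(0, 0.30 * H, 0))
  )
  for (s in names(segs)) {
    It <- segs[[s]]$mass * (0.3 * segs[[s]]$length)^2
    segs[[s]]$inertia <- c(x = It, y = 0.3 * It, z = It)
  }
  model <- structure(list(
    participant = p,
    segments = segs,
    dofs = .squat_dofs,
    dof_axis = .dof_axis,
    dof_mech_sign = .dof_mech_sign,
    muscles = .default_muscles(),
    markers = .default_markers(lf, ls, lt, H),
    tibial_plateau_width = tibial_width_m %||% (0.08 * H / 1.72),
    barbell_height = 0.35 * H,   # above hip, along the trunk axis
    # DOFs whose net moment is distributed among muscles by static
    # optimization; the knee frontal/transverse moments are carried by
    # articular contact and passive structures (that asymmetry is what
    # the medial/lateral decomposition resolves), not by recruitment.
    muscle_balance_dofs = setdiff(.squat_dofs,
                                  c("knee_adduction", "knee_rotation")),
    weight_share = weight_share,
    gravity = 9.81,
    scaled = FALSE,
    scale_factors = c(foot = 1, shank = 1, thigh = 1, pelvis = 1)
  ), class = "squat_model")
  model
}

#' Total segment mass of a model
#' @param model A `squat_model`.
#' @return Sum of segment masses in kg.
#' @export
model_total_mass <- function(model) {
  sum(vapply(model$segments, function(s) s$mass, numeric(1)))
}

# Apply per-segment geometric scale factors: segment lengths, local
# marker/COM offsets and inertias (masses are anthropometric fractions of
# body mass and do not change).
apply_segment_scales <- function(model, factors) {
  stopifnot(all(names(model$segments) %in% names(factors)))
  for (s in names(model$segments)) {
    f <- factors[[s]]
    model$segments[[s]]$length <- model$segments[[s]]$length * f
    model$segments[[s]]$com_local <- model$segments[[s]]$com_local * f
    if (!is.null(model$segments[[s]]$ankle_height)) {
      model$segments[[s]]$ankle_height <- model$segments[[s]]$ankle_height * f
    }
    model$segments[[s]]$inertia <- model$segments[[s]]$inertia * f^2
  }
  for (m in names(model$markers)) {
    seg <- model$markers[[m]]$segment
    if (seg == "calcaneus") seg <- "foot"  # heel scales with the foot
    model$markers[[m]]$offset <- model$markers[[m]]$offset * factors[[seg]]
  }
  model$barbell_height <- model$barbell_height * factors[["pelvis"]]
  model$scale_factors <- model$scale_factors *
    unlist(factors)[names(model$scale_factors)]
  model
}

#' Signed moment arm of a muscle about a DOF
#'
#' Arms are explicit low-order polynomials in the spanned DOF's
#' convention-positive angle (degrees); a muscle producing a
#' flexion-direction moment has a positive arm on a flexion DOF.
#'
#' @param model A `squat_model`.
#' @param muscle Muscle name.
#' @param dof DOF name (see [sign_convention()]).
#' @param pose Named numeric of joint angles in degrees; only the entry
#'   for `dof` is consulted (missing entries are treated as 0).
#' @return Signed arm in meters; 0 if the muscle does not act on `dof`.
#' @export
moment_arm <- function(model, muscle, dof, pose = NULL) {
  if (!muscle %in% names(model$muscles)) {
    stop_squatmech(sprintf("unknown muscle '%s'", muscle), "lookup_error")
  }
  if (!dof %in% model$dofs) {
    stop_squatmech(sprintf("unknown dof '%s'", dof), "lookup_error")
  }
  coefs <- model$muscles[[muscle]]$arms[[dof]]
  if (is.null(coefs)) return(0)
  theta <- if (!is.null(pose) && dof %in% names(pose)) pose[[dof]] else 0
  polyval_asc(coefs, theta)
}

#' Musculotendon length of a muscle at a pose
#'
#' Defined from the moment-arm polynomials by tendon excursion:
#' dL/d(theta) = -r(theta) with theta in radians, integrated from the
#' neutral pose, plus a nominal resting length.  Used to verify the
#' consistency of arms and lengths.
#'
#' @inheritParams moment_arm
#' @return Length in meters.
#' @export
muscle_length <- function(model, muscle, pose = NULL) {
  if (!muscle %in% names(model$muscles)) {
    stop_squatmech(sprintf("unknown muscle '%s'", muscle), "lookup_error")
  }
  L <- 0.3
  arms <- model$muscles[[muscle]]$arms
  for (dof in names(arms)) {
    theta <- if (!is.null(pose) && dof %in% names(pose)) pose[[dof]] else 0
    coefs <- arms[[dof]]
    # integral of the polynomial in degrees, converted to radians
    int <- sum(coefs * theta^(seq_along(coefs)) / seq_along(coefs))
    L <- L - (pi / 180) * int
  }
  L
}

#' Serialize a model to a structured text config
#'
#' Writes segments, joints/DOFs, muscles, marker map and scalar
#' parameters as YAML so a model can be stored and rebuilt.
#'
#' @param model A `squat_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
model_to_config <- function(model, path) {
  part <- unclass(model$participant)
  part$segment_scales <- as.list(part$segment_scales)
  obj <- list(
    participant = part,
    segments = model$segments,
    dofs = model$dofs,
    dof_axis = as.list(model$dof_axis),
    dof_mech_sign = as.list(model$dof_mech_sign),
    muscles = model$muscles,
    markers = model$markers,
    tibial_plateau_width = model$tibial_plateau_width,
    barbell_height = model$barbell_height,
    weight_share = model$weight_share,
    gravity = model$gravity,
    scaled = model$scaled,
    scale_factors = as.list(model$scale_factors)
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Rebuild a model from a config written by [model_to_config()]
#' @param path Config file path.
#' @return A `squat_model`.
#' @export
model_from_config <- function(path) {
  obj <- yaml::read_yaml(path)
  p <- obj$participant
  part <- participant(p$id, p$mass_kg, p$height_m, p$valgus_deg, p$onerm_kg,
                      segment_scales = unlist(p$segment_scales))
  model <- structure(list(
    participant = part,
    segments = lapply(obj$segments, function(s) {
      s$com_local <- as.numeric(s$com_local)
      s$inertia <- unlist(s$inertia)
      s
    }),
    dofs = obj$dofs,
    dof_axis = unlist(obj$dof_axis),
    dof_mech_sign = unlist(obj$dof_mech_sign),
    muscles = lapply(obj$muscles, function(m) {
      m$arms <- lapply(m$arms, as.numeric); m
    }),
    markers = lapply(obj$markers, function(m) {
      m$offset <- as.numeric(m$offset); m
    }),
    tibial_plateau_width = obj$tibial_plateau_width,
    barbell_height = obj$barbell_height,
    weight_share = obj$weight_share,
    gravity = obj$gravity,
    scaled = obj$scaled,
    scale_factors = unlist(obj$scale_factors)
  ), class = "squat_model")
  model
}

#' @export
print.squat_model <- function(x, ...) {
  cat("squat_model:", length(x$segments), "segments,",
      length(x$dofs), "DOFs,", length(x$muscles), "muscles,",
      length(x$markers), "markers\n")
  cat(sprintf("  total mass %.2f kg, scaled: %s\n",
              model_total_mass(x), x$scaled))
  invisible(x)
}
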