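# Forward kinematics of the right-leg chain rooted at the planted foot.
# Global frame: x anterior, y up, z lateral (subject's right); the foot
# segment is fixed flat on the ground with its origin under the ankle.
# The subtalar angle rolls the calcaneus sub-frame (heel markers) about
# the anterior axis -- the rearfoot valgus measurement -- while the
# shank chain carries ankle flexion and everything above.

# Accumulated global rotations for a pose in convention-positive
# degrees.  Because the chain runs child-to-parent (planted foot up),
# each joint composes rotation - adduction - flexion, the inverse of the
# anatomical flexion-first sequence: the flexion axis then stays fixed
# to the proximal (anatomically parent) segment and the varus/valgus
# axis stays close to the distal segment's anterior axis, as in a joint
# coordinate system.
joint_rotations <- function(model, q_deg) {
  m <- deg2rad(q_deg[model$dofs] * model$dof_mech_sign[model$dofs])
  R_calc <- rot_x(m[["subtalar_supination"]])
  R_shank <- rot_z(m[["ankle_dorsiflexion"]])
  R_thigh <- R_shank %*% rot_y(m[["knee_rotation"]]) %*%
    rot_x(m[["knee_adduction"]]) %*% rot_z(m[["knee_flexion"]])
  R_pelvis <- R_thigh %*% rot_y(m[["hip_rotation"]]) %*%
    rot_x(m[["hip_adduction"]]) %*% rot_z(m[["hip_flexion"]])
  list(foot = diag(3), calcaneus = R_calc, shank = R_shank,
       thigh = R_thigh, pelvis = R_pelvis)
}

#' Forward kinematics of one pose
#'
#' @param model A `squat_model`.
#' @param q_deg Named numeric of the 8 joint angles in degrees
#'   (convention-positive; missing names are treated as 0).
#' @return List with segment rotations `R`, joint centers `joints`
#'   (ankle, knee, hip), segment origins, COM positions (4 x 3 matrix),
#'   barbell position and the predicted `markers` (n x 3 matrix).
#' @export
fk_pose <- function(model, q_deg) {
  q <- stats::setNames(numeric(length(model$dofs)), model$dofs)
  q[names(q_deg)[names(q_deg) %in% model$dofs]] <-
    q_deg[names(q_deg) %in% model$dofs]
  R <- joint_rotations(model, q)
  segs <- model$segments
  p_ankle <- c(0, segs$foot$ankle_height, 0)
  p_knee <- p_ankle + as.numeric(R$shank %*% c(0, segs$shank$length, 0))
  p_hip <- p_knee + as.numeric(R$thigh %*% c(0, segs$thigh$length, 0))
  origins <- list(foot = c(0, 0, 0), calcaneus = c(0, 0, 0),
                  shank = p_ankle, thigh = p_knee, pelvis = p_hip)
  com <- rbind(
    foot = segs$foot$com_local,
    shank = p_ankle + as.numeric(R$shank %*% segs$shank$com_local),
    thigh = p_knee + as.numeric(R$thigh %*% segs$thigh$com_local),
    pelvis = p_hip + as.numeric(R$pelvis %*% segs$pelvis$com_local)
  )
  barbell <- p_hip + as.numeric(R$pelvis %*% c(0, model$barbell_height, 0))
  mk <- predict_markers(model, R, origins)
  list(R = R, joints = list(ankle = p_ankle, knee = p_knee, hip = p_hip),
       origins = origins, com = com, barbell = barbell, markers = mk)
}

# Predicted global marker positions given precomputed rotations/origins.
predict_markers <- function(model, R, origins) {
  nm <- names(model$markers)
  out <- matrix(0, length(nm), 3, dimnames = list(nm, c("x", "y", "z")))
  for (i in seq_along(nm)) {
    mk <- model$markers[[i]]
    out[i, ] <- origins[[mk$segment]] +
      as.numeric(R[[mk$segment]] %*% mk$offset)
  }
  out
}

# Fast marker-only FK used in the IK inner loop: returns a length-3n
# vector (row-major by marker).
fk_marker_vec <- function(model, q) {
  R <- joint_rotations(model, q)
  segs <- model$segments
  p_ankle <- c(0, segs$foot$ankle_height, 0)
  p_knee <- p_ankle + as.numeric(R$shank %*% c(0, segs$shank$length, 0))
  p_hip <- p_knee + as.numeric(R$thigh %*% c(0, segs$thigh$length, 0))
  origins <- list(foot = c(0, 0, 0), calcaneus = c(0, 0, 0),
                  shank = p_ankle, thigh = p_knee, pelvis = p_hip)
  mks <- model$markers
  out <- numeric(3L * length(mks))
  for (i in seq_along(mks)) {
    mk <- mks[[i]]
    out[(3 * i - 2):(3 * i)] <- origins[[mk$segment]] +
      as.numeric(R[[mk$segment]] %*% mk$offset)
  }
  out
}
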