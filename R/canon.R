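#' Canonical angle, subscore, and feature catalogues
#'
#' The pipeline works with 18 relative joint/segment angles per body side
#' (Plug-in-Gait-style full-body decomposition), six ordinal SMS subscores,
#' and a fixed 680-entry stride-pair feature vector. These helpers define the
#' canonical names and ordering used everywhere: generated cohorts, feature
#' tables, selection masks, and fitted models all refer to features by these
#' names, in this order.
#'
#' @name canon
NULL

# 18 angles per side; grouped by body region for the expert masks
.sms_angles <- c(
  "pelvis_tilt", "pelvis_obliquity", "pelvis_rotation",
  "thorax_tilt", "thorax_side_tilt", "thorax_rotation",
  "foot_progression",
  "hip_flexion", "hip_adduction",
  "knee_flexion",
  "ankle_dorsiflexion", "ankle_inversion",
  "spine_tilt", "spine_side_tilt", "spine_rotation",
  "shoulder_flexion", "shoulder_adduction",
  "elbow_flexion"
)

# lower-body / posture angles used by the Leg mask; the complement (trunk +
# upper limb) is used by the Arm mask
.sms_leg_angles <- c(
  "pelvis_tilt", "pelvis_obliquity", "pelvis_rotation",
  "foot_progression",
  "hip_flexion", "hip_adduction",
  "knee_flexion",
  "ankle_dorsiflexion", "ankle_inversion"
)

.sms_arm_angles <- c(
  "thorax_tilt", "thorax_side_tilt", "thorax_rotation",
  "spine_tilt", "spine_side_tilt", "spine_rotation",
  "shoulder_flexion", "shoulder_adduction",
  "elbow_flexion"
)

.sms_subscores <- c("trunk", "leg", "arm", "speed", "fluency", "stability")

.sms_sides <- c("ipsi", "contra")

# 15 spatiotemporal gait parameters per side, canonical order
.sms_gait_params <- c(
  "gait_speed", "cadence", "stride_time", "step_time",
  "single_support_time", "double_support_time",
  "single_support_pct", "double_support_pct",
  "step_width_norm", "step_length_norm", "stride_length_norm",
  "limp_index",
  "swing_start_pct", "stance_duration_pct", "swing_duration_pct"
)

.sms_signals <- c("angle", "nav")
.sms_windows <- c("stance", "swing", "cycle")
.sms_stats <- c("min", "median", "max")

#' @describeIn canon the 18 angle identifiers (one body side).
#' @export
sms_angles <- function() .sms_angles

#' @describeIn canon the six subscore identifiers, canonical order.
#' @export
sms_subscores <- function() .sms_subscores

#' @describeIn canon the 15 per-side spatiotemporal gait parameter names.
#' @export
sms_gait_parameters <- function() .sms_gait_params

#' Names of the 18 numerical characterizations of one angle
#'
#' min/median/max of the angle and of its normalized angular velocity (NAV),
#' over the stance phase, the swing phase, and the whole gait cycle:
#' 2 signals x 3 windows x 3 statistics = 18 named values.
#'
#' @param angle angle identifier (see [sms_angles()]); used as name prefix.
#' @return character vector of 18 names, canonical order.
#' @export
sms_characterization_names <- function(angle = NULL) {
  grid <- expand.grid(
    stat = .sms_stats, window = .sms_windows, signal = .sms_signals,
    stringsAsFactors = FALSE
  )
  nm <- paste(grid$signal, grid$window, grid$stat, sep = "_")
  if (!is.null(nm) && !is.null(angle)) nm <- paste(angle, nm, sep = "_")
  nm
}

#' The canonical 680 stride-pair feature names
#'
#' 30 gait parameters (15 per side), 648 characterizations (18 angles x 18
#' statistics x 2 sides), and the two walking-aid flags. The order returned
#' here is the fixed, platform-independent feature order of the pipeline.
#'
#' @return character vector of length 680.
#' @export
sms_feature_names <- function() {
  params <- as.vector(vapply(
    .sms_sides,
    function(s) paste(.sms_gait_params, s, sep = "_"),
    character(length(.sms_gait_params))
  ))
  chars <- as.vector(vapply(
    .sms_sides,
    function(s) {
      unlist(lapply(.sms_angles, function(a) {
        paste(sms_characterization_names(a), s, sep = "_")
      }))
    },
    character(length(.sms_angles) * 18L)
  ))
  c(params, chars, "cane", "afo")
}

# internal: feature names for one angle-side block
.char_names_side <- function(angles, side) {
  unlist(lapply(angles, function(a) {
    paste(sms_characterization_names(a), side, sep = "_")
  }))
}

#' Side annotation of each feature
#'
#' Maps feature names to "ipsi", "contra", or NA (the two aid flags), used
#' when reporting the ipsilateral/contralateral share of key features.
#'
#' @param features character vector of canonical feature names.
#' @return character vector of the same length.
#' @export
sms_feature_side <- function(features) {
  side <- rep(NA_character_, length(features))
  side[endsWith(features, "_ipsi")] <- "ipsi"
  side[endsWith(features, "_contra")] <- "contra"
  side
}
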