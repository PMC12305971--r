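#' Normalized angular velocity of an angle trace
#'
#' Differentiates a joint-angle trace with respect to gait-cycle progress
#' (the NAV), on the normalized 0-100% grid: central differences at
#' interior samples, one-sided differences at the endpoints. Units are
#' degrees per % cycle. The scheme is second-order accurate and exact for
#' linear traces; it is a linear operator.
#'
#' @param trace numeric vector of 101 finite samples (0-100% cycle).
#' @return numeric vector of 101 NAV samples.
#' @export
compute_nav <- function(trace) {
  if (length(trace) != 101L)
    stop("an angle trace has exactly 101 samples", call. = FALSE)
  if (!all(is.finite(trace)))
    stop("angle trace contains non-finite values", call. = FALSE)
  n <- length(trace)
  nav <- numeric(n)
  nav[1] <- trace[2] - trace[1]
  nav[n] <- trace[n] - trace[n - 1]
  nav[2:(n - 1)] <- (trace[3:n] - trace[1:(n - 2)]) / 2
  nav
}

#' Numerical characterization of one angle's movement
#'
#' Computes the 18 descriptive statistics of an angle trace: the minimum,
#' median, and maximum of the angle and of its NAV, over the stance phase,
#' the swing phase, and the whole gait cycle. The stance window covers the
#' samples from 0% up to the foot-off sample, the swing window the samples
#' from foot-off to 100%; the boundary sample at foot off belongs to both
#' windows (closed windows).
#'
#' @param trace numeric vector of 101 samples.
#' @param stance_fraction foot-off as a fraction of the stride, in (0, 1).
#' @param angle optional angle id used to prefix the names.
#' @return named numeric vector of length 18, in the canonical order of
#'   [sms_characterization_names()].
#' @export
characterize_angle <- function(trace, stance_fraction, angle = NULL) {
  if (!(stance_fraction > 0 && stance_fraction < 1))
    stop("`stance_fraction` must lie in (0, 1)", call. = FALSE)
  nav <- compute_nav(trace)
  b <- floor(stance_fraction * 100) + 1L  # foot-off sample (1-based)
  windows <- list(stance = 1:b, swing = b:101L, cycle = 1:101L)
  out <- numeric(18)
  k <- 0L
  for (sig in list(trace, nav)) {
    for (w in windows) {
      x <- sig[w]
      out[k + 1:3] <- c(min(x), stats::median(x), max(x))
      k <- k + 3L
    }
  }
  names(out) <- sms_characterization_names(angle)
  out
}

# gait parameters for one side of a stride pair; ev_s / ev_o are one-row
# event records for the side and its opposite, fs_opp the opposite foot
# strike inside this side's stride used for step timing
.side_gait_params <- function(ev_s, ev_o) {
  stride_time <- ev_s$next_foot_strike_s - ev_s$foot_strike_s
  stride_time_o <- ev_o$next_foot_strike_s - ev_o$foot_strike_s
  if (stride_time <= 0 || stride_time_o <= 0)
    stop("non-positive stride time", call. = FALSE)
  stance <- ev_s$foot_off_s - ev_s$foot_strike_s
  stance_o <- ev_o$foot_off_s - ev_o$foot_strike_s
  swing_o <- stride_time_o - stance_o

  # step: from the opposite foot strike to this side's next strike (or from
  # this side's strike to the opposite strike, whichever pair of strikes is
  # consecutive in time)
  step_time <- if (ev_o$foot_strike_s > ev_s$foot_strike_s)
    ev_s$next_foot_strike_s - ev_o$foot_strike_s
  else
    ev_s$foot_strike_s - ev_o$foot_strike_s

  gait_speed <- ev_s$stride_length_m / stride_time
  single_support <- swing_o
  double_support <- stance - swing_o
  step_length <- gait_speed * step_time

  c(
    gait_speed = gait_speed,
    cadence = 2 / stride_time,
    stride_time = stride_time,
    step_time = step_time,
    single_support_time = single_support,
    double_support_time = double_support,
    single_support_pct = 100 * single_support / stride_time,
    double_support_pct = 100 * double_support / stride_time,
    step_width_norm = ev_s$step_width_m / ev_s$body_height_m,
    step_length_norm = step_length / ev_s$leg_length_m,
    stride_length_norm = ev_s$stride_length_m / ev_s$leg_length_m,
    limp_index = stance / stance_o,
    swing_start_pct = 100 * stance / stride_time,
    stance_duration_pct = 100 * stance / stride_time,
    swing_duration_pct = 100 * (1 - stance / stride_time)
  )
}

#' Spatiotemporal gait parameters of a stride pair
#'
#' Computes the 15 parameters per side: gait speed (m/s), cadence
#' (steps/s), stride and step times (s), single and double support times
#' (s) and shares (% cycle), height-normalized step width, leg-length
#' normalized step and stride lengths, limp index (own over opposite
#' stance time; 1 = symmetric), start of swing, and stance/swing durations
#' (% cycle). Single support of one side is the opposite side's swing
#' time; step length is derived as gait speed times step time.
#'
#' @param ipsi,contra one-row event records (as in a cohort's `events`
#'   table) for the coupled ipsilateral and contralateral strides.
#' @return named numeric vector of length 30 (`_ipsi` block then `_contra`
#'   block).
#' @export
compute_gait_parameters <- function(ipsi, contra) {
  if (any(c(ipsi$body_height_m, ipsi$leg_length_m,
            contra$body_height_m, contra$leg_length_m) <= 0))
    stop("body height and leg length must be positive", call. = FALSE)
  for (ev in list(ipsi, contra)) {
    if (!(ev$foot_strike_s < ev$foot_off_s &&
          ev$foot_off_s < ev$next_foot_strike_s))
      stop("gait events must satisfy foot strike < foot off < next foot strike",
           call. = FALSE)
  }
  p_i <- .side_gait_params(ipsi, contra)
  p_c <- .side_gait_params(contra, ipsi)
  c(stats::setNames(p_i, paste0(names(p_i), "_ipsi")),
    stats::setNames(p_c, paste0(names(p_c), "_contra")))
}

# stance fraction of one event record
.stance_fraction <- function(ev) {
  (ev$foot_off_s - ev$foot_strike_s) /
    (ev$next_foot_strike_s - ev$foot_strike_s)
}

#' Feature vector of one stride pair
#'
#' Assembles the canonical 680-entry feature vector: 30 gait parameters,
#' 648 numerical characterizations of movement (18 angles x 18 statistics
#' x 2 sides), and the two walking-aid flags. Each stride contributes 339
#' stride-derived features (15 parameters + 324 characterizations).
#'
#' @param ipsi_events,contra_events one-row event records of the two
#'   coupled strides.
#' @param ipsi_angles,contra_angles 101 x 18 matrices (columns named as
#'   [sms_angles()]) with the angle traces of the two strides.
#' @param cane,afo walking-aid flags, 0 or 1.
#' @return named numeric vector of length 680, canonical order.
#' @export
extract_feature_vector <- function(ipsi_events, contra_events,
                                   ipsi_angles, contra_angles,
                                   cane, afo) {
  for (m in list(ipsi_angles, contra_angles)) {
    missing <- setdiff(sms_angles(), colnames(m))
    if (length(missing))
      stop("missing angle trace(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  params <- compute_gait_parameters(ipsi_events, contra_events)

  chars <- numeric(648)
  nm <- character(648)
  k <- 0L
  sides <- list(ipsi = list(ipsi_angles, .stance_fraction(ipsi_events)),
                contra = list(contra_angles, .stance_fraction(contra_events)))
  for (side in c("ipsi", "contra")) {
    mat <- sides[[side]][[1]]
    sf <- sides[[side]][[2]]
    for (a in sms_angles()) {
      v <- characterize_angle(mat[, a], sf, angle = a)
      chars[k + 1:18] <- v
      nm[k + 1:18] <- paste(names(v), side, sep = "_")
      k <- k + 18L
    }
  }
  names(chars) <- nm

  out <- c(params, chars, cane = as.numeric(cane), afo = as.numeric(afo))
  out[sms_feature_names()]
}

#' Stride-pair feature table of a cohort
#'
#' Builds all stride pairs ([build_stride_pairs()]), extracts the 680
#' features of each, and couples every pair with its patient's expert-board
#' labels.
#'
#' @param cohort an `sms_cohort`.
#' @return tibble with one row per stride pair: `patient_id`, `pair`, the
#'   680 feature columns, the six board subscores, and `sms`.
#' @export
extract_features <- function(cohort) {
  pairs <- build_stride_pairs(cohort)
  boards <- board_scores(cohort$raters)
  ev <- cohort$events
  ev_key <- paste(ev$patient_id, ev$side, ev$stride)

  ang <- cohort$angles
  ang_key <- paste(ang$patient_id, ang$side, ang$stride)
  ang_mat <- as.matrix(ang[, sms_angles()])
  ang_rows <- split(seq_len(nrow(ang)), ang_key)

  feat <- matrix(NA_real_, nrow(pairs), 680,
                 dimnames = list(NULL, sms_feature_names()))
  for (r in seq_len(nrow(pairs))) {
    pid <- pairs$patient_id[r]
    ev_i <- ev[ev_key == paste(pid, "ipsi", pairs$ipsi_stride[r]), ]
    ev_c <- ev[ev_key == paste(pid, "contra", pairs$contra_stride[r]), ]
    m_i <- ang_mat[ang_rows[[paste(pid, "ipsi", pairs$ipsi_stride[r])]], ,
                   drop = FALSE]
    m_c <- ang_mat[ang_rows[[paste(pid, "contra", pairs$contra_stride[r])]], ,
                   drop = FALSE]
    pt <- cohort$patients[cohort$patients$patient_id == pid, ]
    feat[r, ] <- extract_feature_vector(ev_i, ev_c, m_i, m_c,
                                        pt$cane, pt$afo)
  }

  dplyr::bind_cols(
    pairs[, c("patient_id", "pair")],
    tibble::as_tibble(feat)
  ) |>
    dplyr::left_join(boards, by = "patient_id")
}
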