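#' Simulation configuration for a synthetic hemiparetic cohort
#'
#' Defines the generative model for a synthetic stroke cohort in which latent
#' per-subscore severities (each on the 0-3 scale of the SMS subscores) drive
#' the gait kinematics, the walking-aid use, and the five expert raters'
#' recommendations. The defaults are the package's reference study
#' conditions: 100 patients, 4-12 strides per side, rater noise 0.25 score
#' units, kinematic jitter 1.5 degrees.
#'
#' Severity couplings (all per unit of severity on the 0-3 scale):
#' \describe{
#'   \item{speed_time, speed_length}{stride time lengthens and stride length
#'     shrinks with the Speed severity, so gait speed falls monotonically.}
#'   \item{stance_stability}{stance fraction rises with the Stability
#'     severity (cautious gait).}
#'   \item{stance_asym}{ipsilateral stance shortens and contralateral stance
#'     lengthens with the Leg severity, producing the limp-index signal.}
#'   \item{amp}{joint-angle amplitudes shrink with the region's severity
#'     (Leg for lower-body angles, Trunk for thorax/spine, Arm for
#'     shoulder/elbow); the contralateral side receives half the effect.}
#'   \item{offset}{joint-angle offsets drift with the region's severity.}
#'   \item{fluency_wobble}{a 6th-harmonic wobble, scaled by the Fluency
#'     severity, roughens every angle trace (strong NAV signature).}
#'   \item{width_stability}{step width widens with the Stability severity.}
#'   \item{cane_slope, cane_mid}{logistic model for cane use in the
#'     Stability severity.}
#'   \item{afo_slope, afo_mid}{logistic model for ankle-foot-orthosis use in
#'     the Leg severity.}
#' }
#'
#' @param n_patients number of patients (>= 1).
#' @param strides_range integer range (min, max) of strides per side,
#'   min >= 2 (a stride pair needs two consecutive strides).
#' @param sigma_rater sd of the rater noise, score units (>= 0).
#' @param sigma_kin sd of the periodic kinematic jitter, degrees (>= 0).
#' @param severity_cor latent rank correlation between subscore severities
#'   (Gaussian copula, equicorrelated), in [0, 1).
#' @param coupling named list overriding individual coupling coefficients.
#' @param seed integer seed fixing the whole cohort bit-for-bit.
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_patients = 100L,
                       strides_range = c(4L, 12L),
                       sigma_rater = 0.25,
                       sigma_kin = 1.5,
                       severity_cor = 0.5,
                       coupling = list(),
                       seed = 1L) {
  if (length(n_patients) != 1L || n_patients < 1)
    stop("`n_patients` must be a positive count", call. = FALSE)
  if (length(strides_range) != 2L || strides_range[1] < 2L ||
      strides_range[2] < strides_range[1])
    stop("`strides_range` must be (min, max) with min >= 2", call. = FALSE)
  if (sigma_rater < 0 || sigma_kin < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (severity_cor < 0 || severity_cor >= 1)
    stop("`severity_cor` must lie in [0, 1)", call. = FALSE)

  default_coupling <- list(
    speed_time = 0.25,       # s per severity unit on stride time
    speed_length = 0.27,     # m per severity unit off stride length
    leg_length_penalty = 0.03,
    stance_stability = 0.020,
    stance_asym = 0.012,
    offset_asym = 0.015,     # contralateral event offset shift per unit
    amp = 0.09,              # fractional amplitude loss per unit
    offset = 1.2,            # degrees of offset drift per unit
    fluency_wobble = 0.9,    # degrees of 6th-harmonic wobble per unit
    contra_factor = 0.5,     # contralateral share of the kinematic effect
    width_stability = 0.013, # m of step width per unit
    cane_slope = 3.0, cane_mid = 1.6,
    afo_slope = 2.0, afo_mid = 2.2
  )
  unknown <- setdiff(names(coupling), names(default_coupling))
  if (length(unknown))
    stop("unknown coupling coefficient(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  default_coupling[names(coupling)] <- coupling

  structure(
    list(
      n_patients = as.integer(n_patients),
      strides_range = as.integer(strides_range),
      sigma_rater = sigma_rater,
      sigma_kin = sigma_kin,
      severity_cor = severity_cor,
      coupling = default_coupling,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' A latent severity profile
#'
#' One patient's latent severities, one per SMS subscore, each in [0, 3],
#' plus the stroke-affected side.
#'
#' @param trunk,leg,arm,speed,fluency,stability severities in [0, 3].
#' @param affected_side `"left"` or `"right"`.
#' @return a one-row tibble of class `sms_severity`.
#' @export
sms_severity <- function(trunk = 0, leg = 0, arm = 0, speed = 0,
                         fluency = 0, stability = 0,
                         affected_side = c("left", "right")) {
  affected_side <- match.arg(affected_side)
  th <- stats::setNames(
    as.numeric(c(trunk, leg, arm, speed, fluency, stability)),
    c("trunk", "leg", "arm", "speed", "fluency", "stability"))
  if (any(th < 0 | th > 3))
    stop("severities must lie in [0, 3]", call. = FALSE)
  out <- tibble::as_tibble(as.list(th))
  out$affected_side <- affected_side
  class(out) <- c("sms_severity", class(out))
  out
}

# Normative Fourier templates, degrees: offset + sum_k a_k cos(2 pi k t) +
# b_k sin(2 pi k t), t = cycle fraction. Shapes approximate textbook
# normative full-body gait curves; the knee template was fitted to a
# normative flexion curve (stance flexion wave, ~60 degree swing peak).
.sms_templates <- list(
  pelvis_tilt        = list(offset = 10, a = c(0.8, 1.0), b = c(-0.5, 0.6)),
  pelvis_obliquity   = list(offset = 0, a = c(3.5, 1.2), b = c(1.0, -0.8)),
  pelvis_rotation    = list(offset = 0, a = c(5.0), b = c(2.0)),
  thorax_tilt        = list(offset = 5, a = c(1.2, 1.5), b = c(0.4, 0.8)),
  thorax_side_tilt   = list(offset = 0, a = c(2.5), b = c(1.2)),
  thorax_rotation    = list(offset = 0, a = c(6.0), b = c(2.5)),
  foot_progression   = list(offset = -8, a = c(3.0, 2.0), b = c(1.5, 1.0)),
  hip_flexion        = list(offset = 12, a = c(18, 3), b = c(6, -2)),
  hip_adduction      = list(offset = 2, a = c(4, 2), b = c(2, 1)),
  knee_flexion       = list(offset = 22.42,
                            a = c(-3.539, -14.245, 0.237, 0.638),
                            b = c(-18.708, 7.735, 2.929, -0.877)),
  ankle_dorsiflexion = list(offset = 2, a = c(3, -5, 2), b = c(-4, 3, 1)),
  ankle_inversion    = list(offset = 1, a = c(2, 1.5), b = c(1, -1)),
  spine_tilt         = list(offset = 3, a = c(1.0, 1.2), b = c(0.5, 0.6)),
  spine_side_tilt    = list(offset = 0, a = c(2.0), b = c(1.0)),
  spine_rotation     = list(offset = 0, a = c(4.0), b = c(1.5)),
  shoulder_flexion   = list(offset = -5, a = c(12), b = c(4)),
  shoulder_adduction = list(offset = 5, a = c(3), b = c(1)),
  elbow_flexion      = list(offset = 35, a = c(8, 2), b = c(3, 1))
)

# region severity driving each angle's modulation
.sms_angle_region <- c(
  pelvis_tilt = "leg", pelvis_obliquity = "leg", pelvis_rotation = "leg",
  thorax_tilt = "trunk", thorax_side_tilt = "trunk", thorax_rotation = "trunk",
  foot_progression = "leg",
  hip_flexion = "leg", hip_adduction = "leg",
  knee_flexion = "leg",
  ankle_dorsiflexion = "leg", ankle_inversion = "leg",
  spine_tilt = "trunk", spine_side_tilt = "trunk", spine_rotation = "trunk",
  shoulder_flexion = "arm", shoulder_adduction = "arm",
  elbow_flexion = "arm"
)

# round-half-away-from-zero, the score rounding used for rater draws
.round_half_up <- function(x) floor(x + 0.5)

#' Severity-modulated joint-angle trace for one stride
#'
#' Evaluates the normative Fourier template of an angle on the 101-sample
#' normalized gait cycle (0-100%), modulated by the relevant latent
#' severity: amplitude shrinks and offset drifts with the region's severity
#' (half effect on the contralateral side), a 6th-harmonic wobble grows with
#' the Fluency severity, and smooth periodic jitter with pointwise sd
#' `sigma_kin` is added as random low-order harmonics (so the trace stays
#' exactly periodic: first and last samples are equal).
#'
#' @param angle one of [sms_angles()].
#' @param severity an [sms_severity()] profile (defaults to all-zero).
#' @param side_role `"ipsi"` (affected side, full effect) or `"contra"`.
#' @param config a [sim_config()] supplying couplings and `sigma_kin`.
#' @param seed optional integer; if given, the jitter is drawn under this
#'   seed and the caller's RNG state is left untouched.
#' @return numeric vector of 101 samples, degrees.
#' @export
angle_template <- function(angle, severity = sms_severity(),
                           side_role = c("ipsi", "contra"),
                           config = sim_config(), seed = NULL) {
  side_role <- match.arg(side_role)
  if (!angle %in% names(.sms_templates))
    stop("unknown angle id: ", angle, call. = FALSE)
  tpl <- .sms_templates[[angle]]
  cp <- config$coupling
  region <- .sms_angle_region[[angle]]
  theta_region <- severity[[region]]
  side_factor <- if (side_role == "ipsi") 1 else cp$contra_factor

  amp <- max(1 - cp$amp * theta_region * side_factor, 0.05)
  off_shift <- cp$offset * theta_region * side_factor
  wobble <- cp$fluency_wobble * severity$fluency * side_factor

  t <- seq(0, 1, length.out = 101L)
  y <- rep(tpl$offset + off_shift, 101L)
  for (k in seq_along(tpl$a)) {
    y <- y + amp * (tpl$a[k] * cos(2 * pi * k * t) +
                      tpl$b[k] * sin(2 * pi * k * t))
  }
  if (wobble > 0) y <- y + wobble * sin(2 * pi * 6 * t)

  if (config$sigma_kin > 0) {
    draw <- function() {
      s <- config$sigma_kin / sqrt(3)
      ab <- stats::rnorm(6, 0, s)
      j <- rep(0, 101L)
      for (k in 1:3) {
        j <- j + ab[k] * cos(2 * pi * k * t) + ab[k + 3] * sin(2 * pi * k * t)
      }
      j
    }
    jit <- if (is.null(seed)) draw() else withr_seed(seed, draw())
    y <- y + jit
  }
  y
}

# run code under a temporary seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a synthetic hemiparetic cohort
#'
#' Draws latent severity profiles (per-subscore Uniform[0,3] marginals with
#' an equicorrelated Gaussian copula), then generates for every patient:
#' gait events and spatiotemporal stride measurements on both sides,
#' 101-sample traces of all 18 angles per stride, walking-aid flags
#' (logistic in the relevant severity), and five raters' integer
#' recommendations per subscore, `clip(round(theta_k + eps), 0, 3)` with
#' `eps ~ Normal(0, sigma_rater)` i.i.d. per rater.
#'
#' The same configuration (which includes the seed) always reproduces the
#' identical cohort.
#'
#' @param config a [sim_config()].
#' @return an object of class `sms_cohort`: a list of tibbles `patients`
#'   (severities, affected side, aid flags, anthropometrics), `events` (one
#'   row per stride and side, times in seconds), `angles` (101 rows per
#'   stride and side, one column per angle), and `raters` (5 raters x 6
#'   subscores per patient).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  cp <- config$coupling
  subs <- sms_subscores()

  # equicorrelated Gaussian copula -> Uniform[0,3] severities
  rho <- config$severity_cor
  z0 <- stats::rnorm(n)
  z <- sapply(subs, function(s) {
    sqrt(rho) * z0 + sqrt(1 - rho) * stats::rnorm(n)
  })
  theta <- 3 * stats::pnorm(matrix(z, nrow = n))
  colnames(theta) <- subs

  patients <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(n)),
    affected_side = sample(c("left", "right"), n, replace = TRUE)
  )
  for (s in subs) patients[[paste0("theta_", s)]] <- theta[, s]
  patients$cane <- stats::rbinom(
    n, 1, stats::plogis(cp$cane_slope * (theta[, "stability"] - cp$cane_mid)))
  patients$afo <- stats::rbinom(
    n, 1, stats::plogis(cp$afo_slope * (theta[, "leg"] - cp$afo_mid)))
  patients$body_height_m <- pmax(stats::rnorm(n, 1.72, 0.09), 1.45)
  patients$leg_length_m <- pmax(stats::rnorm(n, 0.89, 0.05), 0.70)
  sizes <- seq.int(config$strides_range[1], config$strides_range[2])
  patients$n_strides <- sizes[sample.int(length(sizes), n, replace = TRUE)]

  # five raters x six subscores
  raters <- tidyr::expand_grid(
    patient_id = patients$patient_id, subscore = subs, rater = 1:5)
  th_long <- theta[match(raters$patient_id, patients$patient_id), ]
  th_i <- th_long[cbind(seq_len(nrow(raters)), match(raters$subscore, subs))]
  eps <- stats::rnorm(nrow(raters), 0, config$sigma_rater)
  raters$value <- as.integer(pmin(pmax(.round_half_up(th_i + eps), 0), 3))

  events_list <- vector("list", n)
  angles_list <- vector("list", n)
  for (i in seq_len(n)) {
    th <- theta[i, ]
    sev <- sms_severity(
      trunk = th["trunk"], leg = th["leg"], arm = th["arm"],
      speed = th["speed"], fluency = th["fluency"],
      stability = th["stability"],
      affected_side = patients$affected_side[i])
    ns <- patients$n_strides[i]

    T_p <- 1.05 + cp$speed_time * th["speed"] + stats::rnorm(1, 0, 0.03)
    L_p <- max(1.30 - cp$speed_length * th["speed"] -
                 cp$leg_length_penalty * th["leg"] + stats::rnorm(1, 0, 0.04),
               0.25)
    sf_i <- 0.60 + cp$stance_stability * th["stability"] -
      cp$stance_asym * th["leg"]
    sf_c <- 0.60 + cp$stance_stability * th["stability"] +
      cp$stance_asym * th["leg"] * 0.8
    off_frac <- min(0.5 + cp$offset_asym * th["leg"], 0.62)
    W_p <- max(0.09 + cp$width_stability * th["stability"] +
                 stats::rnorm(1, 0, 0.01), 0.04)

    # ipsilateral foot strikes bounding ns strides, plus the contralateral
    # strike inside each ipsilateral stride
    Tj <- pmax(T_p + stats::rnorm(ns + 1, 0, 0.02), 0.4)
    fs_i <- cumsum(c(0, Tj))            # ns + 2 strikes -> ns + 1 strides
    fs_c <- fs_i[seq_len(ns + 1)] + off_frac * Tj

    ev <- list()
    for (side in c("ipsi", "contra")) {
      fs <- if (side == "ipsi") fs_i else fs_c
      sf <- if (side == "ipsi") sf_i else sf_c
      st <- diff(fs)[seq_len(ns)]
      fsj <- fs[seq_len(ns)]
      sfj <- pmin(pmax(sf + stats::rnorm(ns, 0, 0.006), 0.45), 0.78)
      len_adj <- if (side == "ipsi") -0.01 * th["leg"] else 0
      ev[[side]] <- tibble::tibble(
        patient_id = patients$patient_id[i],
        stride = seq_len(ns),
        side = side,
        foot_strike_s = fsj,
        foot_off_s = fsj + sfj * st,
        next_foot_strike_s = fs[2:(ns + 1)],
        stride_length_m = pmax(
          L_p + len_adj + stats::rnorm(ns, 0, 0.02), 0.15),
        step_width_m = pmax(W_p + stats::rnorm(ns, 0, 0.005), 0.03),
        leg_length_m = patients$leg_length_m[i],
        body_height_m = patients$body_height_m[i]
      )
    }
    events_list[[i]] <- dplyr::bind_rows(ev)

    ang <- tidyr::expand_grid(
      patient_id = patients$patient_id[i],
      side = c("ipsi", "contra"),
      stride = seq_len(ns),
      pct = 0:100
    )
    for (a in sms_angles()) {
      col <- numeric(nrow(ang))
      for (side in c("ipsi", "contra")) {
        for (j in seq_len(ns)) {
          idx <- ang$side == side & ang$stride == j
          col[idx] <- angle_template(a, sev, side_role = side,
                                     config = config)
        }
      }
      ang[[a]] <- col
    }
    angles_list[[i]] <- ang
  }

  structure(
    list(
      patients = patients,
      events = dplyr::bind_rows(events_list),
      angles = dplyr::bind_rows(angles_list),
      raters = raters,
      config = config
    ),
    class = "sms_cohort"
  )
}

#' @export
print.sms_cohort <- function(x, ...) {
  cat("<sms_cohort> ", nrow(x$patients), " patients, ",
      nrow(x$events), " strides (both sides), seed ", x$config$seed, "\n",
      sep = "")
  invisible(x)
}
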