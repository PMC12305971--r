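test_that("the same configuration reproduces the identical cohort", {
  a <- tiny_cohort(n = 5, seed = 11)
  b <- tiny_cohort(n = 5, seed = 11)
  expect_identical(a$patients, b$patients)
  expect_identical(a$events, b$events)
  expect_identical(a$angles, b$angles)
  expect_identical(a$raters, b$raters)
  c <- tiny_cohort(n = 5, seed = 12)
  expect_false(identical(a$events, c$events))
})

test_that("noise-free raters reproduce the latent severity", {
  co <- simulate_cohort(sim_config(n_patients = 6, sigma_rater = 0,
                                   seed = 21))
  th <- co$patients[, paste0("theta_", sms_subscores())]
  for (i in seq_len(nrow(co$raters))) {
    r <- co$raters[i, ]
    theta <- th[match(r$patient_id, co$patients$patient_id),
                paste0("theta_", r$subscore)][[1]]
    expect_equal(r$value, min(max(floor(theta + 0.5), 0), 3))
  }
})

test_that("every stride has 101-sample traces for all 18 angles", {
  co <- tiny_cohort(n = 4, seed = 31)
  counts <- co$angles |>
    dplyr::count(patient_id, side, stride)
  expect_true(all(counts$n == 101))
  expect_true(all(sms_angles() %in% names(co$angles)))
  # at least two consecutive strides per side
  strides <- co$events |> dplyr::count(patient_id, side)
  expect_true(all(strides$n >= 2))
  # events ordered: foot strike < foot off < next foot strike
  expect_true(all(co$events$foot_strike_s < co$events$foot_off_s))
  expect_true(all(co$events$foot_off_s < co$events$next_foot_strike_s))
})

test_that("angle templates are periodic and noise-free at zero severity", {
  cfg0 <- sim_config(sigma_kin = 0)
  for (a in c("knee_flexion", "hip_flexion", "thorax_tilt")) {
    tr <- angle_template(a, config = cfg0)
    expect_length(tr, 101)
    expect_equal(tr[1], tr[101], tolerance = 1e-10)
  }
  # jittered traces stay periodic (harmonic jitter)
  tr <- angle_template("knee_flexion", config = sim_config(sigma_kin = 2),
                       seed = 5)
  expect_equal(tr[1], tr[101], tolerance = 1e-10)
  expect_error(angle_template("knee_twist"), "unknown angle")
})

test_that("severe leg impairment shrinks the knee flexion range", {
  cfg0 <- sim_config(sigma_kin = 0)
  healthy <- angle_template("knee_flexion", sms_severity(leg = 0),
                            config = cfg0)
  severe <- angle_template("knee_flexion", sms_severity(leg = 3),
                           config = cfg0)
  expect_lt(diff(range(severe)), diff(range(healthy)))
})

test_that("severity couplings drive speed, stance fraction, and rater mean", {
  co <- simulate_cohort(sim_config(n_patients = 200, seed = 41,
                                   sigma_rater = 0.25))
  ev <- co$events |>
    dplyr::mutate(
      speed = stride_length_m / (next_foot_strike_s - foot_strike_s),
      stance_frac = (foot_off_s - foot_strike_s) /
        (next_foot_strike_s - foot_strike_s)) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(speed = mean(speed), stance_frac = mean(stance_frac))
  ev <- dplyr::left_join(ev, co$patients, by = "patient_id")
  expect_lt(cor(ev$theta_speed, ev$speed), -0.8)
  expect_gt(cor(ev$theta_stability, ev$stance_frac), 0.5)

  # rater mean tracks the latent severity within ~0.1 on average
  rm <- co$raters |>
    dplyr::group_by(patient_id, subscore) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  th <- co$patients |>
    tidyr::pivot_longer(dplyr::starts_with("theta_"),
                        names_to = "subscore", values_to = "theta",
                        names_prefix = "theta_")
  j <- dplyr::inner_join(rm, th[, c("patient_id", "subscore", "theta")],
                         by = c("patient_id", "subscore"))
  # interior severities (rounding is unbiased away from the 0/3 clips)
  interior <- j[j$theta > 0.5 & j$theta < 2.5, ]
  expect_lt(abs(mean(interior$m - interior$theta)), 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_patients = 0), "positive")
  expect_error(sim_config(strides_range = c(1, 5)), "min >= 2")
  expect_error(sim_config(sigma_rater = -1), ">= 0")
  expect_error(sim_config(coupling = list(bogus = 1)), "unknown coupling")
  expect_error(sms_severity(leg = 4), "0, 3")
})

test_that("cohorts round-trip through the directory format", {
  co <- tiny_cohort(n = 3, seed = 51)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.json")))
  expect_true(file.exists(file.path(dir, "events.csv")))
  back <- read_cohort(dir)

  expect_equal(back$events, co$events, tolerance = 1e-12)
  expect_equal(
    dplyr::arrange(back$raters, patient_id, subscore, rater),
    dplyr::arrange(co$raters, patient_id, subscore, rater) |>
      dplyr::mutate(rater = as.integer(rater), value = as.integer(value)),
    tolerance = 1e-12, ignore_attr = TRUE)
  ord <- function(df) dplyr::arrange(df, patient_id, side, stride, pct)
  expect_equal(ord(back$angles), ord(co$angles), tolerance = 1e-12,
               ignore_attr = TRUE)
})
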