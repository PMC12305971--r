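test_that("expert masks reproduce the per-subscore feature counts", {
  sizes <- vapply(sms_subscores(), function(t) length(step1_mask(t)),
                  integer(1))
  expect_equal(unname(sizes[c("trunk", "leg", "arm", "speed",
                              "fluency", "stability")]),
               c(680L, 356L, 330L, 32L, 680L, 680L))
  # masks follow canonical order and keep the aid flags
  for (t in sms_subscores()) {
    m <- step1_mask(t)
    expect_identical(m, sms_feature_names()[sms_feature_names() %in% m])
    expect_true(all(c("cane", "afo") %in% m))
  }
  expect_error(step1_mask("sms"), "unknown target")
})

test_that("representative pairs minimize distance to the patient median", {
  # 1-D toy: pairs at 0, 0.1, 5 -> the 0.1 pair is nearest the median
  df <- tibble::tibble(patient_id = "a", pair = 1:3, f = c(0, 0.1, 5))
  rp <- representative_pairs(df, "f")
  expect_equal(rp$pair, 2)

  # a single pair is its own representative
  expect_equal(representative_pairs(df[1, ], "f")$pair, 1)

  # ties resolve to the lowest pair index
  df2 <- tibble::tibble(patient_id = "a", pair = 1:3, f = c(2, 2, 2))
  expect_equal(representative_pairs(df2, "f")$pair, 1)

  # brute-force scan oracle in 3 dimensions
  set.seed(13)
  for (i in 1:10) {
    d <- tibble::tibble(patient_id = rep(c("a", "b"), each = 5),
                        pair = rep(1:5, 2),
                        x = rnorm(10), y = rnorm(10), z = rnorm(10))
    rp <- representative_pairs(d, c("x", "y", "z"))
    zs <- scale(as.matrix(d[, c("x", "y", "z")]))
    for (p in c("a", "b")) {
      rows <- which(d$patient_id == p)
      med <- apply(zs[rows, ], 2, median)
      dist <- sqrt(colSums((t(zs[rows, ]) - med)^2))
      expect_equal(rp$pair[rp$patient_id == p], which.min(dist))
    }
  }
})

test_that("the Alexander-Govern test behaves at the extremes", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  r <- alexander_govern(g)
  expect_lt(r$statistic, 1e-12)
  expect_gt(r$p_value, 0.999)
  expect_equal(r$df, 1)

  set.seed(14)
  far <- list(rnorm(50, 0), rnorm(50, 5))
  expect_lt(alexander_govern(far)$p_value, 0.001)

  expect_error(alexander_govern(list(1:5)), "two")
  expect_error(alexander_govern(list(c(1, 1, 1), 1:5)), "zero-variance")
  expect_error(alexander_govern(list(1, 1:5)), "at least two observations")
})

test_that("the AG statistic matches scipy on random instances", {
  set.seed(15)
  inst <- lapply(1:25, function(i) {
    k <- sample(2:5, 1)
    lapply(seq_len(k), function(j) {
      rnorm(sample(5:30, 1), mean = rnorm(1, 0, 2), sd = runif(1, 0.5, 3))
    })
  })
  ref <- scipy_alexander_govern(inst)
  for (i in seq_along(inst)) {
    r <- alexander_govern(inst[[i]])
    expect_equal(r$statistic, ref$statistic[i], tolerance = 1e-8)
    expect_equal(r$p_value, ref$p_value[i], tolerance = 1e-8)
  }
})

test_that("the step-2 filter keeps separators and drops flat features", {
  set.seed(16)
  n <- 40
  lab <- rep(0:3, each = 10)
  df <- tibble::tibble(
    patient_id = sprintf("p%02d", 1:n), pair = 1L, leg = lab,
    flat = rep(5, n),                       # constant: zero-variance groups
    same = rnorm(n),                        # label-independent noise
    sep = lab + rnorm(n, 0, 0.01))          # near-perfect separator
  out <- step2_filter(df, "leg", c("flat", "same", "sep"), alpha = 0.05)
  expect_true("sep" %in% out$selected)
  expect_false("flat" %in% out$selected)
  expect_equal(out$report$note[out$report$feature == "flat"],
               "zero-variance group")

  # idempotence: re-filtering the retained set returns the same set
  out2 <- step2_filter(df, "leg", out$selected, alpha = 0.05)
  expect_identical(out2$selected, out$selected)

  # a single usable group skips the filter
  df1 <- df
  df1$leg <- 0
  expect_warning(out3 <- step2_filter(df1, "leg", c("same", "sep")),
                 "skipped")
  expect_identical(out3$selected, c("same", "sep"))
})

test_that("selection enriches the features the generator actually couples", {
  # couple the leg severity into the lower-body angle shapes only:
  # independent severities, no stance asymmetry or stride-length penalty,
  # so the gait parameters carry no leg signal
  cfg <- sim_config(n_patients = 50, seed = 17, severity_cor = 0,
                    coupling = list(stance_asym = 0, leg_length_penalty = 0))
  co <- simulate_cohort(cfg)
  ds <- assemble_dataset(extract_features(co), seed = 17)
  sel <- select_features(ds, "leg", alpha = 0.05)
  expect_true(all(sel$selected %in% sel$mask))
  # coupled = lower-body characterizations + the AFO flag (logistic in the
  # leg severity); hypergeometric tail test of retention enrichment
  coupled <- grepl("^(knee|hip|ankle|pelvis|foot)", sel$mask) |
    sel$mask == "afo"
  retained <- sel$mask %in% sel$selected
  p <- phyper(sum(coupled & retained) - 1, sum(coupled), sum(!coupled),
              sum(retained), lower.tail = FALSE)
  expect_lt(p, 0.01)
})
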