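test_that("pairing couples each ipsilateral stride with the contralateral one starting within it", {
  # toy sequence i1 c1 i2 c2: enumeration gives exactly (i1,c1), (i2,c2)
  ev <- dplyr::bind_rows(
    make_event(0.0, 0.6, 1.0), make_event(0.5, 1.1, 1.5),
    make_event(1.0, 1.6, 2.0), make_event(1.5, 2.1, 2.5))
  ev$patient_id <- "A"
  ev$side <- c("ipsi", "contra", "ipsi", "contra")
  ev$stride <- c(1L, 1L, 2L, 2L)
  co <- structure(list(events = ev), class = "sms_cohort")
  pairs <- build_stride_pairs(co)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$ipsi_stride, c(1, 2))
  expect_equal(pairs$contra_stride, c(1, 2))

  # a single ipsilateral stride pairs with nothing
  solo <- ev[1, ]
  co2 <- structure(list(events = solo), class = "sms_cohort")
  expect_warning(p2 <- build_stride_pairs(co2), "dropped")
  expect_equal(nrow(p2), 0)
})

test_that("simulated cohorts yield one pair per contralateral stride", {
  co <- tiny_cohort(n = 6, seed = 71)
  pairs <- build_stride_pairs(co)
  per_patient <- dplyr::count(pairs, patient_id)
  expect_equal(per_patient$n,
               co$patients$n_strides[match(per_patient$patient_id,
                                           co$patients$patient_id)])
})

test_that("the stratified split allocates patients, not pairs", {
  # 10 patients at SMS 0 and 10 at SMS 9 -> exactly 3 test patients each
  df <- tibble::tibble(patient_id = sprintf("P%02d", 1:20),
                       sms = rep(c(0, 9), each = 10))
  sp <- stratified_patient_split(df, 0.30, seed = 5)
  tab <- table(df$sms[match(sp$patient_id[sp$split == "test"],
                            df$patient_id)])
  expect_equal(unname(c(tab)), c(3L, 3L))

  # determinism and disjointness
  sp2 <- stratified_patient_split(df, 0.30, seed = 5)
  expect_identical(sp, sp2)
  expect_false(any(duplicated(sp$patient_id)))

  # singleton strata stay in training
  df3 <- tibble::tibble(patient_id = c("A", "B", "C", "D", "E"),
                        sms = c(5, 1, 1, 1, 1))
  sp3 <- stratified_patient_split(df3, 0.30, seed = 1)
  expect_equal(sp3$split[sp3$patient_id == "A"], "train")
})

test_that("the test fraction lands near 0.30 on a synthetic cohort", {
  co <- simulate_cohort(sim_config(n_patients = 100, seed = 81))
  feats <- dplyr::left_join(
    build_stride_pairs(co)[, c("patient_id", "pair")],
    board_scores(co$raters), by = "patient_id")
  sp <- stratified_patient_split(feats, 0.30, seed = 2)
  frac <- mean(sp$split == "test")
  expect_gte(frac, 0.25)
  expect_lte(frac, 0.35)
  # every patient's pairs share one flag by construction (one flag per id)
  expect_equal(nrow(sp), length(unique(feats$patient_id)))
})

test_that("weights reproduce the printed formula", {
  # labels {0: 6 pairs, 3: 2 pairs}; a label-3 pair of a 2-pair patient
  df <- tibble::tibble(
    patient_id = c(rep("a", 3), rep("b", 3), rep("c", 2)),
    leg = c(rep(0, 6), rep(3, 2)))
  w <- compute_weights(df, "leg")
  expect_equal(w[7], (6 / 2) / 2)
  expect_equal(w[1], (6 / 6) / 3)

  # perfectly balanced labels, one pair per patient: all weights 1
  df2 <- tibble::tibble(patient_id = letters[1:6], leg = rep(0:2, each = 2))
  expect_equal(compute_weights(df2, "leg"), rep(1, 6))
})

test_that("weights equalize patient mass within a class and class mass when pairs per patient are constant", {
  set.seed(9)
  for (rep in 1:10) {
    # labels constant within patient, constant pairs per patient
    n_pat <- sample(6:12, 1)
    m <- sample(2:5, 1)
    lab <- sample(0:3, n_pat, replace = TRUE, prob = c(.4, .3, .2, .1))
    df <- tibble::tibble(
      patient_id = rep(sprintf("p%02d", 1:n_pat), each = m),
      leg = rep(lab, each = m))
    w <- compute_weights(df, "leg")
    mass <- tapply(w, df$leg, sum)
    expect_equal(max(mass) - min(mass), 0, tolerance = 1e-12)

    # irregular pairs per patient: per-patient mass within a class is
    # Nmax / N_s, identical for all patients of that class
    sizes <- sample(1:6, n_pat, replace = TRUE)
    df3 <- tibble::tibble(
      patient_id = rep(sprintf("p%02d", 1:n_pat), times = sizes),
      leg = rep(lab, times = sizes))
    w3 <- compute_weights(df3, "leg")
    pm <- tapply(w3, df3$patient_id, sum)
    n_s <- table(df3$leg)
    expected <- max(n_s) / n_s[as.character(lab)]
    expect_equal(unname(pm[sprintf("p%02d", 1:n_pat)]), unname(expected))

    # the class-balance factor alone has equal class mass on any dataset
    bal <- as.numeric(max(n_s) / n_s[as.character(df3$leg)])
    bal_mass <- tapply(bal, df3$leg, sum)
    expect_equal(max(bal_mass) - min(bal_mass), 0, tolerance = 1e-9)
  }
})

test_that("assembled datasets carry split flags and positive training weights", {
  co <- tiny_cohort(n = 10, seed = 91)
  ds <- assemble_dataset(extract_features(co), seed = 7)
  expect_true(all(c("split", paste0("weight_", c(sms_subscores(), "sms")))
                  %in% names(ds)))
  by_patient <- tapply(ds$split, ds$patient_id,
                       function(x) length(unique(x)))
  expect_true(all(by_patient == 1))
  train <- ds$split == "train"
  expect_true(all(ds$weight_sms[train] > 0))
  expect_true(all(is.na(ds$weight_sms[!train])))
})
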