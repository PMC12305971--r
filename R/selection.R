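#' Expert-knowledge feature mask for a subscore (selection step 1)
#'
#' Trims the 680-entry feature vector for each subscore according to its
#' functional definition: Trunk, Fluency, and Stability keep all 680
#' features; Speed keeps the 30 gait parameters plus the two aid flags
#' (32); Arm keeps gait speed and cadence, the trunk/upper-limb angle
#' characterizations (thorax, spine, shoulder, elbow), and the aid flags
#' (330); Leg keeps all 30 gait parameters, the lower-body angle
#' characterizations (pelvis, foot, hip, knee, ankle), and the aid flags
#' (356).
#'
#' @param target one of the six subscores (see [sms_subscores()]).
#' @return character vector of feature names, canonical order.
#' @export
step1_mask <- function(target) {
  all_names <- sms_feature_names()
  params <- grep(paste0("^(", paste(sms_gait_parameters(), collapse = "|"),
                        ")_(ipsi|contra)$"), all_names, value = TRUE)
  aids <- c("cane", "afo")
  keep <- switch(
    target,
    trunk = , fluency = , stability = all_names,
    speed = c(params, aids),
    leg = c(params,
            .char_names_side(.sms_leg_angles, "ipsi"),
            .char_names_side(.sms_leg_angles, "contra"),
            aids),
    arm = c(grep("^(gait_speed|cadence)_(ipsi|contra)$", all_names,
                 value = TRUE),
            .char_names_side(.sms_arm_angles, "ipsi"),
            .char_names_side(.sms_arm_angles, "contra"),
            aids),
    stop("unknown target: ", target, call. = FALSE)
  )
  all_names[all_names %in% keep]
}

#' Representative stride pair per patient
#'
#' Chooses one "most typical" stride pair per patient: features are
#' z-scored with the supplied set's statistics, and the pair minimizing
#' the Euclidean distance to the patient's component-wise median vector
#' is selected (ties go to the lowest pair index). Constant features
#' contribute nothing to the distance.
#'
#' @param data data frame of stride pairs (`patient_id`, `pair`, feature
#'   columns), typically the training rows.
#' @param feature_cols feature columns over which the distance is taken.
#' @return tibble `patient_id`, `pair` with one row per patient.
#' @export
representative_pairs <- function(data, feature_cols) {
  x <- as.matrix(data[, feature_cols, drop = FALSE])
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- Inf  # constant features drop out
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")

  data |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(g, key) {
      zz <- z[g$.row, , drop = FALSE]
      med <- apply(zz, 2, stats::median)
      d <- sqrt(rowSums(sweep(zz, 2, med)^2))
      tibble::tibble(pair = g$pair[which.min(d)])
    }) |>
    dplyr::ungroup()
}

#' Alexander-Govern heteroscedastic one-way test
#'
#' Tests equality of k group means without assuming equal variances: each
#' group contributes a t statistic of its mean against the
#' variance-weighted grand mean, normalized to an approximate standard
#' normal deviate via Hill's transformation; the statistic is the sum of
#' the squared deviates, referred to a chi-square distribution with k-1
#' degrees of freedom.
#'
#' @param x numeric values, or a list of numeric group samples.
#' @param g group labels (ignored when `x` is a list).
#' @return tibble with `statistic`, `df`, `p_value`, `k`.
#' @export
alexander_govern <- function(x, g = NULL) {
  groups <- if (is.list(x)) x else split(x, g)
  groups <- groups[lengths(groups) > 0]
  k <- length(groups)
  if (k < 2) stop("need at least two non-empty groups", call. = FALSE)
  n <- lengths(groups)
  if (any(n < 2))
    stop("every group needs at least two observations", call. = FALSE)
  v <- vapply(groups, stats::var, numeric(1))
  if (any(v == 0)) stop("zero-variance group", call. = FALSE)
  m <- vapply(groups, mean, numeric(1))

  se2 <- v / n
  w <- (1 / se2) / sum(1 / se2)
  grand <- sum(w * m)
  t_stat <- (m - grand) / sqrt(se2)

  nu <- n - 1
  a <- nu - 0.5
  b <- 48 * a^2
  cc <- sqrt(a * log1p(t_stat^2 / nu))
  z <- cc + (cc^3 + 3 * cc) / b -
    (4 * cc^7 + 33 * cc^5 + 240 * cc^3 + 855 * cc) /
    (10 * b^2 + 8 * b * cc^4 + 1000 * b)
  A <- sum(z^2)

  tibble::tibble(
    statistic = A, df = k - 1,
    p_value = stats::pchisq(A, k - 1, lower.tail = FALSE),
    k = k
  )
}

#' Alexander-Govern filter on representative pairs (selection step 2)
#'
#' Groups one representative stride pair per training patient by the
#' board-assigned subscore level and retains, from the step-1 mask, the
#' features whose Alexander-Govern p-value falls below `alpha`. Label
#' groups with fewer than two pairs are dropped from the test; features
#' with a zero-variance group are excluded from testing and flagged in the
#' report. With fewer than two usable groups the filter is skipped with a
#' warning and the mask is returned unchanged.
#'
#' @param rep_data data frame with one representative pair per patient:
#'   the label column named by `target` and the masked feature columns.
#' @param target subscore name (label column).
#' @param mask character vector of candidate feature names.
#' @param alpha retention threshold on the p-value (default 0.05, no
#'   multiplicity correction).
#' @return list with `selected` (character, canonical order) and `report`
#'   (tibble: feature, statistic, df, p_value, retained, note).
#' @export
step2_filter <- function(rep_data, target, mask, alpha = 0.05) {
  lab <- rep_data[[target]]
  sizes <- table(lab)
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < length(sizes))
    message("dropping label group(s) with a single representative pair: ",
            paste(setdiff(names(sizes), usable), collapse = ", "))
  keep_rows <- lab %in% usable
  if (length(usable) < 2) {
    warning("fewer than two usable label groups; step-2 filter skipped",
            call. = FALSE)
    return(list(selected = mask,
                report = tibble::tibble(feature = character(),
                                        statistic = numeric(),
                                        df = integer(), p_value = numeric(),
                                        retained = logical(),
                                        note = character())))
  }
  lab <- lab[keep_rows]

  rows <- lapply(mask, function(f) {
    x <- rep_data[[f]][keep_rows]
    vs <- vapply(split(x, lab), stats::var, numeric(1))
    if (any(vs == 0)) {
      return(tibble::tibble(feature = f, statistic = NA_real_,
                            df = NA_integer_, p_value = NA_real_,
                            retained = FALSE, note = "zero-variance group"))
    }
    r <- alexander_govern(x, lab)
    tibble::tibble(feature = f, statistic = r$statistic,
                   df = as.integer(r$df), p_value = r$p_value,
                   retained = r$p_value < alpha, note = NA_character_)
  })
  report <- dplyr::bind_rows(rows)
  list(selected = report$feature[report$retained], report = report)
}

#' Two-step feature selection for one subscore
#'
#' Applies the expert mask ([step1_mask()]), picks the representative
#' stride pair of every training patient ([representative_pairs()], in
#' z-score space over the masked features), and filters the mask with the
#' Alexander-Govern test ([step2_filter()]).
#'
#' @param dataset assembled dataset from [assemble_dataset()] (the
#'   training rows are used).
#' @param target one of the six subscores.
#' @param alpha step-2 retention threshold.
#' @return list with `selected`, `report`, `representatives`, `mask`.
#' @export
select_features <- function(dataset, target, alpha = 0.05) {
  train <- dataset[dataset$split == "train", ]
  mask <- step1_mask(target)
  reps <- representative_pairs(train, mask)
  rep_rows <- dplyr::semi_join(
    dplyr::mutate(train, .key = paste(.data$patient_id, .data$pair)),
    dplyr::mutate(reps, .key = paste(.data$patient_id, .data$pair)),
    by = ".key"
  )
  out <- step2_filter(rep_rows, target, mask, alpha)
  c(out, list(representatives = reps, mask = mask))
}
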