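#' Clip predictions to a score's definition range
#'
#' @param x numeric predictions.
#' @param lo,hi range bounds (0-3 for a subscore, 0-18 for the SMS).
#' @return `x` cut to the nearest boundary; idempotent and non-decreasing.
#' @export
clip_score <- function(x, lo = 0, hi = 3) pmin(pmax(x, lo), hi)

#' Patient-level subscore prediction
#'
#' Averages a model's pair-level outputs across one patient's stride
#' pairs, then cuts the mean to the subscore's definition range [0, 3].
#'
#' @param model a fitted `sms_model` (or anything with a `predict`
#'   method over the feature columns).
#' @param pairs data frame with the patient's stride-pair feature rows.
#' @return a single clipped prediction.
#' @export
predict_patient <- function(model, pairs) {
  if (!nrow(pairs)) stop("no stride pairs for patient", call. = FALSE)
  clip_score(mean(predict(model, pairs)), 0, 3)
}

#' Compose an SMS prediction from subscore predictions
#'
#' @param subscores numeric vector of the six patient-level subscore
#'   predictions (clipped to [0, 3] if they are not already).
#' @return their sum, guaranteed within [0, 18].
#' @export
predict_sms <- function(subscores) {
  if (length(subscores) != 6L || any(is.na(subscores)))
    stop("need all six subscore predictions", call. = FALSE)
  sum(clip_score(subscores, 0, 3))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` against the mean of the observations; may be
#' negative; `NA` (with a warning) when the observations have zero
#' variance.
#'
#' @param obs,pred numeric vectors of equal length (>= 2).
#' @return real number <= 1.
#' @export
r_squared <- function(obs, pred) {
  if (length(obs) < 2) stop("need at least two observations", call. = FALSE)
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) {
    warning("zero variance in observations; R-squared undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 - sum((obs - pred)^2) / ss_tot
}

#' One-way random-effects single-rater ICC
#'
#' ICC(1,1): `(MSB - MSW) / (MSB + (k - 1) MSW)` with MSB/MSW the
#' between- and within-patient mean squares of a one-way ANOVA over the
#' patients-by-raters matrix.
#'
#' @param ratings numeric matrix, patients in rows, raters in columns.
#' @return the ICC estimate.
#' @export
icc_1_1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2) stop("need at least two patients", call. = FALSE)
  if (k < 2) stop("need at least two raters", call. = FALSE)
  row_m <- rowMeans(ratings)
  grand <- mean(ratings)
  msb <- k * sum((row_m - grand)^2) / (n - 1)
  msw <- sum((ratings - row_m)^2) / (n * (k - 1))
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Inter-rater reliability of the rater panels
#'
#' ICC(1,1) per subscore (patients x 5 raters on the raw recommendations)
#' and for the total SMS (each rater's six-subscore sum per patient).
#'
#' @param raters rater table (`patient_id`, `subscore`, `rater`, `value`).
#' @return tibble `target`, `icc`.
#' @export
icc_panels <- function(raters) {
  wide <- function(df) {
    m <- tidyr::pivot_wider(df, id_cols = "patient_id",
                            names_from = "rater", values_from = "value")
    as.matrix(m[, -1])
  }
  rows <- lapply(sms_subscores(), function(s) {
    tibble::tibble(target = s,
                   icc = icc_1_1(wide(raters[raters$subscore == s, ])))
  })
  sums <- raters |>
    dplyr::group_by(.data$patient_id, .data$rater) |>
    dplyr::summarise(value = sum(.data$value), .groups = "drop")
  dplyr::bind_rows(rows,
                   tibble::tibble(target = "sms", icc = icc_1_1(wide(sums))))
}

# R-squared that degrades to NA (with a warning) on degenerate test sets
.safe_r2 <- function(obs, pred) {
  if (length(obs) < 2) {
    warning("fewer than two test patients; R-squared undefined",
            call. = FALSE)
    return(NA_real_)
  }
  r_squared(obs, pred)
}

# patient-level clipped predictions of one model over a dataset slice
.patient_predictions <- function(model, data) {
  data |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ tibble::tibble(
      prediction = predict_patient(model, .x))) |>
    dplyr::ungroup()
}

#' Evaluate trained subscore models at patient level
#'
#' For every fitted model: pair-level predictions are averaged per patient
#' and clipped to [0, 3]; for each family with all six subscore models the
#' SMS prediction is their sum. Test-set performance is the unweighted
#' patient-level R-squared against the board values; per-patient scatter
#' data for both splits is returned alongside. When a rater table is
#' supplied the ICC(1,1) column is added per target.
#'
#' @param models list of `sms_model` objects (any mix of targets and
#'   families).
#' @param dataset assembled dataset (with `split` and board labels).
#' @param raters optional rater table for the ICC column.
#' @return object of class `sms_evaluation`: list with `metrics` (tibble
#'   target, family, r2, n_test_patients, icc) and `scatter` (tibble
#'   target, family, dataset, patient_id, board, prediction).
#' @export
evaluate_models <- function(models, dataset, raters = NULL) {
  metrics <- list()
  scatter <- list()
  fam_preds <- list()  # family -> target -> patient predictions (test+train)

  for (model in models) {
    for (sp in c("train", "test")) {
      slice <- dataset[dataset$split == sp, ]
      preds <- .patient_predictions(model, slice)
      board <- dplyr::distinct(slice, .data$patient_id,
                               board = .data[[model$target]])
      sc <- dplyr::left_join(preds, board, by = "patient_id")
      scatter[[length(scatter) + 1L]] <- tibble::tibble(
        target = model$target, family = model$family, dataset = sp,
        patient_id = sc$patient_id, board = as.numeric(sc$board),
        prediction = sc$prediction
      )
      if (sp == "test") {
        metrics[[length(metrics) + 1L]] <- tibble::tibble(
          target = model$target, family = model$family,
          r2 = .safe_r2(sc$board, sc$prediction),
          n_test_patients = nrow(sc)
        )
      }
      fam_preds[[model$family]][[sp]][[model$target]] <- sc
    }
  }

  # composed SMS per family, when all six subscores are present
  for (fam in names(fam_preds)) {
    for (sp in c("train", "test")) {
      byt <- fam_preds[[fam]][[sp]]
      if (!all(sms_subscores() %in% names(byt))) next
      agg <- dplyr::bind_rows(byt[sms_subscores()], .id = "target") |>
        dplyr::group_by(.data$patient_id) |>
        dplyr::summarise(prediction = predict_sms(.data$prediction),
                         .groups = "drop")
      board <- dplyr::distinct(dataset[dataset$split == sp, ],
                               .data$patient_id, board = .data$sms)
      sc <- dplyr::left_join(agg, board, by = "patient_id")
      scatter[[length(scatter) + 1L]] <- tibble::tibble(
        target = "sms", family = fam, dataset = sp,
        patient_id = sc$patient_id, board = as.numeric(sc$board),
        prediction = sc$prediction
      )
      if (sp == "test") {
        metrics[[length(metrics) + 1L]] <- tibble::tibble(
          target = "sms", family = fam,
          r2 = .safe_r2(sc$board, sc$prediction),
          n_test_patients = nrow(sc)
        )
      }
    }
  }

  metrics <- dplyr::bind_rows(metrics)
  if (!is.null(raters))
    metrics <- dplyr::left_join(metrics, icc_panels(raters), by = "target")

  structure(
    list(metrics = metrics, scatter = dplyr::bind_rows(scatter)),
    class = "sms_evaluation"
  )
}

#' @export
print.sms_evaluation <- function(x, ...) {
  cat("<sms_evaluation>\n")
  print(x$metrics)
  invisible(x)
}
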