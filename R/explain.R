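#' Permutation feature importance
#'
#' Estimates each input feature's importance to a fitted model as the mean
#' degradation of the pair-level R-squared when that feature's column is
#' randomly shuffled (globally, across all rows), over a number of
#' repetitions. A feature the model provably ignores (for a decision tree,
#' any feature appearing in no split) has importance exactly 0 and is not
#' resampled.
#'
#' @param model a fitted `sms_model` (or `sms_dt` / `sms_mlp`).
#' @param data data frame of stride pairs holding the model's feature
#'   columns and the label column.
#' @param target label column name (defaults to the model's target).
#' @param reps shuffling repetitions (default 500).
#' @param seed integer seed for the shuffles.
#' @return tibble `feature`, `importance`, `se`, `side`, sorted by
#'   descending importance (ties in canonical feature order), with
#'   attributes `baseline_r2` and `reps`.
#' @export
permutation_importance <- function(model, data, target = NULL, reps = 500L,
                                   seed = 1L) {
  features <- if (inherits(model, "sms_model")) model$features
              else model$features
  if (is.null(target)) {
    if (!inherits(model, "sms_model"))
      stop("supply `target` for a bare predictor", call. = FALSE)
    target <- model$target
  }
  if (nrow(data) < 2) stop("need at least two pairs", call. = FALSE)
  y <- data[[target]]
  x <- as.matrix(data[, features, drop = FALSE])
  baseline <- r_squared(y, predict(model, as.data.frame(x)))

  # features a tree never splits on cannot change its predictions
  inert <- rep(FALSE, length(features))
  dt <- if (inherits(model, "sms_dt")) model
        else if (inherits(model, "sms_model") &&
                 inherits(model$fit, "sms_dt")) model$fit
  if (!is.null(dt)) {
    used <- unique(dt$tree$feature[dt$tree$feature >= 0]) + 1L
    inert <- !(seq_along(features) %in% used)
  }

  imp <- numeric(length(features))
  se <- numeric(length(features))
  withr_seed(seed, {
    for (j in seq_along(features)) {
      if (inert[j]) next
      drops <- vapply(seq_len(reps), function(r) {
        xs <- x
        xs[, j] <- xs[sample.int(nrow(xs)), j]
        baseline - r_squared(y, predict(model, as.data.frame(xs)))
      }, numeric(1))
      imp[j] <- mean(drops)
      se[j] <- stats::sd(drops) / sqrt(reps)
    }
  })

  ord <- order(-imp, seq_along(features))
  out <- tibble::tibble(
    feature = features[ord], importance = imp[ord], se = se[ord],
    side = sms_feature_side(features[ord])
  )
  attr(out, "baseline_r2") <- baseline
  attr(out, "reps") <- reps
  out
}

#' Ipsilateral/contralateral share of key features
#'
#' Summarizes an importance ranking's top features by body side (the two
#' aid flags carry no side and are excluded from the denominator).
#'
#' @param importance tibble from [permutation_importance()] or
#'   [dt_importance()] (a `side` column is added if absent).
#' @param top_n number of top-ranked features to summarize (default all
#'   with positive importance).
#' @return tibble `side`, `n`, `share`.
#' @export
side_share <- function(importance, top_n = NULL) {
  df <- importance
  if (!"side" %in% names(df)) df$side <- sms_feature_side(df$feature)
  df <- df[df$importance > 0, ]
  if (!is.null(top_n)) df <- utils::head(df, top_n)
  df <- df[!is.na(df$side), ]
  df |>
    dplyr::count(.data$side, name = "n") |>
    dplyr::mutate(share = .data$n / sum(.data$n))
}
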