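#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the cross-validation table of a fitted score model
#'
#' @param x an `sms_model`.
#' @param ... unused.
#' @return tibble with one row per evaluated grid cell (hyperparameters
#'   plus `cv_r2`), in evaluation order.
#' @method tidy sms_model
#' @export
tidy.sms_model <- function(x, ...) {
  g <- x$cv_table
  if ("hidden" %in% names(g))
    g$hidden <- vapply(g$hidden, function(h) paste(h, collapse = "-"),
                       character(1))
  tibble::as_tibble(g)
}

#' One-row summary of a fitted score model
#'
#' @param x an `sms_model`.
#' @param ... unused.
#' @return one-row tibble: target, family, chosen hyperparameters, number
#'   of selected features, CV mean R-squared, seed.
#' @method glance sms_model
#' @export
glance.sms_model <- function(x, ...) {
  hp <- x$hyperparameters
  if ("hidden" %in% names(hp))
    hp$hidden <- vapply(hp$hidden, function(h) paste(h, collapse = "-"),
                        character(1))
  dplyr::bind_cols(
    tibble::tibble(target = x$target, family = x$family),
    tibble::as_tibble(hp),
    tibble::tibble(n_features = length(x$features),
                   cv_r2 = x$cv_r2, seed = x$seed)
  )
}

#' Tidy a fitted decision tree into one row per node
#'
#' @param x an `sms_dt`.
#' @param ... unused.
#' @return tibble: node, depth, feature (NA for leaves), threshold,
#'   n, weight_fraction, prediction, improvement.
#' @method tidy sms_dt
#' @export
tidy.sms_dt <- function(x, ...) {
  tr <- x$tree
  tibble::tibble(
    node = seq_along(tr$feature) - 1L,
    depth = tr$depth,
    feature = ifelse(tr$feature >= 0, x$features[tr$feature + 1L],
                     NA_character_),
    threshold = ifelse(tr$feature >= 0, tr$threshold, NA_real_),
    n = tr$n,
    weight_fraction = tr$weight / tr$total_weight,
    prediction = tr$value,
    improvement = tr$improvement
  )
}

#' @method glance sms_dt
#' @export
glance.sms_dt <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$tree$feature),
    n_splits = sum(x$tree$feature >= 0),
    depth = max(x$tree$depth),
    max_depth = x$hp$max_depth,
    splitter = x$hp$splitter
  )
}

#' Tidy an evaluation report
#'
#' @param x an `sms_evaluation`.
#' @param ... unused.
#' @return the metrics tibble (target, family, test R-squared, ICC when
#'   available).
#' @method tidy sms_evaluation
#' @export
tidy.sms_evaluation <- function(x, ...) x$metrics

#' @method glance sms_evaluation
#' @export
glance.sms_evaluation <- function(x, ...) {
  tidyr::pivot_wider(x$metrics[, c("target", "family", "r2")],
                     names_from = "family", values_from = "r2",
                     names_prefix = "r2_")
}
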