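#' Hyperparameter grids of the two model families
#'
#' The decision-tree grid crosses the max-features rule (sqrt(n), n,
#' log2(n)), the split strategy (best, random), the minimum node weight
#' fraction (0.00-0.05 in steps of 0.01), and the maximum depth (3, 4, 5):
#' 108 cells. The MLP grid crosses the hidden architecture ({16, 8} or
#' {32, 16, 8}, ReLU units), the output activation (linear, ReLU), and the
#' Adam learning rate (1e-3, 1e-4, 1e-5): 12 cells, with a conditional
#' refinement — if 1e-5 wins, seven finer rates (7.5e-5 down to 2.5e-6)
#' are additionally scanned with the winning architecture and output
#' activation held fixed.
#'
#' @return a tibble with one row per grid cell.
#' @name grids
NULL

#' @rdname grids
#' @export
dt_grid <- function() {
  tidyr::expand_grid(
    max_features = c("sqrt", "all", "log2"),
    splitter = c("best", "random"),
    min_weight_fraction = seq(0, 0.05, by = 0.01),
    max_depth = 3:5
  )
}

#' @rdname grids
#' @export
mlp_grid <- function() {
  tidyr::expand_grid(
    hidden = list(c(16L, 8L), c(32L, 16L, 8L)),
    output_activation = c("linear", "relu"),
    learning_rate = c(1e-3, 1e-4, 1e-5)
  )
}

# the conditional fine learning-rate scan
.mlp_refinement_rates <- c(7.5e-5, 5e-5, 2.5e-5, 1e-5, 7.5e-6, 5e-6, 2.5e-6)

# label-stratified fold assignment at stride-pair level
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(sample.int(k), length(idx))
  }
  fold
}

# fit one model family with one hyperparameter cell
.fit_family <- function(family, x, y, w, hp, seed, mlp_control) {
  if (family == "dt") {
    fit_dt(x, y, w,
           max_features = hp$max_features, splitter = hp$splitter,
           min_weight_fraction = hp$min_weight_fraction,
           max_depth = hp$max_depth, seed = seed)
  } else {
    fit_mlp(x, y, w,
            hidden = hp$hidden[[1]],
            output_activation = hp$output_activation,
            learning_rate = hp$learning_rate,
            epochs = mlp_control$epochs,
            batch_size = mlp_control$batch_size,
            seed = seed)
  }
}

#' Cross-validated score of one hyperparameter cell
#'
#' K-fold cross-validation over training stride pairs, stratified by the
#' target label at pair level. In every iteration the representative
#' stride pairs (used for feature selection) are removed from the held-out
#' fold and reinserted into the training side, so they never contribute to
#' a validation score; fitting uses the per-pair weights; the fold score
#' is the unweighted R-squared on the remaining held-out pairs, and the
#' cell score is the mean over folds. Folds left empty after reinsertion
#' are skipped with a warning.
#'
#' @param train training rows of an assembled dataset.
#' @param target subscore (or `"sms"`) label column.
#' @param family `"dt"` or `"mlp"`.
#' @param hp one-row tibble (a grid cell).
#' @param selected selected feature names.
#' @param rep_ids `patient_id`/`pair` tibble of representative pairs.
#' @param k number of folds.
#' @param seed integer; fold assignment and fits derive from it.
#' @param mlp_control list with `epochs`, `batch_size`.
#' @return mean validation R-squared across usable folds.
#' @export
cv_evaluate <- function(train, target, family, hp, selected, rep_ids,
                        k = 10L, seed = 1L,
                        mlp_control = list(epochs = 60L, batch_size = 32L)) {
  if (k < 2) stop("need k >= 2 folds", call. = FALSE)
  if (!length(selected)) stop("empty selected-feature set", call. = FALSE)
  y <- train[[target]]
  w <- train[[paste0("weight_", target)]]
  x <- as.matrix(train[, selected, drop = FALSE])
  is_rep <- paste(train$patient_id, train$pair) %in%
    paste(rep_ids$patient_id, rep_ids$pair)

  fold <- withr_seed(seed, .stratified_folds(y, k))
  scores <- numeric(0)
  for (i in seq_len(k)) {
    val <- which(fold == i & !is_rep)
    if (!length(val)) {
      warning("fold ", i, " empty after representative-pair reinsertion; skipped",
              call. = FALSE)
      next
    }
    if (length(val) < 2 || length(unique(y[val])) < 2) {
      warning("fold ", i, " has degenerate validation labels; skipped",
              call. = FALSE)
      next
    }
    tr <- setdiff(seq_len(nrow(x)), val)
    fit <- .fit_family(family, x[tr, , drop = FALSE], y[tr], w[tr], hp,
                       seed = seed + i, mlp_control = mlp_control)
    pred <- predict(fit, as.data.frame(x[val, , drop = FALSE]))
    scores <- c(scores, r_squared(y[val], pred))
  }
  mean(scores)
}

#' Grid-search a model for one subscore
#'
#' Evaluates every cell of the family's hyperparameter grid with
#' [cv_evaluate()] (including the MLP conditional learning-rate
#' refinement), picks the cell maximizing the mean cross-validation
#' R-squared (ties to the earlier cell), and refits it on the full
#' training set with the per-pair weights.
#'
#' @inheritParams cv_evaluate
#' @param grid optional grid override (defaults to [dt_grid()] /
#'   [mlp_grid()]).
#' @return an object of class `sms_model`: the fitted predictor plus the
#'   chosen hyperparameters, selected features, CV table, and seed.
#' @export
grid_search <- function(train, target, family = c("dt", "mlp"), selected,
                        rep_ids, k = 10L, seed = 1L,
                        mlp_control = list(epochs = 60L, batch_size = 32L),
                        grid = NULL) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- if (family == "dt") dt_grid() else mlp_grid()

  score_cells <- function(g, seed_off) {
    vapply(seq_len(nrow(g)), function(i) {
      cv_evaluate(train, target, family, g[i, ], selected, rep_ids,
                  k = k, seed = seed + seed_off * 10000L,
                  mlp_control = mlp_control)
    }, numeric(1))
  }
  grid$cv_r2 <- score_cells(grid, 0L)

  if (family == "mlp" && "learning_rate" %in% names(grid)) {
    best <- grid[which.max(grid$cv_r2), ]
    if (isTRUE(all.equal(best$learning_rate, 1e-5))) {
      fine <- best[rep(1, length(.mlp_refinement_rates)), ]
      fine$learning_rate <- .mlp_refinement_rates
      fine$cv_r2 <- score_cells(fine, 0L)
      grid <- dplyr::bind_rows(grid, fine)
    }
  }

  winner <- grid[which.max(grid$cv_r2), ]
  y <- train[[target]]
  w <- train[[paste0("weight_", target)]]
  x <- as.matrix(train[, selected, drop = FALSE])
  fit <- .fit_family(family, x, y, w, winner, seed = seed,
                     mlp_control = mlp_control)

  structure(
    list(target = target, family = family,
         hyperparameters = winner[, setdiff(names(winner), "cv_r2")],
         fit = fit, features = selected,
         cv_table = grid, cv_r2 = winner$cv_r2, seed = seed),
    class = "sms_model"
  )
}

#' @export
predict.sms_model <- function(object, newdata, ...) {
  predict(object$fit, newdata, ...)
}

#' @export
print.sms_model <- function(x, ...) {
  cat("<sms_model> target ", x$target, ", family ", x$family,
      ", ", length(x$features), " features, CV R2 ",
      format(x$cv_r2, digits = 3), "\n", sep = "")
  invisible(x)
}
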