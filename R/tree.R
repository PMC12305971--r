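#' Fit a weighted CART regression tree
#'
#' Greedy binary recursive partitioning minimizing the weighted squared
#' error, honouring the four tuned hyperparameters: the number of
#' candidate features per node (`max_features` rule), the split strategy
#' (`"best"` scans all cut points of each candidate feature; `"random"`
#' draws one uniform threshold per candidate feature and keeps the best of
#' those), the minimum weight fraction each child node must hold (relative
#' to the total training weight), and the maximum tree depth. Duplicating
#' a row is exactly equivalent to doubling its weight.
#'
#' @param x numeric feature matrix (columns named).
#' @param y numeric response.
#' @param weights positive case weights (default all 1).
#' @param max_features `"sqrt"`, `"all"`, or `"log2"`: candidate features
#'   per node as a function of the number of columns.
#' @param splitter `"best"` or `"random"`.
#' @param min_weight_fraction minimum child weight fraction in \[0, 0.5).
#' @param max_depth maximum number of splits along any path.
#' @param seed optional integer seed (feature subsampling and random
#'   thresholds draw from R's RNG).
#' @return an object of class `sms_dt`.
#' @export
fit_dt <- function(x, y, weights = NULL, max_features = "all",
                   splitter = "best", min_weight_fraction = 0,
                   max_depth = 5L, seed = NULL) {
  x <- as.matrix(x)
  if (!nrow(x)) stop("empty training data", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  p <- ncol(x)
  mf <- switch(match.arg(max_features, c("all", "sqrt", "log2")),
               all = p,
               sqrt = max(1L, floor(sqrt(p))),
               log2 = max(1L, floor(log2(p))))
  splitter <- match.arg(splitter, c("best", "random"))
  fit_call <- function() {
    cart_fit_cpp(x, as.numeric(y), as.numeric(weights),
                 as.integer(max_depth), min_weight_fraction,
                 as.integer(mf), splitter == "random")
  }
  tree <- if (is.null(seed)) fit_call() else withr_seed(seed, fit_call())
  structure(
    list(tree = tree, features = colnames(x),
         hp = list(max_features = max_features, splitter = splitter,
                   min_weight_fraction = min_weight_fraction,
                   max_depth = max_depth)),
    class = "sms_dt"
  )
}

#' @export
predict.sms_dt <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  cart_predict_cpp(object$tree, x)
}

#' @export
print.sms_dt <- function(x, ...) {
  n_split <- sum(x$tree$feature >= 0)
  cat("<sms_dt> ", n_split, " splits, depth <= ", x$hp$max_depth,
      ", splitter ", x$hp$splitter, "\n", sep = "")
  invisible(x)
}

#' Split-gain feature importance of a fitted tree
#'
#' Sums, per feature, the weighted squared-error reduction achieved over
#' all splits using that feature, normalized to total 1. Features never
#' used split nothing and get importance 0; a single-node tree yields an
#' empty ranking.
#'
#' @param tree an `sms_dt`.
#' @return tibble `feature`, `importance`, sorted descending (ties in
#'   canonical feature order).
#' @export
dt_importance <- function(tree) {
  stopifnot(inherits(tree, "sms_dt"))
  split <- tree$tree$feature >= 0
  if (!any(split))
    return(tibble::tibble(feature = character(), importance = numeric()))
  gains <- tapply(tree$tree$improvement[split],
                  tree$tree$feature[split] + 1L, sum)
  imp <- stats::setNames(numeric(length(tree$features)), tree$features)
  imp[as.integer(names(gains))] <- gains
  imp <- imp / sum(imp)
  ord <- order(-imp, seq_along(imp))
  tibble::tibble(feature = names(imp)[ord],
                 importance = unname(imp[ord]))
}

# nested-list form of a fitted tree
.tree_as_list <- function(tree, node = 1L) {
  tr <- tree$tree
  rec <- list(
    n = tr$n[node],
    weight_fraction = tr$weight[node] / tr$total_weight,
    prediction = tr$value[node]
  )
  if (tr$feature[node] >= 0) {
    rec$feature <- tree$features[tr$feature[node] + 1L]
    rec$threshold <- tr$threshold[node]
    rec$left <- .tree_as_list(tree, tr$left[node] + 1L)
    rec$right <- .tree_as_list(tree, tr$right[node] + 1L)
  }
  rec
}

#' Export a fitted tree as a structured document
#'
#' Renders the tree as a nested record per node (feature, threshold,
#' weighted sample fraction, prediction) plus Graphviz DOT text, for
#' inspection and plotting. The exported structure fully determines the
#' tree's predictions.
#'
#' @param tree an `sms_dt`.
#' @param json_path,dot_path optional output file paths.
#' @return list with `structure` (nested list), `json` (string), `dot`
#'   (string).
#' @export
export_tree <- function(tree, json_path = NULL, dot_path = NULL) {
  stopifnot(inherits(tree, "sms_dt"))
  nested <- .tree_as_list(tree)
  json <- jsonlite::toJSON(nested, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)

  tr <- tree$tree
  lines <- c("digraph cart {", "  node [shape=box];")
  for (i in seq_along(tr$feature)) {
    lab <- if (tr$feature[i] >= 0) {
      sprintf("%s <= %.4g\\nn=%d w=%.3f",
              tree$features[tr$feature[i] + 1L], tr$threshold[i],
              tr$n[i], tr$weight[i] / tr$total_weight)
    } else {
      sprintf("pred=%.3f\\nn=%d w=%.3f", tr$value[i], tr$n[i],
              tr$weight[i] / tr$total_weight)
    }
    lines <- c(lines, sprintf("  n%d [label=\"%s\"];", i - 1L, lab))
    if (tr$feature[i] >= 0) {
      lines <- c(lines,
                 sprintf("  n%d -> n%d [label=\"yes\"];", i - 1L, tr$left[i]),
                 sprintf("  n%d -> n%d [label=\"no\"];", i - 1L, tr$right[i]))
    }
  }
  dot <- paste(c(lines, "}"), collapse = "\n")

  if (!is.null(json_path)) writeLines(json, json_path)
  if (!is.null(dot_path)) writeLines(dot, dot_path)
  list(structure = nested, json = as.character(json), dot = dot)
}
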