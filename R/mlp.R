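#' Fit a multilayer perceptron regressor
#'
#' Fully connected feed-forward network with ReLU hidden units and a
#' linear or ReLU output unit, trained on the weighted squared error with
#' the Adam optimizer. Inputs are z-scored with the training statistics
#' (stored in the fit and reapplied at prediction); a fixed seed controls
#' the Glorot-uniform initialization and the mini-batch shuffling, making
#' training bit-reproducible.
#'
#' @param x numeric feature matrix (columns named).
#' @param y numeric response.
#' @param weights positive case weights (default all 1).
#' @param hidden integer vector of hidden-layer sizes, e.g. `c(16, 8)` or
#'   `c(32, 16, 8)`.
#' @param output_activation `"linear"` or `"relu"`.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param seed optional integer seed.
#' @return an object of class `sms_mlp` (weights, scaler, loss history).
#' @export
fit_mlp <- function(x, y, weights = NULL, hidden = c(16L, 8L),
                    output_activation = c("linear", "relu"),
                    learning_rate = 1e-3, epochs = 200L, batch_size = 32L,
                    seed = NULL) {
  output_activation <- match.arg(output_activation)
  x <- as.matrix(x)
  n <- nrow(x)
  if (!n) stop("empty training data", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- as.numeric(weights)

  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  y <- as.numeric(y)

  run <- function() .mlp_train(xs, y, weights, hidden, output_activation,
                               learning_rate, epochs, batch_size)
  fit <- if (is.null(seed)) run() else withr_seed(seed, run())

  structure(
    c(fit,
      list(features = colnames(x), center = center, scale = scale,
           hp = list(hidden = hidden, output_activation = output_activation,
                     learning_rate = learning_rate, epochs = epochs,
                     batch_size = batch_size))),
    class = "sms_mlp"
  )
}

.mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
                     sizes[l], sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b)
}

.mlp_forward <- function(par, x, output_activation) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1]] <- x
  for (l in seq_len(L)) {
    z <- A[[l]] %*% par$W[[l]] +
      matrix(par$b[[l]], nrow(A[[l]]), length(par$b[[l]]), byrow = TRUE)
    A[[l + 1]] <- if (l < L || output_activation == "relu") pmax(z, 0) else z
  }
  A
}

.mlp_train <- function(xs, y, w, hidden, output_activation, lr, epochs,
                       batch_size) {
  n <- nrow(xs)
  sizes <- c(ncol(xs), hidden, 1L)
  par <- .mlp_init(sizes)
  L <- length(par$W)
  adam_m <- lapply(c(par$W, par$b), function(p) p * 0)
  adam_v <- adam_m
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_hist <- numeric(epochs)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    ep_loss <- 0; ep_w <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      xb <- xs[idx, , drop = FALSE]
      yb <- y[idx]
      wb <- w[idx]

      A <- .mlp_forward(par, xb, output_activation)
      pred <- A[[L + 1]][, 1]
      resid <- pred - yb
      sw <- sum(wb)
      loss <- sum(wb * resid^2) / sw
      if (!is.finite(loss))
        stop("MLP training diverged at learning rate ", lr, call. = FALSE)
      ep_loss <- ep_loss + loss * sw; ep_w <- ep_w + sw

      # backprop, weighted MSE
      delta <- matrix(2 * wb * resid / sw, ncol = 1)
      if (output_activation == "relu")
        delta <- delta * (A[[L + 1]] > 0)
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in L:1) {
        gW[[l]] <- crossprod(A[[l]], delta)
        gb[[l]] <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(par$W[[l]])) * (A[[l]] > 0)
        }
      }

      step <- step + 1L
      grads <- c(gW, gb)
      params <- c(par$W, par$b)
      for (j in seq_along(params)) {
        adam_m[[j]] <- beta1 * adam_m[[j]] + (1 - beta1) * grads[[j]]
        adam_v[[j]] <- beta2 * adam_v[[j]] + (1 - beta2) * grads[[j]]^2
        mhat <- adam_m[[j]] / (1 - beta1^step)
        vhat <- adam_v[[j]] / (1 - beta2^step)
        params[[j]] <- params[[j]] - lr * mhat / (sqrt(vhat) + eps)
      }
      par$W <- params[seq_len(L)]
      par$b <- params[L + seq_len(L)]
    }
    loss_hist[ep] <- ep_loss / ep_w
  }
  list(W = par$W, b = par$b, loss = loss_hist)
}

#' @export
predict.sms_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  A <- .mlp_forward(object[c("W", "b")], xs,
                    object$hp$output_activation)
  A[[length(A)]][, 1]
}

#' @export
print.sms_mlp <- function(x, ...) {
  cat("<sms_mlp> hidden [", paste(x$hp$hidden, collapse = ", "),
      "], output ", x$hp$output_activation,
      ", lr ", format(x$hp$learning_rate),
      ", final loss ", format(utils::tail(x$loss, 1), digits = 4), "\n",
      sep = "")
  invisible(x)
}
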