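#' Sigmoid transfer functions
#'
#' `tansig` is the hyperbolic tangent sigmoid `2 / (1 + exp(-2n)) - 1`
#' (range `(-1, 1)`), used for hidden layers; `logsig` is the logistic
#' sigmoid `1 / (1 + exp(-n))` (range `(0, 1)`), used for output units so
#' that network outputs read as posterior probabilities. Both are computed
#' in a numerically stable form: no overflow for any finite input.
#'
#' @param n numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' tansig(0)                      # 0
#' logsig(0)                      # 0.5
#' all.equal(tansig(1.3), 2 * logsig(2 * 1.3) - 1)
#' @export
tansig <- function(n) tanh(n)

#' @rdname tansig
#' @export
logsig <- function(n) {
  out <- numeric(length(n))
  pos <- !is.na(n) & n >= 0
  out[pos] <- 1 / (1 + exp(-n[pos]))
  out[!pos] <- exp(n[!pos]) / (1 + exp(n[!pos]))
  out[is.na(n)] <- NA_real_
  out
}

#' Train a small feed-forward classification network
#'
#' A single-hidden-layer back-propagation network — tansig hidden units,
#' one logsig output unit — trained on the cross-entropy loss by full-batch
#' resilient back-propagation (iRprop-), with early stopping on a held-out
#' validation fraction: training stops once the validation loss has not
#' improved for `patience` consecutive epochs, and the weights of the best
#' validation epoch are restored. Inputs are standardized (train-set mean
#' and sd, stored in the model) before entering the network. All randomness
#' — initial weights and the stratified validation split — is drawn from
#' R's RNG, so the same seed and data give bit-identical parameters.
#'
#' @param x numeric matrix, observations x features; all finite.
#' @param y binary target: logical, 0/1 numeric, or `"positive"`/
#'   `"negative"` labels (positive maps to 1).
#' @param hidden number of hidden units.
#' @param max_epochs training epoch cap.
#' @param val_fraction fraction held out for early stopping (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @param class_weights if `TRUE`, weight the loss inversely to class
#'   frequency.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first.
#' @param init optional list `W1` (hidden x features), `b1`, `W2`, `b2`
#'   overriding the random initialization.
#' @return An object of class `errp_mlp`.
#' @export
mlp_fit <- function(x, y, hidden = 10L, max_epochs = 200L,
                    val_fraction = 0.15, patience = 20L,
                    class_weights = FALSE, seed = NULL, init = NULL) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  y <- as_binary_target(y)
  if (length(y) != nrow(x)) stop("'y' must have one entry per row of 'x'")
  if (!any(y == 1) || !any(y == 0)) stop("both classes must be present")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x); d <- ncol(x)

  center <- colMeans(x)
  scale <- apply(x, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  if (is.null(init)) {
    init <- list(W1 = matrix(rnorm(hidden * d, 0, 1 / sqrt(d)), hidden, d),
                 b1 = rnorm(hidden, 0, 0.1),
                 W2 = matrix(rnorm(hidden, 0, 1 / sqrt(hidden)), 1, hidden),
                 b2 = 0)
  }
  # stratified validation split so small minority classes stay in training
  val_idx <- integer(0)
  if (val_fraction > 0 && n >= 10) {
    for (cls in c(0, 1)) {
      members <- which(y == cls)
      k <- floor(val_fraction * length(members))
      if (k >= 1 && k < length(members))
        val_idx <- c(val_idx, sample(members, k))
    }
    val_idx <- sort(val_idx)
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  wts <- c(1, 1)
  if (class_weights) wts <- n / (2 * c(sum(y == 0), sum(y == 1)))

  fit <- cpp_mlp_train(xs, y, init$W1, as.numeric(init$b1),
                       matrix(init$W2, nrow = 1), init$b2,
                       train_idx - 1L, val_idx - 1L,
                       as.integer(max_epochs), as.integer(patience),
                       wts[2], wts[1])
  structure(list(W1 = fit$W1, b1 = as.numeric(fit$b1),
                 W2 = matrix(fit$W2, nrow = 1), b2 = fit$b2,
                 center = center, scale = scale,
                 hidden = hidden, d = d,
                 epochs_run = fit$epochs_run, best_epoch = fit$best_epoch,
                 train_loss = fit$train_loss, val_loss = fit$val_loss),
            class = "errp_mlp")
}

as_binary_target <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- !y %in% .ERRP_LABELS
    if (any(bad)) stop("labels must be 'positive' or 'negative'")
    as.numeric(y == "positive")
  } else {
    y <- as.numeric(y)
    if (!all(y %in% c(0, 1))) stop("numeric targets must be 0/1")
    y
  }
}

#' @export
print.errp_mlp <- function(x, ...) {
  cat(sprintf("<errp_mlp> %d-%d-1 (tansig/logsig), %d epoch(s) run, best at %d\n",
              x$d, x$hidden, x$epochs_run, x$best_epoch))
  invisible(x)
}

#' Predict posterior scores from a trained network
#'
#' @param object an `errp_mlp`.
#' @param newdata matrix with the training feature dimension.
#' @param ... unused.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict.errp_mlp <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop(sprintf("newdata has %d features, the network expects %d",
                 ncol(newdata), object$d))
  xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  as.numeric(cpp_mlp_predict(xs, object$W1, object$b1, object$W2, object$b2))
}
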