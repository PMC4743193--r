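#' Fit per-channel class-mean templates
#'
#' The temporal feature set is built against the arithmetic mean waveform of
#' each feedback class, computed per channel over the training partition
#' only. Templates are fitted once and reused verbatim for training and
#' test feature extraction.
#'
#' @param train an [errp_epochs()] object containing both classes.
#' @return An object of class `errp_templates` with channels-by-samples
#'   matrices `positive` and `negative`, plus `n_samples` and
#'   `channel_labels`.
#' @export
fit_class_templates <- function(train) {
  stopifnot(inherits(train, "errp_epochs"))
  for (lab in .ERRP_LABELS)
    if (!any(train$labels == lab, na.rm = TRUE))
      stop("training set has no '", lab, "' epochs")
  arr <- epoch_array(train)
  mean_class <- function(lab) {
    idx <- which(train$labels == lab)
    apply(arr[, , idx, drop = FALSE], c(1, 2), mean)
  }
  structure(list(positive = mean_class("positive"),
                 negative = mean_class("negative"),
                 n_samples = dim(arr)[2],
                 channel_labels = train$channel_labels),
            class = "errp_templates")
}

#' @export
print.errp_templates <- function(x, ...) {
  cat(sprintf("<errp_templates> %d channels x %d samples (positive & negative class means)\n",
              nrow(x$positive), x$n_samples))
  invisible(x)
}

# N x 2*(max_lag+1) matrix whose columns are right-shifted copies of y
# (raw or centred); x %*% this evaluates the lagged sums for all lags.
lag_matrix <- function(y, max_lag) {
  N <- length(y)
  sapply(0:max_lag, function(m) c(rep(0, m), y[seq_len(N - m)]))
}

#' Level-1 temporal feature vector for one epoch channel
#'
#' The lagged (unnormalized) correlation and covariance of a single-channel
#' epoch `x` against the positive- and negative-class template waveforms:
#' for lag `m = 0..max_lag`,
#' `R(m) = sum_{j=0}^{N-m-1} x[j+m] * ybar[j]` and `C(m)` is the same sum
#' with the full-signal means of `x` and `ybar` subtracted inside the
#' product. The feature vector concatenates
#' `[R_pos, R_neg, C_pos, C_neg]`, so the default lag grid `m = 0..40`
#' gives `4 * 41 = 164` dimensions. Negative lags are not included, and
#' nothing is normalized.
#'
#' @param x numeric vector, one epoch channel of length `N`.
#' @param template_pos,template_neg the matching channel rows of the fitted
#'   class templates, length `N`.
#' @param max_lag largest lag, default 40; must be `< N`.
#' @return Named numeric vector of length `4 * (max_lag + 1)`.
#' @seealso [fit_class_templates()]
#' @export
temporal_feature <- function(x, template_pos, template_neg, max_lag = 40L) {
  N <- length(x)
  if (length(template_pos) != N || length(template_neg) != N)
    stop("epoch channel and templates must have equal length")
  if (max_lag >= N) stop("'max_lag' must be smaller than the signal length")
  B <- temporal_basis(template_pos, template_neg, max_lag)
  f <- drop(matrix(x, 1) %*% B$mat) - mean(x) * B$mean_adj
  names(f) <- c(sprintf("R_pos_%02d", 0:max_lag), sprintf("R_neg_%02d", 0:max_lag),
                sprintf("C_pos_%02d", 0:max_lag), sprintf("C_neg_%02d", 0:max_lag))
  f
}

# Precomputed basis so that features for a whole epoch matrix X (epochs x N)
# are X %*% mat - rowMeans(X) outer mean_adj. The covariance columns use the
# centred template; the residual term -mean(x)*sum(centred template over the
# overlap) is linear in mean(x) and supplied by mean_adj.
temporal_basis <- function(template_pos, template_neg, max_lag) {
  N <- length(template_pos)
  cp <- template_pos - mean(template_pos)
  cn <- template_neg - mean(template_neg)
  mat <- cbind(lag_matrix(template_pos, max_lag),
               lag_matrix(template_neg, max_lag),
               lag_matrix(cp, max_lag),
               lag_matrix(cn, max_lag))
  zero <- rep(0, 2 * (max_lag + 1))
  adj <- c(zero,
           sapply(0:max_lag, function(m) sum(cp[seq_len(N - m)])),
           sapply(0:max_lag, function(m) sum(cn[seq_len(N - m)])))
  list(mat = mat, mean_adj = adj)
}

# epochs x 164 feature matrix for channel index ch
temporal_features_channel <- function(X, templates, ch, max_lag = 40L) {
  B <- temporal_basis(templates$positive[ch, ], templates$negative[ch, ], max_lag)
  X %*% B$mat - outer(rowMeans(X), B$mean_adj)
}
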