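#' Mean class covariance matrices
#'
#' For each epoch `X` the spatial covariance is the trace-normalized outer
#' product `X X' / trace(X X')` — the standard normalization so that
#' epochs contribute equal total power — and the class matrices are the
#' arithmetic means over all epochs of each feedback class.
#'
#' @param train an [errp_epochs()] object with both classes.
#' @return An object of class `errp_covariances` with symmetric, unit-trace
#'   matrices `positive` and `negative` and the channel labels.
#' @export
class_covariances <- function(train) {
  stopifnot(inherits(train, "errp_epochs"))
  for (lab in .ERRP_LABELS)
    if (!any(train$labels == lab, na.rm = TRUE))
      stop("training set has no '", lab, "' epochs")
  covs <- lapply(seq_along(train$epochs), function(i) {
    X <- train$epochs[[i]]
    R <- tcrossprod(X)
    tr <- sum(diag(R))
    if (tr <= 0) stop("epoch ", i, " has zero energy; cannot normalize its covariance")
    R / tr
  })
  mean_class <- function(lab) {
    idx <- which(train$labels == lab)
    Reduce(`+`, covs[idx]) / length(idx)
  }
  structure(list(positive = mean_class("positive"),
                 negative = mean_class("negative"),
                 channel_labels = train$channel_labels),
            class = "errp_covariances")
}

#' Fit common spatial patterns
#'
#' The two-class CSP decomposition: eigendecompose
#' `R_p + R_n = U_C lambda_C U_C'`, whiten with
#' `P = lambda_C^{-1/2} U_C'`, transform `S_i = P R_i P'`; `S_p` and `S_n`
#' then share eigenvectors `B` with eigenvalue pairs summing to one, and
#' every row of the projection matrix `W = B' P` is one spatial filter.
#' Rows are ordered by the positive-class eigenvalue, descending, with ties
#' broken by original eigenvector index, so virtual-channel indexing is
#' reproducible. When the composite covariance is ill-conditioned
#' (condition number above 1e10) a ridge `1e-8 * trace/channels * I` is
#' added before whitening. All filters are retained; no manual filter
#' selection takes place.
#'
#' @param cov an `errp_covariances` object (or a list with symmetric
#'   positive semi-definite `positive` and `negative` matrices).
#' @return An object of class `errp_csp` with `W`, `P`, `B`, `U_C`,
#'   `lambda_C`, `lambda_p`, `lambda_n` and `channel_labels`.
#' @export
fit_csp <- function(cov) {
  Rp <- cov$positive
  Rn <- cov$negative
  if (!isTRUE(all.equal(Rp, t(Rp), tolerance = 1e-8)) ||
      !isTRUE(all.equal(Rn, t(Rn), tolerance = 1e-8)))
    stop("class covariance matrices must be symmetric")
  C <- (Rp + Rn + t(Rp + Rn)) / 2
  nch <- nrow(C)
  ec <- eigen(C, symmetric = TRUE)
  if (min(ec$values) < -1e-10 * max(abs(ec$values)))
    stop("class covariances are not positive semi-definite")
  if (min(ec$values) <= 0 ||
      max(ec$values) / max(min(ec$values), .Machine$double.xmin) > 1e10) {
    C <- C + diag(1e-8 * sum(diag(C)) / nch, nch)
    ec <- eigen(C, symmetric = TRUE)
  }
  P <- diag(1 / sqrt(ec$values), nrow = nch) %*% t(ec$vectors)
  Sp <- P %*% Rp %*% t(P)
  Sp <- (Sp + t(Sp)) / 2
  eb <- eigen(Sp, symmetric = TRUE)
  ord <- order(eb$values, decreasing = TRUE)  # stable: ties keep eigen order
  B <- eb$vectors[, ord, drop = FALSE]
  lambda_p <- eb$values[ord]
  W <- t(B) %*% P
  structure(list(W = W, P = P, B = B,
                 U_C = ec$vectors, lambda_C = ec$values,
                 lambda_p = lambda_p, lambda_n = 1 - lambda_p,
                 channel_labels = cov$channel_labels),
            class = "errp_csp")
}

#' @export
print.errp_csp <- function(x, ...) {
  cat(sprintf("<errp_csp> %d spatial filters; lambda_p range %.3f-%.3f\n",
              nrow(x$W), min(x$lambda_p), max(x$lambda_p)))
  invisible(x)
}

#' Project an epoch through the CSP filter bank
#'
#' `Y = W X`: row `i` of the result is the time course of virtual channel
#' `i` (one spatial filter), with the same number of samples as the epoch
#' (161 with the default window). These rows are the level-1 spatial
#' feature vectors.
#'
#' @param epoch channels x samples matrix.
#' @param bank a fitted [fit_csp()] object.
#' @return A channels x samples matrix of filtered time courses.
#' @export
csp_project <- function(epoch, bank) {
  stopifnot(inherits(bank, "errp_csp"))
  epoch <- as.matrix(epoch)
  if (nrow(epoch) != nrow(bank$W))
    stop(sprintf("epoch has %d channels but the filter bank expects %d",
                 nrow(epoch), nrow(bank$W)))
  bank$W %*% epoch
}
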