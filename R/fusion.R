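.ERRP_DOMAINS <- c("temporal", "spectral", "spatial")

#' Control parameters for the fusion classifier
#'
#' Collects the tunable architecture and training settings of
#' [errp_fusion()]. Hidden-layer sizes are deliberately small — each
#' network only has to collapse one feature block to a posterior — and the
#' epoch budget is capped with validation-based early stopping.
#'
#' @param hidden_stage1 hidden units of each per-(domain, channel) network.
#' @param hidden_stage2 hidden units of the per-domain 56-input networks.
#' @param hidden_combiner hidden units of the final combiner network(s).
#' @param max_epochs training epoch cap for every network.
#' @param val_fraction validation fraction for early stopping.
#' @param patience early-stopping patience, epochs.
#' @param max_lag temporal lag grid is `0..max_lag` (164 features at 40).
#' @param max_imfs,keep_imfs EMD depth and number of summarized IMFs.
#' @param freq_unit unit of the mean-frequency feature, `"rad"` or `"hz"`.
#' @param class_weights weight the loss inversely to class frequency
#'   (default off).
#' @return A list of class `errp_control`.
#' @export
fusion_control <- function(hidden_stage1 = 10L, hidden_stage2 = 8L,
                           hidden_combiner = 4L, max_epochs = 200L,
                           val_fraction = 0.15, patience = 20L,
                           max_lag = 40L, max_imfs = 4L, keep_imfs = 3L,
                           freq_unit = c("rad", "hz"),
                           class_weights = FALSE) {
  freq_unit <- match.arg(freq_unit)
  structure(list(hidden_stage1 = as.integer(hidden_stage1),
                 hidden_stage2 = as.integer(hidden_stage2),
                 hidden_combiner = as.integer(hidden_combiner),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction, patience = as.integer(patience),
                 max_lag = as.integer(max_lag),
                 max_imfs = as.integer(max_imfs),
                 keep_imfs = as.integer(keep_imfs),
                 freq_unit = freq_unit, class_weights = class_weights),
            class = "errp_control")
}

canonical_domains <- function(domains) {
  domains <- unique(match.arg(domains, .ERRP_DOMAINS, several.ok = TRUE))
  .ERRP_DOMAINS[.ERRP_DOMAINS %in% domains]
}

domain_key <- function(domains) paste(canonical_domains(domains), collapse = "+")

# all 7 non-empty domain subsets, canonical order
domain_subsets <- function() {
  subs <- list()
  for (k in 1:3) {
    cmb <- utils::combn(.ERRP_DOMAINS, k, simplify = FALSE)
    subs <- c(subs, cmb)
  }
  subs
}

# level-1 feature blocks: per domain, a list over (virtual) channels of
# n_epochs x M_d matrices (M = 164 / 12 / 161 with defaults)
extract_level1 <- function(epochs, templates, csp, control) {
  arr <- epoch_array(epochs)
  nch <- length(epochs$channel_labels)
  temporal <- lapply(seq_len(nch), function(ch)
    temporal_features_channel(channel_matrix(arr, ch), templates, ch,
                              control$max_lag))
  names(temporal) <- epochs$channel_labels
  n_short <- 0L
  spectral <- lapply(seq_len(nch), function(ch) {
    f <- spectral_features_matrix(channel_matrix(arr, ch), epochs$fs,
                                  max_imfs = control$max_imfs,
                                  keep_imfs = control$keep_imfs,
                                  freq_unit = control$freq_unit, warn = FALSE)
    n_short <<- n_short + attr(f, "n_short")
    f
  })
  names(spectral) <- epochs$channel_labels
  if (n_short > 0)
    warning(sprintf("spectral features: %d epoch-channel signal(s) gave fewer than %d IMFs (zero-filled)",
                    n_short, control$keep_imfs))
  proj <- lapply(epochs$epochs, csp_project, bank = csp)
  parr <- array(unlist(proj, use.names = FALSE),
                dim = c(nch, ncol(proj[[1]]), length(proj)))
  spatial <- lapply(seq_len(nch), function(ch) channel_matrix(parr, ch))
  names(spatial) <- sprintf("CSP%02d", seq_len(nch))
  list(temporal = temporal, spectral = spectral, spatial = spatial)
}

fit_stage1_bank <- function(lvl1, y, control) {
  lapply(names(lvl1), function(d) {
    nets <- lapply(names(lvl1[[d]]), function(ch) {
      F <- lvl1[[d]][[ch]]
      if (!all(is.finite(F)))
        stop("non-finite level-1 features in domain '", d, "', channel ", ch)
      mlp_fit(F, y, hidden = control$hidden_stage1,
              max_epochs = control$max_epochs,
              val_fraction = control$val_fraction,
              patience = control$patience,
              class_weights = control$class_weights)
    })
    names(nets) <- names(lvl1[[d]])
    nets
  }) -> bank
  names(bank) <- names(lvl1)
  bank
}

apply_stage1_bank <- function(bank, lvl1) {
  out <- lapply(names(bank), function(d) {
    nets <- bank[[d]]
    L2 <- matrix(0, nrow(lvl1[[d]][[1]]), length(nets),
                 dimnames = list(NULL, names(nets)))
    for (i in seq_along(nets)) L2[, i] <- predict(nets[[i]], lvl1[[d]][[i]])
    L2
  })
  names(out) <- names(bank)
  out
}

#' Fit the multi-domain ErrP fusion classifier
#'
#' The complete training orchestration: per-channel class templates and the
#' CSP filter bank are fitted on the training epochs; level-1 temporal,
#' spectral and spatial feature blocks are extracted; one small
#' back-propagation network per (domain, channel) collapses each block to a
#' per-channel posterior (level-2, the first dimensionality reduction); one
#' network per domain collapses the channel posteriors to a scalar
#' per-domain posterior (level-3, the second reduction); and a final
#' feed-forward network classifies the three-dimensional level-3 vector.
#' Stage-2 and final networks are trained on in-sample stage-1 outputs
#' (straight stacking). Combiner networks for all seven domain subsets
#' (three singles, three pairs, the triple) are fitted alongside, so
#' single- and pair-domain scores are available at predict time without
#' re-training the feature stages.
#'
#' The positive class is correct feedback; scores near 1 favor a correct
#' trial, scores near 0 an error.
#'
#' @param epochs a labeled [errp_epochs()] training set with both classes.
#' @param control an [fusion_control()] list.
#' @param seed master seed; the whole fit is deterministic given
#'   `epochs`, `control` and `seed`.
#' @return An object of class `errp_fusion`: all trained stages, the
#'   fitted templates and CSP bank, the training-set level-3 features and
#'   in-sample scores.
#' @seealso [predict.errp_fusion()], [per_subject_auc()],
#'   [electrode_ablation()]
#' @export
errp_fusion <- function(epochs, control = fusion_control(), seed = 1L) {
  stopifnot(inherits(epochs, "errp_epochs"), inherits(control, "errp_control"))
  if (any(is.na(epochs$labels))) stop("all training epochs must be labeled")
  set.seed(seed)
  y <- as_binary_target(epochs$labels)
  templates <- fit_class_templates(epochs)
  csp <- fit_csp(class_covariances(epochs))
  lvl1 <- extract_level1(epochs, templates, csp, control)
  stage1 <- fit_stage1_bank(lvl1, y, control)
  lvl2 <- apply_stage1_bank(stage1, lvl1)
  stage2 <- lapply(lvl2, function(L2)
    mlp_fit(L2, y, hidden = control$hidden_stage2,
            max_epochs = control$max_epochs,
            val_fraction = control$val_fraction, patience = control$patience,
            class_weights = control$class_weights))
  lvl3 <- sapply(.ERRP_DOMAINS, function(d) predict(stage2[[d]], lvl2[[d]]))
  if (is.null(dim(lvl3))) lvl3 <- matrix(lvl3, nrow = 1,
                                         dimnames = list(NULL, .ERRP_DOMAINS))
  combiners <- lapply(domain_subsets(), function(ds)
    mlp_fit(lvl3[, ds, drop = FALSE], y, hidden = control$hidden_combiner,
            max_epochs = control$max_epochs,
            val_fraction = control$val_fraction, patience = control$patience,
            class_weights = control$class_weights))
  names(combiners) <- vapply(domain_subsets(), paste, "", collapse = "+")
  scores <- predict(combiners[["temporal+spectral+spatial"]], lvl3)
  structure(list(templates = templates, csp = csp,
                 stage1 = stage1, stage2 = stage2, combiners = combiners,
                 control = control, seed = as.integer(seed),
                 channel_labels = epochs$channel_labels,
                 fs = epochs$fs, window = epochs$window,
                 level3_train = lvl3, labels_train = epochs$labels,
                 subjects_train = epochs$subjects,
                 fitted_scores = scores),
            class = "errp_fusion")
}

check_channels <- function(object, epochs) {
  if (!identical(epochs$channel_labels, object$channel_labels))
    stop("channel labels/order of the epochs do not match the fitted model")
}

#' Per-channel stage-1 posteriors (level-2 features)
#'
#' Applies the fitted feature stages and the stage-1 network bank to new
#' epochs, returning one posterior per (domain, channel): the level-2
#' representation of each epoch.
#'
#' @param object a fitted [errp_fusion()] model.
#' @param epochs an [errp_epochs()] object with the model's channels.
#' @return A list of three `n_epochs x n_channels` matrices in `[0, 1]`,
#'   named `temporal`, `spectral`, `spatial`.
#' @export
stage1_posteriors <- function(object, epochs) {
  stopifnot(inherits(object, "errp_fusion"))
  check_channels(object, epochs)
  lvl1 <- extract_level1(epochs, object$templates, object$csp, object$control)
  apply_stage1_bank(object$stage1, lvl1)
}

#' Per-domain level-3 features for new epochs
#'
#' @inheritParams stage1_posteriors
#' @return An `n_epochs x 3` matrix of per-domain posteriors, columns
#'   `temporal`, `spectral`, `spatial`.
#' @export
level3_features <- function(object, epochs) {
  lvl2 <- stage1_posteriors(object, epochs)
  lvl3 <- sapply(.ERRP_DOMAINS, function(d)
    predict(object$stage2[[d]], lvl2[[d]]))
  if (is.null(dim(lvl3))) lvl3 <- matrix(lvl3, nrow = 1,
                                         dimnames = list(NULL, .ERRP_DOMAINS))
  lvl3
}

#' Predict error/correct scores for new epochs
#'
#' Runs the stored feature stages (training-fitted templates and CSP bank
#' only — nothing is re-fitted) and the network cascade. `domains` selects
#' which per-domain features feed the combiner: the default uses all three;
#' any single domain or pair uses the corresponding combiner network fitted
#' during training.
#'
#' @param object a fitted [errp_fusion()] model.
#' @param newdata an [errp_epochs()] object with matching channels.
#' @param type `"score"` (posterior of the positive/correct class),
#'   `"label"` (thresholded at 0.5, positive iff score >= 0.5), or
#'   `"both"` (data.frame with both).
#' @param domains subset of `c("temporal", "spectral", "spatial")`.
#' @param ... unused.
#' @return Scores, labels, or a data.frame, one entry per epoch.
#' @export
predict.errp_fusion <- function(object, newdata,
                                type = c("score", "label", "both"),
                                domains = .ERRP_DOMAINS, ...) {
  type <- match.arg(type)
  domains <- canonical_domains(domains)
  lvl3 <- level3_features(object, newdata)
  scores <- predict(object$combiners[[domain_key(domains)]],
                    lvl3[, domains, drop = FALSE])
  labels <- ifelse(scores >= 0.5, "positive", "negative")
  switch(type,
         score = scores,
         label = labels,
         both = data.frame(score = scores, label = labels,
                           stringsAsFactors = FALSE))
}

#' @export
print.errp_fusion <- function(x, ...) {
  cat(sprintf("<errp_fusion> %d channels @ %g Hz, window %g-%g ms, seed %d\n",
              length(x$channel_labels), x$fs, x$window[1], x$window[2], x$seed))
  cat(sprintf("  stage 1: 3 x %d networks (%d hidden); stage 2: 3 networks (%d hidden); combiners: %d (%d hidden)\n",
              length(x$channel_labels), x$control$hidden_stage1,
              x$control$hidden_stage2, length(x$combiners),
              x$control$hidden_combiner))
  cat(sprintf("  trained on %d epochs (%d positive / %d negative)\n",
              length(x$labels_train), sum(x$labels_train == "positive"),
              sum(x$labels_train == "negative")))
  invisible(x)
}

#' @export
summary.errp_fusion <- function(object, ...) {
  print(object)
  cm <- confusion_matrix(object$fitted_scores, object$labels_train)
  roc <- roc_auc(object$fitted_scores, object$labels_train)
  cat(sprintf("  in-sample (training) accuracy %.1f%%, AUC %.4f\n",
              cm$accuracy_pct, roc$auc))
  invisible(list(confusion = cm, roc = roc))
}

#' @export
coef.errp_fusion <- function(object, ...) {
  net <- object$combiners[["temporal+spectral+spatial"]]
  list(W1 = net$W1, b1 = net$b1, W2 = net$W2, b2 = net$b2)
}

#' @export
fitted.errp_fusion <- function(object, ...) object$fitted_scores

#' @export
residuals.errp_fusion <- function(object, ...)
  as_binary_target(object$labels_train) - object$fitted_scores

#' @export
plot.errp_fusion <- function(x, ...) {
  plot(roc_auc(x$fitted_scores, x$labels_train),
       main = "In-sample ROC (training epochs)", ...)
}
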