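check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length")
  if (length(scores) == 0) stop("empty input")
  bad <- !labels %in% .ERRP_LABELS
  if (any(bad)) stop("labels must be 'positive' or 'negative'")
}

#' Confusion-matrix summary at a score threshold
#'
#' Cells are reported as percentages of all test epochs, with the positive
#' class being correct feedback (so under realistic ~70% correct trials the
#' true-positive cell is the large one). Total accuracy is the sum of the
#' true-positive and true-negative percentages.
#'
#' @param scores numeric scores in `[0, 1]` (posterior of the positive
#'   class).
#' @param labels `"positive"` / `"negative"` per epoch.
#' @param threshold decision threshold; predicted positive iff
#'   `score >= threshold`.
#' @return An object of class `errp_confusion` with `tn_pct`, `fp_pct`,
#'   `fn_pct`, `tp_pct`, `accuracy_pct`, the raw `counts`, `threshold` and
#'   `n`.
#' @export
confusion_matrix <- function(scores, labels, threshold = 0.5) {
  check_scores_labels(scores, labels)
  pred_pos <- scores >= threshold
  act_pos <- labels == "positive"
  n <- length(scores)
  counts <- c(tn = sum(!act_pos & !pred_pos), fp = sum(!act_pos & pred_pos),
              fn = sum(act_pos & !pred_pos), tp = sum(act_pos & pred_pos))
  pct <- 100 * counts / n
  structure(list(tn_pct = pct[["tn"]], fp_pct = pct[["fp"]],
                 fn_pct = pct[["fn"]], tp_pct = pct[["tp"]],
                 accuracy_pct = pct[["tp"]] + pct[["tn"]],
                 counts = counts, threshold = threshold, n = n),
            class = "errp_confusion")
}

#' @export
print.errp_confusion <- function(x, ...) {
  cat(sprintf("<errp_confusion> n = %d, threshold = %g\n", x$n, x$threshold))
  cat(sprintf("  TN %5.1f%%   FP %5.1f%%\n  FN %5.1f%%   TP %5.1f%%\n",
              x$tn_pct, x$fp_pct, x$fn_pct, x$tp_pct))
  cat(sprintf("  accuracy %.1f%%\n", x$accuracy_pct))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps every unique score as a decision threshold to build the ROC
#' curve, with endpoints (0,0) and (1,1). The AUC is the Mann-Whitney rank
#' statistic `P(score_pos > score_neg) + 0.5 * P(tie)`, which equals the
#' trapezoidal area under the curve; ties receive half credit. Invariant
#' under any strictly increasing transform of the scores.
#'
#' @inheritParams confusion_matrix
#' @return An object of class `errp_roc` with `thresholds`, `tpr`, `fpr`
#'   and `auc`; both classes must be present.
#' @export
roc_auc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  pos <- labels == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(p)[last_of_tie]
  fp <- cumsum(!p)[last_of_tie]
  thr <- c(Inf, s[last_of_tie])
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  r <- rank(scores)  # average ranks: half-credit for ties
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "errp_roc")
}

#' @export
print.errp_roc <- function(x, ...) {
  cat(sprintf("<errp_roc> AUC = %.4f (%d threshold points)\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

#' @export
plot.errp_roc <- function(x, main = "ROC curve", ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "False positive rate", ylab = "True positive rate",
       main = main, ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Per-subject AUC table across feature combinations
#'
#' Scores the test epochs with every stored domain-combination combiner
#' (three single domains, three pairs, the triple) and reports the AUC per
#' subject plus an unweighted average row. Subjects whose test epochs
#' contain only one class are skipped with a warning.
#'
#' @param model a fitted [errp_fusion()].
#' @param test a labeled [errp_epochs()] set carrying subject ids.
#' @param combinations list of domain subsets; default all seven.
#' @return A data.frame: one row per subject plus `"Average"`, one column
#'   per feature combination.
#' @export
per_subject_auc <- function(model, test, combinations = domain_subsets()) {
  stopifnot(inherits(model, "errp_fusion"), inherits(test, "errp_epochs"))
  if (any(is.na(test$labels))) stop("test epochs must be labeled")
  lvl3 <- level3_features(model, test)
  keys <- vapply(combinations, domain_key, "")
  score_mat <- sapply(seq_along(combinations), function(i) {
    ds <- canonical_domains(combinations[[i]])
    predict(model$combiners[[keys[i]]], lvl3[, ds, drop = FALSE])
  })
  if (is.null(dim(score_mat))) score_mat <- matrix(score_mat, nrow = 1)
  subjects <- unique(test$subjects)
  keep <- vapply(subjects, function(s) {
    labs <- test$labels[test$subjects == s]
    both <- any(labs == "positive") && any(labs == "negative")
    if (!both) warning("subject ", s, " has only one class; skipped")
    both
  }, logical(1))
  subjects <- subjects[keep]
  if (!length(subjects)) stop("no subject has both classes")
  tab <- do.call(rbind, lapply(subjects, function(s) {
    idx <- test$subjects == s
    vapply(seq_along(combinations), function(i)
      roc_auc(score_mat[idx, i], test$labels[idx])$auc, numeric(1))
  }))
  tab <- rbind(tab, colMeans(tab))
  rownames(tab) <- c(subjects, "Average")
  colnames(tab) <- keys
  as.data.frame(tab)
}

#' Electrode-ablation study
#'
#' Quantifies the contribution of individual electrodes: (a) for every
#' electrode, the complete pipeline (templates, CSP, all network stages) is
#' re-trained on that electrode alone and evaluated on the test set; (b)
#' the same is done for cumulative electrode prefixes in montage order
#' (starting at FP1, i.e. the order of `train$channel_labels`). Re-training
#' per subset — not reusing weights — is intentional: adding electrodes
#' changes every stage's weights. With a single electrode the CSP step
#' degenerates to a scalar rescaling, so the spatial branch carries the
#' (rescaled) raw waveform.
#'
#' @param train,test labeled [errp_epochs()] sets sharing channels.
#' @param electrodes electrode subset to study; default all channels of
#'   `train`, in order.
#' @param cumulative also compute the cumulative-prefix series (the single-
#'   electrode series is always computed).
#' @param control,seed passed to each [errp_fusion()] re-fit; the same seed
#'   is used for every subset so runs differ only by electrode set.
#' @return An object of class `errp_ablation`: named numeric vectors
#'   `single` and (optionally) `cumulative` of test AUCs. Electrodes whose
#'   pipeline fails are recorded as `NA` with a warning.
#' @export
electrode_ablation <- function(train, test, electrodes = train$channel_labels,
                               cumulative = TRUE,
                               control = fusion_control(), seed = 1L) {
  stopifnot(inherits(train, "errp_epochs"), inherits(test, "errp_epochs"))
  run_subset <- function(chs) {
    tryCatch({
      m <- errp_fusion(subset_channels(train, chs), control = control,
                       seed = seed)
      roc_auc(predict(m, subset_channels(test, chs)), test$labels)$auc
    }, error = function(e) {
      warning("pipeline failed for {", paste(chs, collapse = ", "), "}: ",
              conditionMessage(e))
      NA_real_
    })
  }
  single <- vapply(electrodes, function(ch) run_subset(ch), numeric(1))
  names(single) <- electrodes
  out <- list(single = single, electrodes = electrodes)
  if (cumulative) {
    cum <- vapply(seq_along(electrodes), function(k)
      run_subset(electrodes[seq_len(k)]), numeric(1))
    names(cum) <- electrodes
    out$cumulative <- cum
  }
  structure(out, class = "errp_ablation")
}

#' @export
print.errp_ablation <- function(x, ...) {
  cat(sprintf("<errp_ablation> %d electrode(s); single-electrode AUC mean %.3f\n",
              length(x$single), mean(x$single, na.rm = TRUE)))
  if (!is.null(x$cumulative))
    cat(sprintf("  cumulative AUC: %.3f (first) -> %.3f (all)\n",
                x$cumulative[1], x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' @export
plot.errp_ablation <- function(x, ...) {
  n <- length(x$single)
  graphics::barplot(x$single, names.arg = names(x$single), las = 2,
                    ylim = c(0, 1), ylab = "AUC",
                    main = "Electrode ablation", ...)
  if (!is.null(x$cumulative))
    graphics::points(seq_len(n) * 1.2 - 0.5, x$cumulative, pch = 8)
  invisible(x)
}
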