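# shared fixtures: small montage subsets and independent oracles

CH2 <- c("FCz", "Cz")
CH4 <- c("FCz", "Cz", "F3", "P8")
CH6 <- c("FCz", "Cz", "F3", "C3", "P8", "O1")
CH8 <- c("FCz", "Cz", "Fz", "F3", "C3", "Pz", "P8", "O1")

small_sim <- function(n_subjects = 1, epochs_per_subject = 30,
                      channels = CH6, snr = 3, seed = 1, ...) {
  sim_config(n_subjects = n_subjects, epochs_per_subject = epochs_per_subject,
             n_channels = length(channels), channel_labels = channels,
             snr = snr, seed = seed, ...)
}

# random unlabeled-structure epoch set (pure noise, balanced-ish labels)
toy_epochs <- function(n = 20, channels = CH4, ns = 50, seed = 1, fs = 200) {
  set.seed(seed)
  labels <- rep(c("positive", "negative"), length.out = n)
  errp_epochs(lapply(seq_len(n), function(i)
    matrix(rnorm(length(channels) * ns), length(channels), ns)),
    labels, subjects = "S01", channel_labels = channels, fs = fs,
    window = c(200, 200 + (ns - 1) * 1000 / fs))
}

# direct double-loop evaluation of the lagged correlation / covariance sums
naive_temporal <- function(x, yp, yn, max_lag) {
  N <- length(x)
  one <- function(y, center) {
    mx <- mean(x); my <- mean(y)
    sapply(0:max_lag, function(m) {
      acc <- 0
      for (j in 0:(N - m - 1)) {
        if (center) acc <- acc + (x[j + m + 1] - mx) * (y[j + 1] - my)
        else acc <- acc + x[j + m + 1] * y[j + 1]
      }
      acc
    })
  }
  c(one(yp, FALSE), one(yn, FALSE), one(yp, TRUE), one(yn, TRUE))
}

# O(n^2) all-pairs AUC with half credit for ties
auc_pairs <- function(scores, labels) {
  sp <- scores[labels == "positive"]
  sn <- scores[labels == "negative"]
  acc <- 0
  for (a in sp) for (b in sn)
    acc <- acc + (a > b) + 0.5 * (a == b)
  acc / (length(sp) * length(sn))
}

# direct enumeration of confusion cells
count_cells <- function(scores, labels, thr = 0.5) {
  tp <- tn <- fp <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] >= thr
    act <- labels[i] == "positive"
    if (act && pred) tp <- tp + 1
    if (act && !pred) fn <- fn + 1
    if (!act && pred) fp <- fp + 1
    if (!act && !pred) tn <- tn + 1
  }
  c(tn = tn, fp = fp, fn = fn, tp = tp) / length(scores) * 100
}

# random symmetric positive definite matrix with given trace
random_spd <- function(n, trace = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- crossprod(matrix(rnorm(n * n), n, n)) + diag(n) * 0.1
  A / sum(diag(A)) * trace
}
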