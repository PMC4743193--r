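#' Configuration for the synthetic ErrP session generator
#'
#' Defines the study conditions emulated by [simulate_session()]: a
#' copy-spelling protocol in which each feedback event is either correct
#' (positive, ~70%) or an error (negative, ~30%), recorded from a 56-channel
#' extended 10-20 montage at 200 Hz. Error trials carry a fronto-central
#' negative deflection peaking 300 ms after feedback onset (an fERN
#' analogue) plus a later positivity; correct trials carry a smaller
#' positive feedback deflection.
#'
#' @param n_subjects number of simulated subjects (default 26, the size of
#'   the emulated study).
#' @param epochs_per_subject feedback trials per subject (default 200).
#' @param p_error probability that a trial is an error (negative feedback).
#' @param fs sampling rate, Hz.
#' @param n_channels number of channels; must match `channel_labels`.
#' @param channel_labels montage labels, drawn from [errp_montage()].
#' @param snr ratio of the error-template peak amplitude to the per-channel
#'   background-noise standard deviation (dimensionless). `snr = 0` plants
#'   no evoked signal in either class.
#' @param latency_jitter_ms standard deviation of the per-trial peak-latency
#'   jitter, ms.
#' @param subject_scale_std standard deviation of the per-subject
#'   log-normal amplitude factor.
#' @param seed integer seed; identical configurations produce bit-identical
#'   sessions.
#' @return An object of class `errp_sim_config`.
#' @export
sim_config <- function(n_subjects = 26L,
                       epochs_per_subject = 200L,
                       p_error = 0.3,
                       fs = 200,
                       n_channels = 56L,
                       channel_labels = errp_montage()$label,
                       snr = 1,
                       latency_jitter_ms = 20,
                       subject_scale_std = 0.2,
                       seed = 1L) {
  if (n_subjects < 1 || epochs_per_subject < 1)
    stop("need at least one subject and one epoch per subject")
  if (!(p_error > 0 && p_error < 1)) stop("'p_error' must be in (0, 1)")
  if (snr < 0) stop("'snr' must be >= 0")
  if (fs <= 0) stop("'fs' must be > 0")
  if (n_channels < 2) stop("'n_channels' must be >= 2")
  if (length(channel_labels) != n_channels || anyDuplicated(channel_labels))
    stop("'channel_labels' must hold exactly n_channels unique entries")
  if (latency_jitter_ms < 0 || latency_jitter_ms > 150)
    stop("'latency_jitter_ms' must be in [0, 150] so events fit their epoch window")
  montage_weights(channel_labels)  # validates labels
  structure(list(n_subjects = as.integer(n_subjects),
                 epochs_per_subject = as.integer(epochs_per_subject),
                 p_error = p_error, fs = fs,
                 n_channels = as.integer(n_channels),
                 channel_labels = as.character(channel_labels),
                 snr = snr, latency_jitter_ms = latency_jitter_ms,
                 subject_scale_std = subject_scale_std,
                 seed = as.integer(seed)),
            class = "errp_sim_config")
}

#' @export
print.errp_sim_config <- function(x, ...) {
  cat(sprintf(paste0("<errp_sim_config> %d subject(s) x %d trials, p_error=%g, ",
                     "%d ch @ %g Hz, snr=%g, seed=%d\n"),
              x$n_subjects, x$epochs_per_subject, x$p_error, x$n_channels,
              x$fs, x$snr, x$seed))
  invisible(x)
}

# evoked waveform added to one trial, on the template time axis (seconds from
# feedback onset). Amplitudes are in units of the noise sd; the channel
# topography multiplies on top.
trial_waveform <- function(t, label, jitter_s) {
  if (label == "negative") {
    # fERN analogue: negative peak 300 ms (sigma 45 ms) plus a half-amplitude
    # later positivity (Pe analogue, 500 ms, sigma 60 ms)
    -exp(-(t - 0.3 - jitter_s)^2 / (2 * 0.045^2)) +
      0.5 * exp(-(t - 0.5 - jitter_s)^2 / (2 * 0.060^2))
  } else {
    # smaller positive feedback deflection
    0.4 * exp(-(t - 0.32 - jitter_s)^2 / (2 * 0.050^2))
  }
}

ar_series <- function(n, coef = 0.95) {
  as.numeric(stats::filter(rnorm(n), coef, method = "recursive"))
}

#' Simulate synthetic ErrP recording sessions
#'
#' Generates one continuous multi-channel recording per subject under the
#' conditions in a [sim_config()]. Background activity is temporally
#' correlated band-limited noise: per-channel AR(1) series (coefficient
#' 0.95) band-passed to 1-40 Hz, a rank-6 spatially mixed set of shared
#' AR sources, and a common 10 Hz sinusoid at a random phase per subject
#' (alpha analogue). Each channel's background is rescaled to unit variance
#' and expressed in microvolts (sd 10), so `snr` is exactly the planted
#' template peak over the noise sd. Error trials receive the fERN-like
#' deflection weighted by the fronto-central montage topography; correct
#' trials a smaller positivity with the same topography. Inter-trial
#' intervals are jittered uniformly in 1.3-1.7 s, which also breaks any
#' phase-locking of the alpha component across trials.
#'
#' @param config an `errp_sim_config`.
#' @return A list of [errp_recording()] objects, one per subject, named
#'   `S01`, `S02`, ...
#' @examples
#' recs <- simulate_session(sim_config(n_subjects = 1, epochs_per_subject = 10,
#'                                     n_channels = 4,
#'                                     channel_labels = c("FCz", "Cz", "F3", "P8"),
#'                                     seed = 7))
#' recs$S01
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "errp_sim_config"))
  set.seed(config$seed)
  fs <- config$fs
  noise_sd <- 10  # microvolts
  w_scalp <- montage_weights(config$channel_labels)
  bp <- design_bandpass(2, 1, 40, fs)
  lapply(seq_len(config$n_subjects), function(si) {
    n_tr <- config$epochs_per_subject
    iti <- runif(n_tr, 1.3, 1.7)
    lead <- 2.0; tail <- 1.5
    ev_time <- lead + cumsum(iti) - iti[1]
    n_samp <- ceiling((lead + sum(iti) - iti[1] + tail) * fs)
    ev_samp <- round(ev_time * fs) + 1L

    # background noise
    nch <- config$n_channels
    idio <- sapply(seq_len(nch), function(i)
      zerophase_bandpass(bp, ar_series(n_samp)))
    shared <- sapply(1:6, function(i) zerophase_bandpass(bp, ar_series(n_samp)))
    mix <- matrix(rnorm(nch * 6), nch, 6) / sqrt(6)
    alpha_phase <- runif(1, 0, 2 * pi)
    alpha <- sin(2 * pi * 10 * seq_len(n_samp) / fs + alpha_phase)
    noise <- t(idio) * 0.8 + mix %*% t(shared) * 0.6 +
      outer(rep(0.45, nch), alpha)
    noise <- noise / apply(noise, 1, sd) * noise_sd

    # planted evoked responses
    amp_subj <- exp(rnorm(1, 0, config$subject_scale_std))
    labels <- ifelse(runif(n_tr) < config$p_error, "negative", "positive")
    jit <- rnorm(n_tr, 0, config$latency_jitter_ms / 1000)
    supp <- 0:round(0.9 * fs)              # template support, 0-900 ms
    t_supp <- supp / fs
    amp <- config$snr * noise_sd * amp_subj
    if (amp > 0) {
      for (k in seq_len(n_tr)) {
        idx <- ev_samp[k] + supp
        idx <- idx[idx <= n_samp]
        wave <- amp * trial_waveform(t_supp[seq_along(idx)], labels[k], jit[k])
        noise[, idx] <- noise[, idx] + outer(w_scalp, wave)
      }
    }
    errp_recording(noise, fs, config$channel_labels,
                   events = data.frame(sample = ev_samp, label = labels,
                                       stringsAsFactors = FALSE),
                   subject = sprintf("S%02d", si))
  }) -> recs
  names(recs) <- sprintf("S%02d", seq_len(config$n_subjects))
  recs
}

#' Simulate labeled epochs directly
#'
#' Convenience wrapper: runs [simulate_session()] and cuts epochs with the
#' default 200-1000 ms window via [extract_epochs()], concatenating all
#' subjects into one labeled set. No filtering or re-referencing is applied;
#' the epochs are raw simulated signal.
#'
#' @inheritParams simulate_session
#' @return An [errp_epochs()] object with
#'   `n_subjects * epochs_per_subject` epochs.
#' @export
simulate_epochs <- function(config) {
  recs <- simulate_session(config)
  win <- epoch_window(fs = config$fs)
  bind_epochs(lapply(recs, extract_epochs, window = win))
}

#' Simulate epochs with complementary class information across domains
#'
#' A stress design for feature fusion: trials are split into three groups
#' and the error trials of each group are distinguishable in (mostly) one
#' domain only. Group 1 errors carry the fERN-like temporal deflection at
#' the fronto-central topography; group 2 errors a 6 Hz theta burst with a
#' random phase (so it survives in spectral statistics but averages out of
#' the class template); group 3 errors extra broadband variance along a
#' fixed spatial pattern (a CSP-visible signature). A classifier restricted
#' to one domain can separate only part of the error trials, whereas the
#' fused classifier sees all three signatures.
#'
#' @param n_epochs total number of trials.
#' @param channel_labels montage labels to simulate.
#' @param p_error error-trial probability.
#' @param snr signature amplitude over noise sd.
#' @param fs sampling rate, Hz.
#' @param n_subjects trials are assigned round-robin to this many subjects.
#' @param seed integer seed.
#' @return An [errp_epochs()] object (161 samples per epoch at the default
#'   rate).
#' @export
simulate_complementary_epochs <- function(n_epochs = 500L,
                                          channel_labels = errp_montage()$label[1:16],
                                          p_error = 0.3, snr = 3, fs = 200,
                                          n_subjects = 2L, seed = 1L) {
  set.seed(seed)
  nch <- length(channel_labels)
  if (nch < 2) stop("need at least 2 channels")
  w <- montage_weights(channel_labels)
  noise_sd <- 10
  win <- epoch_window(fs = fs)
  ns <- win$n_samples
  tt <- seq(win$start_ms, win$end_ms, length.out = ns) / 1000
  bp <- design_bandpass(2, 1, 40, fs)
  pat <- rnorm(nch); pat <- pat / sqrt(sum(pat^2))  # planted spatial pattern
  labels <- ifelse(runif(n_epochs) < p_error, "negative", "positive")
  group <- (seq_len(n_epochs) - 1L) %% 3L + 1L
  amp <- snr * noise_sd
  epochs <- lapply(seq_len(n_epochs), function(k) {
    pad <- 2 * fs  # generate longer, band-pass, then crop (avoids edge bias)
    e <- sapply(seq_len(nch), function(i) zerophase_bandpass(bp, ar_series(ns + pad)))
    e <- t(e)[, (pad / 2 + 1):(pad / 2 + ns), drop = FALSE]
    e <- e / apply(e, 1, sd) * noise_sd
    if (labels[k] == "negative" && amp > 0) {
      if (group[k] == 1L) {
        wave <- -amp * exp(-(tt - 0.3)^2 / (2 * 0.045^2))
        e <- e + outer(w, wave)
      } else if (group[k] == 2L) {
        burst <- amp * sin(2 * pi * 6 * tt + runif(1, 0, 2 * pi)) *
          exp(-(tt - 0.5)^2 / (2 * 0.12^2))
        e <- e + outer(w, burst)
      } else {
        s <- zerophase_bandpass(bp, ar_series(ns + pad))[(pad / 2 + 1):(pad / 2 + ns)]
        e <- e + outer(pat, amp * s / sd(s))
      }
    }
    e
  })
  errp_epochs(epochs, labels,
              subjects = sprintf("S%02d", (seq_len(n_epochs) - 1L) %% n_subjects + 1L),
              channel_labels = channel_labels, fs = fs,
              window = c(win$start_ms, win$end_ms))
}
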