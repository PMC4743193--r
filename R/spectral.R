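#' Empirical mode decomposition
#'
#' Decomposes a waveform into intrinsic mode functions (IMFs) by standard
#' sifting: upper and lower envelopes are natural cubic splines through the
#' local maxima/minima with two extrema mirrored across each boundary, the
#' envelope mean is subtracted, and sifting stops when the Cauchy criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2)` drops below `sd_threshold` or the
#' iteration cap is hit. IMF extraction stops at `max_imfs` or when the
#' residue is monotonic (fewer than two maxima or two minima). By
#' construction the IMFs and residue sum back to the input exactly.
#'
#' @param x numeric waveform, length >= 8, finite.
#' @param max_imfs maximum number of IMFs to extract.
#' @param sd_threshold sifting stop threshold (canonical 0.2).
#' @param max_sift_iters cap on sifting iterations per IMF.
#' @return An object of class `errp_emd`: list with `imfs` (a list of
#'   numeric vectors, possibly empty), `residue`, and `n_imfs`.
#' @examples
#' x <- sin(2 * pi * 25 * (0:159) / 200) + sin(2 * pi * 5 * (0:159) / 200)
#' d <- emd(x)
#' d$n_imfs
#' max(abs(Reduce(`+`, d$imfs) + d$residue - x))  # reconstruction identity
#' @export
emd <- function(x, max_imfs = 4L, sd_threshold = 0.2, max_sift_iters = 100L) {
  x <- as.numeric(x)
  if (length(x) < 8) stop("'x' must have at least 8 samples")
  if (!all(is.finite(x))) stop("'x' contains non-finite values")
  res <- cpp_emd(x, as.integer(max_imfs), sd_threshold,
                 as.integer(max_sift_iters))
  imfs <- if (ncol(res$imfs) > 0)
    lapply(seq_len(ncol(res$imfs)), function(j) res$imfs[, j]) else list()
  structure(list(imfs = imfs, residue = as.numeric(res$residue),
                 n_imfs = length(imfs)),
            class = "errp_emd")
}

#' @export
print.errp_emd <- function(x, ...) {
  cat(sprintf("<errp_emd> %d IMF(s) + residue, %d samples\n",
              x$n_imfs, length(x$residue)))
  invisible(x)
}

#' Hilbert analytic signal and instantaneous quantities
#'
#' Forms the analytic signal `z = c + i H{c}` of an IMF via the frequency-
#' domain Hilbert transform and returns the instantaneous amplitude
#' `|z|`, the unwrapped phase (radians) and the instantaneous frequency
#' `d(phase)/dt` in rad/s, computed by central differences in the interior
#' and one-sided differences at the ends.
#'
#' @param c numeric waveform (typically one IMF), length >= 8.
#' @param fs sampling rate, Hz.
#' @return A list with `amplitude`, `phase`, `inst_frequency` and the
#'   complex `analytic` signal.
#' @export
hilbert_analytic <- function(c, fs) {
  c <- as.numeric(c)
  if (length(c) < 8) stop("'c' must have at least 8 samples")
  if (!all(is.finite(c))) stop("'c' contains non-finite values")
  out <- cpp_hilbert_analysis(c, fs)
  out$amplitude <- as.numeric(out$amplitude)
  out$phase <- as.numeric(out$phase)
  out$inst_frequency <- as.numeric(out$inst_frequency)
  out$analytic <- as.complex(cpp_analytic(c))
  out
}

#' Level-1 spectral feature vector for one epoch channel
#'
#' Runs [emd()] (four IMFs at most), keeps the first three IMFs, and
#' summarizes each with four statistics: relative energy
#' `E_i = sum_t a_i(t)^2 / sum_k sum_t a_k(t)^2` (the Hilbert-spectrum
#' frequency integral collapses to the squared analytic amplitude because a
#' single IMF has one frequency ridge per time point), mean instantaneous
#' frequency `Phi_i` (rad/s by default, Hz with `freq_unit = "hz"`), mean
#' slope `MS_i` (mean first difference times `fs`, microvolt/s), and the
#' coefficient of variation `CV_i = sigma_i / mu_i`. IMFs are near
#' zero-mean, so the CV denominator is guarded by
#' `sign(mu) * max(|mu|, 1e-12 * sigma)`; the statistic is intrinsically
#' unstable and the guard only prevents division by zero, it does not hide
#' the instability. If fewer than three IMFs emerge the missing slots are
#' zero-filled with a warning.
#'
#' @param x numeric epoch channel.
#' @param fs sampling rate, Hz.
#' @param max_imfs decomposition depth (default 4).
#' @param keep_imfs number of IMFs summarized (default 3).
#' @param freq_unit `"rad"` (rad/s, the default) or `"hz"` for `Phi`.
#' @param sd_threshold,max_sift_iters sifting controls, see [emd()].
#' @return Named numeric vector of length `4 * keep_imfs` (12 by default):
#'   `[E_1..3, Phi_1..3, MS_1..3, CV_1..3]`.
#' @export
spectral_feature <- function(x, fs, max_imfs = 4L, keep_imfs = 3L,
                             freq_unit = c("rad", "hz"),
                             sd_threshold = 0.2, max_sift_iters = 100L) {
  freq_unit <- match.arg(freq_unit)
  f <- spectral_features_matrix(matrix(as.numeric(x), nrow = 1), fs,
                                max_imfs, keep_imfs, freq_unit,
                                sd_threshold, max_sift_iters)
  drop(f)
}

# batch path shared with the pipeline: X is epochs x samples; n_short
# (signals with fewer than keep_imfs IMFs) is attached as an attribute
spectral_features_matrix <- function(X, fs, max_imfs = 4L, keep_imfs = 3L,
                                     freq_unit = "rad", sd_threshold = 0.2,
                                     max_sift_iters = 100L, warn = TRUE) {
  if (!all(is.finite(X))) stop("non-finite values in input signals")
  res <- cpp_spectral_features(X, fs, as.integer(max_imfs),
                               as.integer(keep_imfs), sd_threshold,
                               as.integer(max_sift_iters),
                               identical(freq_unit, "hz"))
  if (warn && res$n_short > 0)
    warning(sprintf("%d signal(s) produced fewer than %d IMFs; missing feature slots zero-filled",
                    res$n_short, keep_imfs))
  f <- res$features
  attr(f, "n_short") <- res$n_short
  colnames(f) <- c(sprintf("E_%d", seq_len(keep_imfs)),
                   sprintf("Phi_%d", seq_len(keep_imfs)),
                   sprintf("MS_%d", seq_len(keep_imfs)),
                   sprintf("CV_%d", seq_len(keep_imfs)))
  f
}
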