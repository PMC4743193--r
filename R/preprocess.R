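#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default fourth order, 1-20 Hz) to every
#' channel of a recording independently, forward and backward so that
#' component latencies are not shifted — offline event-related-potential
#' analysis must be zero-phase. The effective magnitude response is
#' therefore the squared one-pass response. The filter runs as a cascade of
#' second-order sections with odd-reflection edge padding, which keeps the
#' operation linear to machine-level accuracy and confines edge transients
#' to the padding.
#'
#' @param recording an [errp_recording()].
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order of the one-pass prototype (per edge).
#' @return The filtered recording, same dimensions, events untouched.
#' @export
bandpass_filter <- function(recording, low_hz = 1, high_hz = 20, order = 4) {
  stopifnot(inherits(recording, "errp_recording"))
  nyq <- recording$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf("band edges must satisfy 0 < low < high < Nyquist (%g Hz)", nyq))
  if (order < 1) stop("'order' must be >= 1")
  des <- design_bandpass(order, low_hz, high_hz, recording$fs)
  out <- recording
  out$data <- t(apply(recording$data, 1, function(ch)
    zerophase_bandpass(des, ch)))
  dimnames(out$data) <- dimnames(recording$data)
  out
}

#' Common average reference
#'
#' Re-references every channel by subtracting the instantaneous mean across
#' all channels, sample by sample. After CAR the cross-channel mean is zero
#' everywhere, and applying CAR twice equals applying it once.
#'
#' @param recording an [errp_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
common_average_reference <- function(recording) {
  stopifnot(inherits(recording, "errp_recording"))
  if (nrow(recording$data) < 2)
    stop("common average reference needs at least 2 channels")
  out <- recording
  out$data <- sweep(recording$data, 2, colMeans(recording$data))
  out
}

#' Epoch window relative to feedback onset
#'
#' Both endpoints are inclusive, so the sample count is
#' `round((end_ms - start_ms) * fs / 1000) + 1`: the default 200-1000 ms
#' window at 200 Hz yields 161 samples, the dimension the spatial feature
#' set inherits.
#'
#' @param start_ms,end_ms window offsets from the event, ms, non-negative,
#'   `start_ms < end_ms`.
#' @param fs sampling rate, Hz.
#' @return An object of class `errp_window` with fields `start_ms`,
#'   `end_ms`, `fs`, `n_samples` and the integer sample `offsets`.
#' @examples
#' epoch_window(fs = 200)$n_samples  # 161
#' @export
epoch_window <- function(start_ms = 200, end_ms = 1000, fs = 200) {
  if (start_ms < 0 || end_ms < 0 || start_ms >= end_ms)
    stop("need 0 <= start_ms < end_ms")
  o1 <- as.integer(round(start_ms * fs / 1000))
  o2 <- as.integer(round(end_ms * fs / 1000))
  structure(list(start_ms = start_ms, end_ms = end_ms, fs = fs,
                 n_samples = o2 - o1 + 1L, offsets = o1:o2),
            class = "errp_window")
}

#' Cut event-locked epochs out of a recording
#'
#' Extracts one channels-by-samples segment per feedback event, in event
#' order. Pure slicing: sample values are never altered. Events whose
#' window would cross a recording boundary are dropped with a warning, not
#' an error.
#'
#' @param recording an [errp_recording()] with at least one event.
#' @param window an [epoch_window()]; its `fs` must match the recording.
#' @return An [errp_epochs()] object.
#' @export
extract_epochs <- function(recording, window = epoch_window(fs = recording$fs)) {
  stopifnot(inherits(recording, "errp_recording"),
            inherits(window, "errp_window"))
  if (window$fs != recording$fs)
    stop("window fs does not match recording fs")
  ev <- recording$events
  if (nrow(ev) == 0) stop("recording has no events")
  n <- ncol(recording$data)
  first <- ev$sample + window$offsets[1]
  last <- ev$sample + window$offsets[length(window$offsets)]
  ok <- first >= 1 & last <= n
  if (any(!ok))
    warning(sprintf("%d event(s) dropped: epoch window outside the recording (events %s)",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  if (!any(ok)) stop("no event has a full epoch window inside the recording")
  eps <- lapply(which(ok), function(i)
    recording$data[, ev$sample[i] + window$offsets, drop = FALSE])
  errp_epochs(eps, ev$label[ok],
              subjects = recording$subject %||% NA_character_,
              channel_labels = recording$channel_labels, fs = recording$fs,
              window = c(window$start_ms, window$end_ms))
}

#' Standard preprocessing chain for one recording
#'
#' Band-pass (1-20 Hz, order 4, zero-phase), optional artifact-removal hook,
#' common average reference, then epoch extraction. The hook is a pluggable
#' stage for e.g. ICA-based artifact removal: any function taking and
#' returning an `errp_recording`; the default pipeline omits it.
#'
#' @param recording an [errp_recording()].
#' @param window an [epoch_window()].
#' @param low_hz,high_hz,order band-pass settings, see [bandpass_filter()].
#' @param artifact_hook `NULL` or `function(recording) recording`.
#' @return An [errp_epochs()] object.
#' @export
preprocess_session <- function(recording,
                               window = epoch_window(fs = recording$fs),
                               low_hz = 1, high_hz = 20, order = 4,
                               artifact_hook = NULL) {
  rec <- bandpass_filter(recording, low_hz, high_hz, order)
  if (!is.null(artifact_hook)) {
    rec <- artifact_hook(rec)
    if (!inherits(rec, "errp_recording"))
      stop("'artifact_hook' must return an errp_recording")
  }
  rec <- common_average_reference(rec)
  extract_epochs(rec, window)
}
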