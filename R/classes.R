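#' Construct a continuous multi-channel recording
#'
#' A recording holds a channels-by-samples signal matrix (microvolts), its
#' sampling rate, ordered channel labels, and the feedback events locked to
#' it. Events are 1-based sample indices with a label that is `"positive"`
#' (correct feedback), `"negative"` (error feedback) or `NA` when labels are
#' supplied separately.
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one per row of `data`.
#' @param events data.frame with columns `sample` (1-based index) and
#'   `label`; may have zero rows.
#' @param subject optional subject identifier.
#' @return An object of class `errp_recording`.
#' @export
errp_recording <- function(data, fs, channel_labels,
                           events = data.frame(sample = integer(),
                                               label = character()),
                           subject = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("'data' must be a numeric matrix")
  if (length(channel_labels) != nrow(data))
    stop("'data' must have one row per channel label (",
         length(channel_labels), " labels, ", nrow(data), " rows)")
  if (anyDuplicated(channel_labels)) stop("duplicate channel labels")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("'fs' must be > 0")
  events <- as.data.frame(events)
  if (!all(c("sample", "label") %in% names(events)))
    stop("'events' needs columns 'sample' and 'label'")
  if (nrow(events) > 0 &&
      (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample indices must lie inside the recording")
  bad <- !is.na(events$label) & !events$label %in% .ERRP_LABELS
  if (any(bad))
    stop("event labels must be 'positive', 'negative' or NA")
  events$sample <- as.integer(events$sample)
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 events = events, subject = subject),
            class = "errp_recording")
}

#' @export
print.errp_recording <- function(x, ...) {
  cat(sprintf("<errp_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (!is.na(x$subject)) cat("  subject:", x$subject, "\n")
  cat(sprintf("  events: %d (%d negative, %d unlabeled)\n",
              nrow(x$events), sum(x$events$label == "negative", na.rm = TRUE),
              sum(is.na(x$events$label))))
  invisible(x)
}

#' Construct a labeled epoch set
#'
#' The container for event-locked EEG segments: a list of channels-by-samples
#' matrices of identical dimension, one binary feedback label and one subject
#' id per epoch, shared channel labels and sampling rate, and the epoch
#' window (ms relative to feedback onset) the segments were cut with.
#'
#' @param epochs list of numeric matrices, all channels x samples.
#' @param labels character vector, `"positive"` / `"negative"` (or `NA`),
#'   one per epoch.
#' @param subjects subject id per epoch (recycled if length one).
#' @param channel_labels channel names, one per matrix row.
#' @param fs sampling rate in Hz.
#' @param window numeric length-2, epoch window start/end in ms.
#' @return An object of class `errp_epochs`.
#' @export
errp_epochs <- function(epochs, labels, subjects, channel_labels, fs,
                        window = c(200, 1000)) {
  if (!length(epochs)) stop("no epochs")
  dims <- vapply(epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all epochs must share the same dimensions")
  if (dims[1, 1] != length(channel_labels))
    stop("epoch rows must match channel_labels")
  if (length(labels) != length(epochs))
    stop("'labels' must have one entry per epoch")
  bad <- !is.na(labels) & !labels %in% .ERRP_LABELS
  if (any(bad)) stop("labels must be 'positive', 'negative' or NA")
  if (length(subjects) == 1) subjects <- rep(subjects, length(epochs))
  if (length(subjects) != length(epochs))
    stop("'subjects' must have one entry per epoch")
  structure(list(epochs = epochs, labels = as.character(labels),
                 subjects = as.character(subjects),
                 channel_labels = as.character(channel_labels),
                 fs = fs, window = window),
            class = "errp_epochs")
}

#' @export
print.errp_epochs <- function(x, ...) {
  d <- dim(x$epochs[[1]])
  cat(sprintf("<errp_epochs> %d epochs, %d channels x %d samples @ %g Hz\n",
              length(x$epochs), d[1], d[2], x$fs))
  cat(sprintf("  window: %g-%g ms;  labels: %d positive / %d negative;  %d subject(s)\n",
              x$window[1], x$window[2],
              sum(x$labels == "positive", na.rm = TRUE),
              sum(x$labels == "negative", na.rm = TRUE),
              length(unique(x$subjects))))
  invisible(x)
}

#' Subset an epoch set
#'
#' `subset_epochs` keeps a subset of epochs (by index or logical mask);
#' `subset_channels` keeps a subset of channels (by label), preserving the
#' requested order. `bind_epochs` concatenates epoch sets that share
#' channels, sampling rate and window.
#'
#' @param x an `errp_epochs` object.
#' @param idx integer or logical epoch selector.
#' @return An `errp_epochs` object.
#' @export
subset_epochs <- function(x, idx) {
  stopifnot(inherits(x, "errp_epochs"))
  errp_epochs(x$epochs[idx], x$labels[idx], x$subjects[idx],
              x$channel_labels, x$fs, x$window)
}

#' @rdname subset_epochs
#' @param channels character vector of channel labels to keep.
#' @export
subset_channels <- function(x, channels) {
  stopifnot(inherits(x, "errp_epochs"))
  pos <- match(channels, x$channel_labels)
  if (anyNA(pos))
    stop("channel(s) not present: ",
         paste(channels[is.na(pos)], collapse = ", "))
  errp_epochs(lapply(x$epochs, function(e) e[pos, , drop = FALSE]),
              x$labels, x$subjects, channels, x$fs, x$window)
}

#' @rdname subset_epochs
#' @param ... `errp_epochs` objects to concatenate.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "errp_epochs")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1)
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s$channel_labels, ref$channel_labels) ||
        !identical(s$fs, ref$fs) || !identical(s$window, ref$window))
      stop("epoch sets differ in channels, fs or window")
  }
  errp_epochs(unlist(lapply(sets, `[[`, "epochs"), recursive = FALSE),
              unlist(lapply(sets, `[[`, "labels")),
              unlist(lapply(sets, `[[`, "subjects")),
              ref$channel_labels, ref$fs, ref$window)
}

# channels x samples x epochs array, for fast per-channel slicing
epoch_array <- function(x) {
  d <- dim(x$epochs[[1]])
  array(unlist(x$epochs, use.names = FALSE),
        dim = c(d[1], d[2], length(x$epochs)))
}

# n_epochs x n_samples matrix for one channel index
channel_matrix <- function(arr, ch) t(arr[ch, , , drop = TRUE])
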