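#' Read and write labeled epoch CSV files
#'
#' The canonical epoch store is a wide CSV: comment lines
#' `# fs=<Hz>`, `# window_start_ms=<ms>`, `# window_end_ms=<ms>` followed
#' by a header `epoch_id,subject,label,channel,s000,...,s{N-1}` and one row
#' per (epoch, channel), values in microvolts. Every epoch must have
#' exactly one row per channel; channel order is taken from the first
#' epoch and must repeat identically. Round trips are lossless to printed
#' precision (better than 1e-9 relative).
#'
#' @param path file path.
#' @return `read_epochs` returns an [errp_epochs()] object.
#' @export
read_epochs <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("no epochs: ", path, " is empty")
  hdr <- grep("^#", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- strsplit(sub("^#\\s*", "", l), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- as.numeric(kv[2])
  }
  for (key in c("fs", "window_start_ms", "window_end_ms"))
    if (is.null(meta[[key]])) stop("missing '", key, "' metadata line in ", path)
  df <- read.csv(path, skip = length(hdr), stringsAsFactors = FALSE,
                 check.names = FALSE)
  need <- c("epoch_id", "subject", "label", "channel")
  if (!all(need %in% names(df)))
    stop("epoch file must have columns ", paste(need, collapse = ", "))
  if (nrow(df) == 0) stop("no epochs in ", path)
  scols <- grep("^s[0-9]+$", names(df), value = TRUE)
  if (!length(scols)) stop("no sample columns (s000...) in ", path)
  bad_lab <- !df$label %in% .ERRP_LABELS & df$label != "NA" & !is.na(df$label)
  if (any(bad_lab))
    stop("unknown label(s) at data line(s) ",
         paste(utils::head(which(bad_lab), 5), collapse = ", "),
         ": ", paste(unique(df$label[bad_lab]), collapse = ", "))
  ids <- unique(df$epoch_id)
  channels <- df$channel[df$epoch_id == ids[1]]
  if (anyDuplicated(channels))
    stop("duplicate channel rows for epoch_id ", ids[1])
  nch <- length(channels)
  smat <- as.matrix(df[, scols])
  epochs <- vector("list", length(ids))
  labels <- character(length(ids)); subjects <- character(length(ids))
  for (k in seq_along(ids)) {
    rows <- which(df$epoch_id == ids[k])
    if (length(rows) != nch || !identical(df$channel[rows], channels))
      stop("epoch_id ", ids[k], " does not have exactly one row per channel ",
           "in the expected order (data lines ",
           paste(range(rows), collapse = "-"), ")")
    if (anyDuplicated(df$channel[rows]))
      stop("duplicate channel rows for epoch_id ", ids[k])
    epochs[[k]] <- unname(smat[rows, , drop = FALSE])
    labels[k] <- df$label[rows[1]]
    subjects[k] <- df$subject[rows[1]]
  }
  labels[which(labels == "NA")] <- NA_character_
  errp_epochs(epochs, labels, subjects, channels, meta$fs,
              window = c(meta$window_start_ms, meta$window_end_ms))
}

#' @rdname read_epochs
#' @param x an [errp_epochs()] object.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "errp_epochs"))
  ns <- ncol(x$epochs[[1]])
  nch <- length(x$channel_labels)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", x$fs),
               sprintf("# window_start_ms=%.10g", x$window[1]),
               sprintf("# window_end_ms=%.10g", x$window[2])), con)
  writeLines(paste(c("epoch_id", "subject", "label", "channel",
                     sprintf("s%03d", seq_len(ns) - 1)), collapse = ","), con)
  for (k in seq_along(x$epochs)) {
    vals <- apply(x$epochs[[k]], 1, function(v)
      paste(sprintf("%.10g", v), collapse = ","))
    writeLines(paste(k, x$subjects[k], ifelse(is.na(x$labels[k]), "NA", x$labels[k]),
                     x$channel_labels, vals, sep = ","), con)
  }
  invisible(path)
}

#' Read a continuous-recording CSV (challenge dialect)
#'
#' Reads the continuous-recording dialect: a `Time` column (seconds,
#' strictly increasing), one column per scalp channel, an `EOG` column
#' (dropped — ocular artifacts are outside the scalp montage), and a
#' `FeedBackEvent` column that is 1 at feedback onsets and 0 elsewhere.
#' The sampling rate is inferred as the reciprocal of the median time
#' step. Event labels are absent in this format; attach them afterwards
#' with [attach_labels()].
#'
#' @param path file path.
#' @return An [errp_recording()] with unlabeled events.
#' @export
read_challenge_recording <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!all(c("Time", "FeedBackEvent") %in% names(df)))
    stop("recording file needs 'Time' and 'FeedBackEvent' columns")
  if (any(diff(df$Time) <= 0)) stop("'Time' must be strictly increasing")
  if (!all(df$FeedBackEvent %in% c(0, 1)))
    stop("'FeedBackEvent' must be 0/1")
  chan_cols <- setdiff(names(df), c("Time", "EOG", "FeedBackEvent"))
  if (!length(chan_cols)) stop("no channel columns found")
  fs <- 1 / stats::median(diff(df$Time))
  ev <- which(df$FeedBackEvent == 1)
  errp_recording(t(as.matrix(df[, chan_cols])), fs, chan_cols,
                 events = data.frame(sample = ev,
                                     label = rep(NA_character_, length(ev)),
                                     stringsAsFactors = FALSE))
}

#' @rdname read_challenge_recording
#' @param recording an [errp_recording()].
#' @export
write_challenge_recording <- function(recording, path) {
  stopifnot(inherits(recording, "errp_recording"))
  n <- ncol(recording$data)
  fb <- integer(n)
  fb[recording$events$sample] <- 1L
  df <- data.frame(Time = (seq_len(n) - 1) / recording$fs,
                   check.names = FALSE)
  for (i in seq_along(recording$channel_labels))
    df[[recording$channel_labels[i]]] <- recording$data[i, ]
  df$EOG <- 0
  df$FeedBackEvent <- fb
  write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach feedback labels to a recording's events
#'
#' Labels for challenge-style recordings ship separately as a two-column
#' CSV `epoch_id,label` where `epoch_id` is the 1-based event number.
#'
#' @param recording an [errp_recording()].
#' @param path path of the label CSV.
#' @return The recording with labeled events.
#' @export
attach_labels <- function(recording, path) {
  stopifnot(inherits(recording, "errp_recording"))
  lab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_id", "label") %in% names(lab)))
    stop("label file needs columns 'epoch_id' and 'label'")
  if (any(!lab$label %in% .ERRP_LABELS)) stop("unknown labels in ", path)
  if (any(lab$epoch_id < 1 | lab$epoch_id > nrow(recording$events)))
    stop("epoch_id out of range in ", path)
  recording$events$label[lab$epoch_id] <- lab$label
  recording
}

#' Write prediction scores as CSV
#'
#' @param scores numeric scores.
#' @param labels predicted labels.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_predictions <- function(scores, labels, path) {
  write.csv(data.frame(epoch_id = seq_along(scores),
                       score = sprintf("%.10g", scores), label = labels),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
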