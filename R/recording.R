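#' Condition labels
#'
#' The ten experimental conditions a recording can carry: three active
#' stepping conditions (arms, arms and legs, legs), three self-viewed and
#' three other-viewed playback conditions, and one device-only control.
#'
#' @return Character vector of the ten valid condition labels.
#' @export
condition_labels <- function() {
  c("active_arms", "active_arms_legs", "active_legs",
    "viewed_self_arms", "viewed_self_arms_legs", "viewed_self_legs",
    "viewed_other_arms", "viewed_other_arms_legs", "viewed_other_legs",
    "viewed_stepper_control")
}

#' Limb labels
#'
#' @return Character vector of the four limbs that produce full-extension
#'   events.
#' @export
limb_labels <- function() {
  c("left_arm", "right_arm", "left_leg", "right_leg")
}

#' Construct a multichannel recording
#'
#' A `recording` is the common currency of the pipeline: a channels-by-samples
#' matrix in microvolts with its sampling rate, channel labels and metadata.
#' Time is in seconds throughout; sample index 0 corresponds to t = 0 and
#' sample i to t = i / fs.
#'
#' @param data Numeric matrix, channels x samples (microvolts).
#' @param fs Sampling rate in Hz, > 0.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param subject_id Subject identifier string.
#' @param condition One of [condition_labels()], or `NA` when not applicable.
#' @return An object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL,
                      subject_id = "synthetic", condition = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  dimnames(data) <- NULL
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  rec <- structure(
    list(data = data, fs = fs, channel_labels = as.character(channel_labels),
         subject_id = subject_id, condition = condition),
    class = "recording")
  validate_recording(rec)
  rec
}

validate_recording <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(rec$fs) || length(rec$fs) != 1L || rec$fs <= 0) {
    stop("sampling rate must be a single positive number")
  }
  if (length(rec$channel_labels) != nrow(rec$data)) {
    stop(sprintf("%d channel labels but %d data rows",
                 length(rec$channel_labels), nrow(rec$data)))
  }
  if (anyNA(rec$data)) stop("recording contains missing values")
  if (!is.na(rec$condition) && !(rec$condition %in% condition_labels())) {
    stop("unknown condition label: ", rec$condition)
  }
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat(sprintf("  subject: %s  condition: %s\n", x$subject_id, x$condition))
  invisible(x)
}

#' @export
dim.recording <- function(x) dim(x$data)

#' Duration of a recording in seconds
#' @param rec A [recording].
#' @return Duration in seconds.
#' @export
rec_duration <- function(rec) ncol(rec$data) / rec$fs

#' Construct a full-extension event table
#'
#' Rows are full-extension events of one limb, ordered by onset. Onsets are
#' seconds from the start of the recording.
#'
#' @param onset Numeric vector of event onsets (s), all >= 0.
#' @param limb Character vector of limbs, values in [limb_labels()].
#' @param kind Event kind; only `"full_extension"` is used by the pipeline.
#' @return A `data.frame` of class `event_table`, sorted by onset.
#' @export
event_table <- function(onset = numeric(0),
                        limb = character(0),
                        kind = "full_extension") {
  if (length(onset) && any(onset < 0)) stop("negative event onset")
  bad <- setdiff(unique(limb), limb_labels())
  if (length(bad)) stop("unknown limb label(s): ", paste(bad, collapse = ", "))
  ev <- data.frame(onset = as.numeric(onset),
                   limb = as.character(limb),
                   kind = rep_len(as.character(kind), length(onset)),
                   stringsAsFactors = FALSE)
  ev <- ev[order(ev$onset), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Onsets of one limb's events
#' @param events An [event_table()].
#' @param limb A limb label.
#' @return Sorted numeric vector of onsets (s).
#' @export
limb_onsets <- function(events, limb) {
  sort(events$onset[events$limb == limb])
}
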