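#' Construct a single-session EMG recording
#'
#' A recording holds the continuous multichannel samples of one experimental
#' session together with its segment annotations. Sample intervals are
#' 0-based and half-open: an annotation covers samples
#' `start_sample, ..., end_sample - 1`.
#'
#' @param samples Numeric matrix, time x channel, arbitrary units.
#' @param fs Sampling rate in Hz.
#' @param annotations Tibble/data frame with columns `movement` (one of
#'   [movement_classes()]), `repetition` (integer), `start_sample`,
#'   `end_sample` (0-based, half-open). May have zero rows.
#' @param subject_id Subject identifier (integer or string).
#' @param day 1-based day index.
#' @param session Session index within the day (1 or 2 in the study protocol).
#'
#' @return An object of class `emg_recording`.
#' @examples
#' rec <- emg_recording(matrix(0, 1600, 8), fs = 200)
#' @export
emg_recording <- function(samples, fs, annotations = NULL,
                          subject_id = 1L, day = 1L, session = 1L) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(annotations)) {
    annotations <- tibble::tibble(
      movement = character(0), repetition = integer(0),
      start_sample = integer(0), end_sample = integer(0)
    )
  }
  annotations <- tibble::as_tibble(annotations)
  rec <- structure(
    list(
      samples = samples,
      fs = fs,
      channels = ncol(samples),
      subject_id = subject_id,
      day = as.integer(day),
      session = as.integer(session),
      annotations = annotations
    ),
    class = "emg_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate an EMG recording
#'
#' Checks the recording invariants: positive sampling rate, channel count
#' matching the sample matrix, and annotations that are sorted, non-overlapping
#' and contained in `[0, T)`.
#'
#' @param rec An `emg_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error naming the field.
#' @export
validate_recording <- function(rec) {
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0) {
    abort_field("fs", "sampling rate must be a single positive number")
  }
  if (!is.matrix(rec$samples)) abort_field("samples", "must be a matrix")
  if (rec$channels != ncol(rec$samples)) {
    abort_field("channels", "must equal the number of sample columns")
  }
  ann <- rec$annotations
  req <- c("movement", "repetition", "start_sample", "end_sample")
  if (!all(req %in% names(ann))) {
    abort_field("annotations", paste(
      "missing column(s):", paste(setdiff(req, names(ann)), collapse = ", ")
    ))
  }
  if (nrow(ann) > 0) {
    if (!all(ann$movement %in% movement_classes())) {
      abort_field("annotations$movement", paste(
        "labels must be drawn from", paste(movement_classes(), collapse = ", ")
      ))
    }
    if (any(ann$end_sample <= ann$start_sample)) {
      abort_field("annotations", "end_sample must exceed start_sample")
    }
    if (any(ann$start_sample < 0) || any(ann$end_sample > nrow(rec$samples))) {
      abort_field("annotations", "segments must lie within [0, T)")
    }
    if (is.unsorted(ann$start_sample, strictly = FALSE)) {
      abort_field("annotations", "segments must be sorted by start_sample")
    }
    if (nrow(ann) > 1 &&
        any(ann$start_sample[-1] < ann$end_sample[-nrow(ann)])) {
      abort_field("annotations", "segments must not overlap")
    }
  }
  invisible(rec)
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> subject %s, day %d, session %d\n",
    x$subject_id, x$day, x$session
  ))
  cat(sprintf(
    "  %d samples x %d channels @ %g Hz (%.1f s), %d annotated segments\n",
    nrow(x$samples), x$channels, x$fs, nrow(x$samples) / x$fs,
    nrow(x$annotations)
  ))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec An `emg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) nrow(rec$samples) / rec$fs
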