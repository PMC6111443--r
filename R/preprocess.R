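#' High-pass filter a recording
#'
#' Applies a causal, single-pass Butterworth high-pass filter (default third
#' order, 2 Hz cutoff) to every channel, removing movement artifacts and DC
#' offsets. The filter state is initialized to the steady-state response to
#' the first sample, which suppresses the startup transient (for a high-pass
#' filter the steady-state response to a constant is identically zero, so this
#' is implemented exactly by filtering `x - x[1]`). A zero-phase
#' forward-backward variant is available behind `zero_phase = TRUE`.
#'
#' @param rec An [emg_recording()].
#' @param order Filter order.
#' @param cutoff_hz Cutoff frequency in Hz; must be below Nyquist.
#' @param zero_phase Use forward-backward (zero-phase) filtering instead of
#'   the causal single pass.
#' @return The filtered recording; annotations unchanged.
#' @export
highpass <- function(rec, order = 3, cutoff_hz = 2, zero_phase = FALSE) {
  validate_recording(rec)
  if (cutoff_hz <= 0 || cutoff_hz >= rec$fs / 2) {
    abort_field("cutoff_hz", sprintf(
      "must lie in (0, %g) Hz (Nyquist)", rec$fs / 2
    ))
  }
  bf <- signal::butter(order, cutoff_hz / (rec$fs / 2), type = "high")
  out <- rec
  for (k in seq_len(rec$channels)) {
    x <- rec$samples[, k]
    if (zero_phase) {
      out$samples[, k] <- signal::filtfilt(bf, x)
    } else {
      out$samples[, k] <- signal::filter(bf, x - x[1])
    }
  }
  out
}

#' Trim transition periods from annotated segments
#'
#' Shrinks every annotation by `trim_s` seconds at each end, discarding the
#' movement onset/offset transients around each contraction.
#'
#' @param rec An [emg_recording()].
#' @param trim_s Seconds removed at each end of every segment.
#' @return The recording with trimmed annotations; samples unchanged.
#' @export
trim_transitions <- function(rec, trim_s = 0.5) {
  validate_recording(rec)
  if (trim_s < 0) abort_field("trim_s", "must be nonnegative")
  if (trim_s == 0) return(rec)
  n <- round_half_up(trim_s * rec$fs)
  ann <- rec$annotations
  too_short <- ann$end_sample - ann$start_sample <= 2 * n
  if (any(too_short)) {
    bad <- ann[too_short, ]
    stop(sprintf(
      "segment too short to trim %g s per side: %s",
      trim_s,
      paste(sprintf("%s rep %d [%d,%d)", bad$movement, bad$repetition,
                    bad$start_sample, bad$end_sample), collapse = "; ")
    ), call. = FALSE)
  }
  ann$start_sample <- ann$start_sample + n
  ann$end_sample <- ann$end_sample - n
  rec$annotations <- ann
  rec
}

#' Extract overlapping labeled windows from a recording
#'
#' Slides a window of `window_ms` with step `step_ms` over every annotated
#' segment; windows never cross segment boundaries. At 200 Hz the defaults
#' give 30-sample windows with a 5-sample step, i.e. 30 x 8 inputs for the
#' raw-signal classifiers.
#'
#' @param rec An [emg_recording()] (typically filtered and trimmed).
#' @param window_ms Window length in milliseconds.
#' @param step_ms Step between consecutive windows in milliseconds.
#' @return An `emg_windows` object: list with `windows` (W x L x C array),
#'   `meta` (tibble: subject_id, day, session, movement, repetition,
#'   start_sample), `fs`, `window_samples`, `step_samples`.
#' @export
extract_windows <- function(rec, window_ms = 150, step_ms = 25) {
  validate_recording(rec)
  L <- round_half_up(window_ms * rec$fs / 1000)
  s <- round_half_up(step_ms * rec$fs / 1000)
  if (L < 1 || s < 1) {
    abort_field("window_ms/step_ms", "must map to at least one sample")
  }
  ann <- rec$annotations
  win_list <- list()
  meta_list <- list()
  for (i in seq_len(nrow(ann))) {
    n <- ann$end_sample[i] - ann$start_sample[i]
    if (n < L) {
      warning(sprintf(
        "skipping segment %s rep %d: %d samples < window length %d",
        ann$movement[i], ann$repetition[i], n, L
      ), call. = FALSE)
      next
    }
    offsets <- seq(0, n - L, by = s)
    starts <- ann$start_sample[i] + offsets
    win_list[[length(win_list) + 1]] <- lapply(starts, function(t0) {
      rec$samples[(t0 + 1):(t0 + L), , drop = FALSE]
    })
    meta_list[[length(meta_list) + 1]] <- tibble::tibble(
      subject_id = rec$subject_id, day = rec$day, session = rec$session,
      movement = ann$movement[i], repetition = ann$repetition[i],
      start_sample = starts
    )
  }
  mats <- unlist(win_list, recursive = FALSE)
  W <- length(mats)
  windows <- array(0, dim = c(W, L, rec$channels))
  for (w in seq_len(W)) windows[w, , ] <- mats[[w]]
  meta <- if (W > 0) dplyr::bind_rows(meta_list) else tibble::tibble(
    subject_id = character(0), day = integer(0), session = integer(0),
    movement = character(0), repetition = integer(0), start_sample = integer(0)
  )
  new_windows(windows, meta, rec$fs, L, s)
}

new_windows <- function(windows, meta, fs, L, s) {
  structure(
    list(windows = windows, meta = meta, fs = fs,
         window_samples = L, step_samples = s),
    class = "emg_windows"
  )
}

#' Combine window sets from multiple sessions
#'
#' @param ws_list List of `emg_windows` objects with matching window geometry.
#' @return A single `emg_windows` object.
#' @export
bind_windows <- function(ws_list) {
  stopifnot(length(ws_list) > 0)
  L <- ws_list[[1]]$window_samples
  C <- dim(ws_list[[1]]$windows)[3]
  if (!all(vapply(ws_list, function(w) {
    w$window_samples == L && dim(w$windows)[3] == C
  }, logical(1)))) {
    stop("window sets have mismatched geometry", call. = FALSE)
  }
  Ws <- vapply(ws_list, function(w) dim(w$windows)[1], integer(1))
  windows <- array(0, dim = c(sum(Ws), L, C))
  at <- 0
  for (w in ws_list) {
    n <- dim(w$windows)[1]
    if (n > 0) windows[(at + 1):(at + n), , ] <- w$windows
    at <- at + n
  }
  new_windows(windows, dplyr::bind_rows(lapply(ws_list, `[[`, "meta")),
              ws_list[[1]]$fs, L, ws_list[[1]]$step_samples)
}

#' Subset a window set by row index
#'
#' @param ws An `emg_windows` object.
#' @param idx Integer or logical index over windows.
#' @return The subsetted `emg_windows`.
#' @export
subset_windows <- function(ws, idx) {
  new_windows(ws$windows[idx, , , drop = FALSE], ws$meta[idx, ],
              ws$fs, ws$window_samples, ws$step_samples)
}

#' @export
print.emg_windows <- function(x, ...) {
  cat(sprintf(
    "<emg_windows> %d windows of %d samples x %d channels @ %g Hz\n",
    dim(x$windows)[1], x$window_samples, dim(x$windows)[3], x$fs
  ))
  invisible(x)
}

#' Run the standard preprocessing pipeline over a whole dataset
#'
#' High-pass filters, trims transitions, and extracts overlapping windows
#' from every session of a manifest, returning one combined window set.
#'
#' @param manifest An `emg_manifest` with loaded recordings.
#' @param cutoff_hz,order High-pass filter parameters (see [highpass()]).
#' @param trim_s Transition trim per segment end (see [trim_transitions()]).
#' @param window_ms,step_ms Windowing parameters (see [extract_windows()]).
#' @return An `emg_windows` spanning all sessions.
#' @export
dataset_windows <- function(manifest, cutoff_hz = 2, order = 3, trim_s = 0.5,
                            window_ms = 150, step_ms = 25) {
  stopifnot(inherits(manifest, "emg_manifest"))
  ws_list <- lapply(manifest$sessions$recording, function(rec) {
    rec |>
      highpass(order = order, cutoff_hz = cutoff_hz) |>
      trim_transitions(trim_s = trim_s) |>
      extract_windows(window_ms = window_ms, step_ms = step_ms)
  })
  bind_windows(ws_list)
}
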