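#' Write a session recording to disk
#'
#' One session is stored as two plain-text files: a samples CSV (one row per
#' time step, one column per channel) and an annotations CSV with columns
#' `movement, repetition, start_sample, end_sample`. Values round-trip at
#' better than float32 precision.
#'
#' @param rec A validated [emg_recording()].
#' @param root Directory to write into (created if absent).
#' @return The path prefix (without `_samples.csv` / `_annotations.csv`),
#'   invisibly.
#' @export
write_session <- function(rec, root) {
  validate_recording(rec)
  if (!dir.exists(root)) {
    ok <- dir.create(root, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", root, call. = FALSE)
  }
  prefix <- file.path(root, session_stem(rec$subject_id, rec$day, rec$session))
  samp <- rec$samples
  colnames(samp) <- paste0("ch", seq_len(ncol(samp)))
  utils::write.csv(format(as.data.frame(samp), digits = 9, trim = TRUE),
                   paste0(prefix, "_samples.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(as.data.frame(rec$annotations),
                   paste0(prefix, "_annotations.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(prefix)
}

session_stem <- function(subject_id, day, session) {
  sprintf("sub%s_day%02d_ses%d", subject_id, day, session)
}

#' Read a session recording from disk
#'
#' @param prefix Path prefix as returned by [write_session()], or a manifest
#'   session row (see [read_manifest()]).
#' @param fs Sampling rate in Hz of the stored data.
#' @param subject_id,day,session Identifiers to attach; parsed from the file
#'   stem when `NULL`.
#' @return A validated [emg_recording()].
#' @export
read_session <- function(prefix, fs = 200, subject_id = NULL, day = NULL,
                         session = NULL) {
  sfile <- paste0(prefix, "_samples.csv")
  afile <- paste0(prefix, "_annotations.csv")
  for (f in c(sfile, afile)) {
    if (!file.exists(f)) stop("file not found: ", f, call. = FALSE)
  }
  samp <- tryCatch(
    utils::read.csv(sfile, colClasses = "numeric"),
    error = function(e) stop("parse error in ", sfile, ": ",
                             conditionMessage(e), call. = FALSE),
    warning = function(w) stop("parse error in ", sfile, ": ",
                               conditionMessage(w), call. = FALSE)
  )
  if (anyNA(samp)) stop("parse error in ", sfile, ": non-numeric or missing values",
                        call. = FALSE)
  ann <- utils::read.csv(afile, stringsAsFactors = FALSE)
  stem <- basename(prefix)
  m <- regmatches(stem, regexec("^sub(.+)_day([0-9]+)_ses([0-9]+)$", stem))[[1]]
  if (is.null(subject_id)) subject_id <- if (length(m)) m[2] else "unknown"
  if (is.null(day)) day <- if (length(m)) as.integer(m[3]) else 1L
  if (is.null(session)) session <- if (length(m)) as.integer(m[4]) else 1L
  emg_recording(as.matrix(samp), fs = fs, annotations = ann,
                subject_id = subject_id, day = day, session = session)
}

#' Write a dataset manifest
#'
#' The manifest (JSON) records the subject x day x session grid, the shared
#' sampling rate, channel count and class names, per-session file prefixes,
#' and generator provenance (seed and config hash) for synthetic datasets.
#'
#' @param manifest An `emg_manifest` (see [generate_dataset()]).
#' @param root Directory holding the session files.
#' @return The manifest file path, invisibly.
#' @export
write_manifest <- function(manifest, root) {
  path <- file.path(root, "manifest.json")
  out <- list(
    fs = manifest$fs,
    channels = manifest$channels,
    classes = manifest$classes,
    sessions = manifest$sessions[
      c("subject_id", "day", "session", "prefix")
    ],
    provenance = manifest$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a dataset manifest and its sessions
#'
#' @param root Directory containing `manifest.json` and the session files.
#' @param load Load the session recordings into memory (default `TRUE`).
#' @return An `emg_manifest`: a list with `fs`, `channels`, `classes`, a
#'   `sessions` tibble (one row per session, with a `recording` list-column
#'   when `load = TRUE`) and `provenance`.
#' @export
read_manifest <- function(root, load = TRUE) {
  path <- file.path(root, "manifest.json")
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sessions <- tibble::as_tibble(raw$sessions)
  sessions$prefix <- file.path(root, basename(sessions$prefix))
  man <- structure(
    list(
      fs = raw$fs, channels = raw$channels, classes = raw$classes,
      sessions = sessions, provenance = raw$provenance
    ),
    class = "emg_manifest"
  )
  if (load) {
    man$sessions$recording <- purrr::pmap(
      sessions[c("prefix", "subject_id", "day", "session")],
      function(prefix, subject_id, day, session) {
        rec <- read_session(prefix, fs = raw$fs, subject_id = subject_id,
                            day = day, session = session)
        if (rec$channels != raw$channels) {
          stop("schema error: session ", basename(prefix), " has ",
               rec$channels, " channels, manifest says ", raw$channels,
               call. = FALSE)
        }
        rec
      }
    )
  }
  man
}

#' @export
print.emg_manifest <- function(x, ...) {
  cat(sprintf(
    "<emg_manifest> %d sessions (%d subject(s)), %d channels @ %g Hz\n",
    nrow(x$sessions), length(unique(x$sessions$subject_id)), x$channels, x$fs
  ))
  invisible(x)
}
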