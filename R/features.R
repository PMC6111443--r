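#' Hudgins time-domain features
#'
#' The four classical time-domain features of myoelectric pattern
#' recognition, computed per window per channel: mean absolute value (MAV),
#' waveform length (WL), slope-sign-change count (SSC) and zero-crossing
#' count (ZC). SSC and ZC use a zero threshold by default: with threshold 0
#' the amplitude condition is vacuous and the strict product tests mean exact
#' zero samples never count.
#'
#' @param x Numeric vector, one channel of one window.
#' @param threshold Amplitude threshold for SSC/ZC (default 0).
#' @return A scalar feature value (integer count for `zc`/`ssc`).
#' @examples
#' mav(c(1, -1, 2, -2))  # 1.5
#' wl(c(0, 1, 3, 2))     # 4
#' zc(c(1, -1, 1, -1))   # 3
#' ssc(c(0, 2, 1, 3))    # 2
#' @name td_features
NULL

#' @rdname td_features
#' @export
mav <- function(x) {
  if (length(x) < 1) abort_field("x", "needs at least 1 sample")
  mean(abs(x))
}

#' @rdname td_features
#' @export
wl <- function(x) {
  if (length(x) < 2) abort_field("x", "needs at least 2 samples")
  sum(abs(diff(x)))
}

#' @rdname td_features
#' @export
zc <- function(x, threshold = 0) {
  if (length(x) < 2) abort_field("x", "needs at least 2 samples")
  a <- x[-length(x)]
  b <- x[-1]
  sum(a * b < 0 & abs(a - b) >= threshold)
}

#' @rdname td_features
#' @export
ssc <- function(x, threshold = 0) {
  if (length(x) < 3) abort_field("x", "needs at least 3 samples")
  n <- length(x)
  mid <- x[2:(n - 1)]
  d1 <- mid - x[1:(n - 2)]
  d2 <- mid - x[3:n]
  sum(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= threshold)
}

#' Compute the 4 x C time-domain feature set for every window
#'
#' Applies MAV, WL, SSC and ZC channel-wise to each window, yielding the
#' 4 x 8 = 32-dimensional inputs used by the LDA and feature-based
#' autoencoder classifiers. Features are flattened channel-major
#' (ch1: MAV, WL, SSC, ZC; ch2: ...).
#'
#' @param ws An `emg_windows` object (see [extract_windows()]).
#' @param threshold Amplitude threshold passed to [zc()] and [ssc()].
#' @return An `emg_features` object: list with `x` (W x 4C feature matrix
#'   with named columns), `meta` (copied from `ws`), `threshold`,
#'   `n_features` (4) and `channels`.
#' @export
featurize <- function(ws, threshold = 0) {
  stopifnot(inherits(ws, "emg_windows"))
  dims <- dim(ws$windows)
  W <- dims[1]; L <- dims[2]; C <- dims[3]
  feats <- matrix(0, W, 4 * C)
  for (k in seq_len(C)) {
    ch <- ws$windows[, , k, drop = TRUE]
    if (W == 1) ch <- matrix(ch, 1, L)
    absx <- abs(ch)
    d <- ch[, -1, drop = FALSE] - ch[, -L, drop = FALSE]
    a <- ch[, -L, drop = FALSE]
    b <- ch[, -1, drop = FALSE]
    mid <- ch[, 2:(L - 1), drop = FALSE]
    d1 <- mid - ch[, 1:(L - 2), drop = FALSE]
    d2 <- mid - ch[, 3:L, drop = FALSE]
    col0 <- (k - 1) * 4
    feats[, col0 + 1] <- rowMeans(absx)
    feats[, col0 + 2] <- rowSums(abs(d))
    feats[, col0 + 3] <- rowSums(d1 * d2 > 0 & pmax(abs(d1), abs(d2)) >= threshold)
    feats[, col0 + 4] <- rowSums(a * b < 0 & abs(a - b) >= threshold)
  }
  colnames(feats) <- as.vector(vapply(
    seq_len(C),
    function(k) paste0("ch", k, "_", c("mav", "wl", "ssc", "zc")),
    character(4)
  ))
  structure(
    list(x = feats, meta = ws$meta, threshold = threshold,
         n_features = 4L, channels = C),
    class = "emg_features"
  )
}

#' Export a feature set as a tibble
#'
#' One row per window: provenance metadata followed by the named feature
#' columns, suitable for writing to CSV.
#'
#' @param fs An `emg_features` object.
#' @return A tibble with `nrow(fs$meta)` rows.
#' @export
features_as_tibble <- function(fs) {
  stopifnot(inherits(fs, "emg_features"))
  dplyr::bind_cols(fs$meta, tibble::as_tibble(fs$x))
}

#' @export
print.emg_features <- function(x, ...) {
  cat(sprintf(
    "<emg_features> %d windows x %d features (%d TD features x %d channels)\n",
    nrow(x$x), ncol(x$x), x$n_features, x$channels
  ))
  invisible(x)
}
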