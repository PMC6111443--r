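make_rec <- function(x, fs = 200, ann = NULL) {
  emg_recording(matrix(x, ncol = 1), fs = fs, annotations = ann)
}

test_that("high-pass removes DC and has the analytic Butterworth gains", {
  fs <- 200
  t <- seq(0, 10, by = 1 / fs)[-1]
  # constant input: output 0 (steady-state initialization); check beyond 2 s
  dc <- make_rec(rep(5, length(t)))
  y <- highpass(dc)$samples[, 1]
  expect_lt(max(abs(y[t > 2])), 1e-3 * 5)

  amp_ratio <- function(f_hz) {
    x <- sin(2 * pi * f_hz * t)
    y <- highpass(make_rec(x))$samples[, 1]
    ss <- t > 5                       # steady state, whole cycles
    sqrt(mean(y[ss]^2) / mean(x[ss]^2))
  }
  # third-order Butterworth at cutoff: |H| = 1/sqrt(2)
  expect_lt(abs(amp_ratio(2) - 1 / sqrt(2)), 0.01 / sqrt(2))
  # far above cutoff: |H| = 1/sqrt(1 + (2/50)^6) > 0.999
  expect_gt(amp_ratio(50), 0.999)
})

test_that("filtering is linear and leaves annotations unchanged", {
  rec <- random_recording(2)
  a <- 3.7
  scaled <- rec
  scaled$samples <- rec$samples * a
  y1 <- highpass(rec)
  y2 <- highpass(scaled)
  expect_lt(max(abs(y2$samples - a * y1$samples)), 1e-9 * max(abs(y1$samples)))
  expect_identical(y1$annotations, rec$annotations)
  expect_error(highpass(rec, cutoff_hz = 120), "cutoff")
})

test_that("transition trimming shrinks segments by round(trim_s * fs)", {
  ann <- tibble::tibble(movement = "CH", repetition = 1L,
                        start_sample = 100L, end_sample = 900L)
  rec <- emg_recording(matrix(0, 1000, 2), fs = 200, annotations = ann)
  tr <- trim_transitions(rec, 0.5)
  expect_equal(tr$annotations$start_sample, 200)
  expect_equal(tr$annotations$end_sample, 800)
  expect_equal(tr$annotations$end_sample - tr$annotations$start_sample, 600)
  expect_identical(trim_transitions(rec, 0)$annotations, ann)
  short <- emg_recording(matrix(0, 1000, 2), fs = 200, annotations =
    tibble::tibble(movement = "OH", repetition = 2L,
                   start_sample = 0L, end_sample = 180L))
  expect_error(trim_transitions(short, 0.5), "OH rep 2")
})

test_that("window extraction yields floor((N - L)/s) + 1 windows per segment", {
  ann <- tibble::tibble(movement = c("CH", "WF"), repetition = c(1L, 1L),
                        start_sample = c(0L, 700L), end_sample = c(600L, 730L))
  rec <- emg_recording(matrix(rnorm(1000 * 8), 1000, 8), fs = 200,
                       annotations = ann)
  ws <- extract_windows(rec)
  expect_equal(ws$window_samples, 30)    # 150 ms at 200 Hz
  expect_equal(dim(ws$windows)[2:3], c(30, 8))
  n_ch <- table(ws$meta$movement)
  expect_equal(unname(n_ch[["CH"]]), floor((600 - 30) / 5) + 1)  # 115
  expect_equal(unname(n_ch[["WF"]]), 1)  # segment of exactly one window
  # windows lie inside their segment and carry its label
  ch <- ws$meta[ws$meta$movement == "CH", ]
  expect_true(all(ch$start_sample >= 0 & ch$start_sample + 30 <= 600))
  # content check: first window equals the raw slice
  expect_equal(ws$windows[1, , ], rec$samples[1:30, ])
  # too-short segment is skipped with a warning, not an error
  tiny <- emg_recording(matrix(0, 100, 2), fs = 200, annotations =
    tibble::tibble(movement = "SUP", repetition = 1L,
                   start_sample = 0L, end_sample = 20L))
  expect_warning(ws0 <- extract_windows(tiny), "skipping")
  expect_equal(dim(ws0$windows)[1], 0)
})

test_that("window extraction is deterministic and order-stable", {
  ann <- tibble::tibble(
    movement = c("CH", "RT", "WE"), repetition = c(1L, 1L, 1L),
    start_sample = c(0L, 250L, 520L), end_sample = c(200L, 480L, 780L)
  )
  rec <- emg_recording(matrix(rnorm(800 * 4), 800, 4), fs = 200,
                       annotations = ann)
  w1 <- extract_windows(rec, 150, 25)
  w2 <- extract_windows(rec, 150, 25)
  expect_identical(w1$windows, w2$windows)
  expect_identical(w1$meta, w2$meta)
  # sorted by segment then offset
  expect_true(!is.unsorted(w1$meta$start_sample))
})
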