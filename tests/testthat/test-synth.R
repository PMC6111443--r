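test_that("default protocol arithmetic: sessions and segments per subject", {
  cfg <- synth_config()
  expect_equal(cfg$n_days * cfg$sessions_per_day, 30)
  expect_equal(length(movement_classes()) * cfg$reps_per_movement, 70)
  # realized on a reduced grid (generation cost), same per-session arithmetic
  man <- generate_dataset(synth_config(n_days = 1, sessions_per_day = 2,
                                       reps_per_movement = 2,
                                       contraction_s = 1, relax_s = 0.25,
                                       seed = 3))
  expect_equal(nrow(man$sessions), 2)
  for (rec in man$sessions$recording) {
    expect_equal(nrow(rec$annotations), 7 * 2)
    expect_equal(sort(unique(rec$annotations$movement)),
                 sort(movement_classes()))
  }
})

test_that("the same config and seed give bit-identical datasets", {
  cfg <- synth_config(n_days = 1, reps_per_movement = 2, contraction_s = 1,
                      relax_s = 0.25, seed = 11)
  m1 <- generate_dataset(cfg)
  m2 <- generate_dataset(cfg)
  expect_identical(m1$sessions$recording[[1]]$samples,
                   m2$sessions$recording[[1]]$samples)
  expect_identical(m1$sessions$recording[[2]]$annotations,
                   m2$sessions$recording[[2]]$annotations)
  expect_identical(m1$provenance$config_hash, m2$provenance$config_hash)
  m3 <- generate_dataset(synth_config(n_days = 1, reps_per_movement = 2,
                                      contraction_s = 1, relax_s = 0.25,
                                      seed = 12))
  expect_false(identical(m1$sessions$recording[[1]]$samples,
                         m3$sessions$recording[[1]]$samples))
})

test_that("rest segments sit at the noise floor", {
  cfg <- synth_config(n_days = 1, sessions_per_day = 1,
                      reps_per_movement = 2, seed = 21)
  rec <- generate_dataset(cfg)$sessions$recording[[1]]
  ann <- rec$annotations
  rt <- ann[ann$movement == "RT", ]
  # two RT contractions of 4 s each = 8 s >= 4 s of samples
  x <- do.call(rbind, lapply(seq_len(nrow(rt)), function(i) {
    rec$samples[(rt$start_sample[i] + 1):rt$end_sample[i], , drop = FALSE]
  }))
  rms <- sqrt(mean(x^2))
  expect_lt(abs(rms - cfg$noise_floor_sd) / cfg$noise_floor_sd, 0.1)
})

test_that("carrier spectral power concentrates in the configured band", {
  cfg <- synth_config(seed = 31)
  fs <- cfg$fs
  n <- 2^15
  bf <- signal::butter(4, cfg$carrier_band / (fs / 2), type = "pass")
  x <- withr::with_seed(31, rnorm(n))
  y <- signal::filter(bf, x)
  spec <- stats::spec.pgram(stats::ts(as.numeric(y), frequency = fs),
                            taper = 0, plot = FALSE, detrend = FALSE)
  inband <- spec$freq >= cfg$carrier_band[1] & spec$freq <= cfg$carrier_band[2]
  expect_lt(sum(spec$spec[!inband]) / sum(spec$spec), 0.05)
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(synth_config(fs = -5), "fs")
  expect_error(synth_config(day_shift_sd = -1), "day_shift_sd")
  expect_error(synth_config(carrier_band = c(20, 150)), "carrier_band")
  expect_error(synth_config(envelope_ramp_s = 3, contraction_s = 4),
               "envelope_ramp_s")
  expect_error(synth_config(synergy = matrix(-1, 7, 8)), "synergy")
})

test_that("drift_sweep validates input and is flat at a degenerate sweep", {
  cfg <- synth_config(n_days = 2, reps_per_movement = 2, contraction_s = 1.5,
                      relax_s = 0.25, seed = 41)
  expect_error(drift_sweep(cfg, numeric(0)), "shift_values")
  expect_error(drift_sweep(cfg, c(0.5, 0.1)), "shift_values")
  sw <- drift_sweep(cfg, 0)
  expect_equal(nrow(sw), 1)
  # shift 0 reproduces the no-drift between-day error of the same seed
  cfg0 <- cfg
  cfg0$day_shift_sd <- 0
  ws <- dataset_windows(generate_dataset(cfg0))
  pw <- pairwise_days_cv(ws, classifier_lda(), seed = cfg$seed)
  expect_equal(sw$mean_pair_ce[1], mean(pw$ce))
})
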