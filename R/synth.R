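#' Configuration for the multiday synthetic EMG generator
#'
#' The generator emulates the recording protocol of a longitudinal armband
#' study: 7 movements x 10 repetitions per session, 2 sessions per day over
#' 15 days, 8 channels sampled at 200 Hz, each repetition a 4 s contraction
#' followed by a 4 s relaxation. Day-to-day nonstationarity is modelled as a
#' fractional circular rotation of the class-by-channel activation pattern
#' (electrode-donning displacement around the forearm ring) plus per-channel
#' log-normal gain drift; same-day sessions get the same perturbation scaled
#' down by `session_jitter_scale`.
#'
#' @param n_subjects Number of subjects.
#' @param n_days Recording days per subject.
#' @param sessions_per_day Sessions per day.
#' @param reps_per_movement Repetitions of each movement per session.
#' @param contraction_s,relax_s Contraction and relaxation duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param channels Electrode channels.
#' @param synergy 7 x channels nonnegative class-by-channel activation matrix;
#'   the RT row should be ~0. Default: smooth bumps around the electrode ring.
#' @param carrier_band Band (low, high) in Hz of the Gaussian carrier noise.
#' @param envelope_ramp_s Linear ramp of the contraction envelope, seconds.
#' @param noise_floor_sd SD of the additive white noise floor (a.u.).
#' @param day_shift_sd SD of the per-day fractional circular channel shift
#'   (channel units; 1 = one electrode spacing).
#' @param day_gain_sd SD of the per-day, per-channel log-gain.
#' @param session_jitter_scale Multiplier (< 1) applied to the shift/gain SDs
#'   for the extra perturbation of the second session of a day.
#' @param rep_amp_jitter_sd SD of the per-repetition log-amplitude jitter.
#' @param seed Integer seed; all randomness derives from it.
#'
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_subjects = 1, n_days = 15, sessions_per_day = 2,
                         reps_per_movement = 10, contraction_s = 4,
                         relax_s = 4, fs = 200, channels = 8,
                         synergy = default_synergy(channels),
                         carrier_band = c(20, 95), envelope_ramp_s = 0.5,
                         noise_floor_sd = 0.05, day_shift_sd = 0.3,
                         day_gain_sd = 0.15, session_jitter_scale = 0.25,
                         rep_amp_jitter_sd = 0.1, seed = 1) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  pos_int <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != floor(v)) {
      abort_field(field, "must be a positive integer")
    }
  }
  for (f in c("n_subjects", "n_days", "sessions_per_day",
              "reps_per_movement", "channels")) pos_int(f)
  for (f in c("noise_floor_sd", "day_shift_sd", "day_gain_sd",
              "rep_amp_jitter_sd", "session_jitter_scale")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || !is.finite(v)) {
      abort_field(f, "must be a nonnegative number")
    }
  }
  if (cfg$fs <= 0) abort_field("fs", "must be positive")
  if (cfg$contraction_s <= 0 || cfg$relax_s < 0) {
    abort_field("contraction_s/relax_s", "durations must be positive")
  }
  if (cfg$envelope_ramp_s <= 0 || cfg$envelope_ramp_s > cfg$contraction_s / 2) {
    abort_field("envelope_ramp_s", "must lie in (0, contraction_s/2]")
  }
  band <- cfg$carrier_band
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= cfg$fs / 2) {
    abort_field("carrier_band", "must satisfy 0 < low < high < fs/2")
  }
  syn <- cfg$synergy
  if (!is.matrix(syn) || nrow(syn) != 7 || ncol(syn) != cfg$channels) {
    abort_field("synergy", sprintf("must be a 7 x %d matrix", cfg$channels))
  }
  if (any(syn < 0)) abort_field("synergy", "entries must be nonnegative")
  invisible(cfg)
}

#' Default class-by-channel activation matrix
#'
#' Each active movement activates a smooth bump of adjacent channels around
#' the electrode ring (flexor/extensor compartments at different angular
#' positions); the RT (rest) row is all zero, so rest segments carry only the
#' noise floor.
#'
#' @param channels Number of electrode channels.
#' @return A 7 x `channels` nonnegative matrix with rows named by
#'   [movement_classes()].
#' @export
default_synergy <- function(channels = 8) {
  classes <- movement_classes()
  syn <- matrix(0, nrow = 7, ncol = channels,
                dimnames = list(classes, NULL))
  active <- classes[classes != "RT"]
  centers <- 1 + (seq_along(active) - 1) * channels / length(active)
  width <- channels / 6
  for (i in seq_along(active)) {
    k <- seq_len(channels)
    d <- pmin(abs(k - centers[i]), channels - abs(k - centers[i]))
    syn[active[i], ] <- exp(-(d / width)^2)
  }
  syn
}

# Circularly rotate one synergy row by a fractional channel shift, with
# linear interpolation between adjacent electrodes.
rotate_row <- function(row, shift) {
  C <- length(row)
  pos <- (seq_len(C) - 1 - shift) %% C
  i0 <- floor(pos)
  frac <- pos - i0
  (1 - frac) * row[i0 %% C + 1] + frac * row[(i0 + 1) %% C + 1]
}

# Generate one session recording for a given subject/day/session.
generate_recording <- function(cfg, subject, day, session) {
  C <- cfg$channels
  fs <- cfg$fs
  nc <- round_half_up(cfg$contraction_s * fs)
  nrel <- round_half_up(cfg$relax_s * fs)
  nr <- round_half_up(cfg$envelope_ramp_s * fs)
  classes <- movement_classes()

  # day-level drift, shared by the day's sessions
  day_fx <- with_seed(derive_seed(cfg$seed, "day", subject, day), {
    list(
      shift = stats::rnorm(1, 0, cfg$day_shift_sd),
      log_gain = stats::rnorm(C, 0, cfg$day_gain_sd)
    )
  })

  with_seed(derive_seed(cfg$seed, "session", subject, day, session), {
    shift <- day_fx$shift
    log_gain <- day_fx$log_gain
    if (session > 1) {
      shift <- shift +
        stats::rnorm(1, 0, cfg$session_jitter_scale * cfg$day_shift_sd)
      log_gain <- log_gain +
        stats::rnorm(C, 0, cfg$session_jitter_scale * cfg$day_gain_sd)
    }
    gain <- exp(log_gain)

    trials <- tidyr::expand_grid(
      movement = classes, repetition = seq_len(cfg$reps_per_movement)
    )
    trials <- trials[sample.int(nrow(trials)), ]
    # repetition index = order of occurrence within the session
    trials <- dplyr::mutate(
      dplyr::group_by(trials, .data$movement),
      repetition = dplyr::row_number()
    )
    trials <- dplyr::ungroup(trials)

    trial_len <- nc + nrel
    total <- nrow(trials) * trial_len

    # band-limited Gaussian carrier, one independent process per channel
    bf <- signal::butter(4, cfg$carrier_band / (fs / 2), type = "pass")
    carrier <- matrix(stats::rnorm(total * C), total, C)
    for (k in seq_len(C)) {
      carrier[, k] <- signal::filter(bf, carrier[, k])
    }
    # renormalize so the carrier has unit RMS per channel
    carrier <- sweep(carrier, 2, sqrt(colMeans(carrier^2)), "/")

    env <- c(
      seq_len(nr) / nr,
      rep(1, nc - 2 * nr),
      rev(seq_len(nr)) / nr
    )

    samples <- matrix(0, total, C)
    ann <- vector("list", nrow(trials))
    rep_jit <- exp(stats::rnorm(nrow(trials), 0, cfg$rep_amp_jitter_sd))
    syn_rot <- t(apply(cfg$synergy, 1, rotate_row, shift = shift))
    for (t in seq_len(nrow(trials))) {
      t0 <- (t - 1) * trial_len            # 0-based start of the contraction
      idx <- (t0 + 1):(t0 + nc)
      amp <- syn_rot[trials$movement[t], ] * rep_jit[t]
      samples[idx, ] <- carrier[idx, ] * (env %o% amp)
      ann[[t]] <- tibble::tibble(
        movement = trials$movement[t],
        repetition = trials$repetition[t],
        start_sample = t0, end_sample = t0 + nc
      )
    }
    samples <- sweep(samples, 2, gain, "*")
    samples <- samples + matrix(
      stats::rnorm(total * C, 0, cfg$noise_floor_sd), total, C
    )
    emg_recording(samples, fs = fs, annotations = dplyr::bind_rows(ann),
                  subject_id = subject, day = day, session = session)
  })
}

#' Generate a multiday synthetic EMG dataset
#'
#' Builds one recording per subject x day x session under `config` (see
#' [synth_config()] for the signal model). All randomness derives from
#' `config$seed`; the same config yields bit-identical datasets.
#'
#' @param config A [synth_config()].
#' @param root Optional directory; when given, sessions and a JSON manifest
#'   are written there via [write_session()] / [write_manifest()].
#' @return An `emg_manifest` whose `sessions` tibble has one row per session
#'   with a `recording` list-column.
#' @examples
#' cfg <- synth_config(n_days = 2, reps_per_movement = 2,
#'                     contraction_s = 1, relax_s = 0.5)
#' man <- generate_dataset(cfg)
#' man$sessions$recording[[1]]
#' @export
generate_dataset <- function(config, root = NULL) {
  validate_synth_config(config)
  grid <- tidyr::expand_grid(
    subject_id = seq_len(config$n_subjects),
    day = seq_len(config$n_days),
    session = seq_len(config$sessions_per_day)
  )
  grid$recording <- purrr::pmap(grid, function(subject_id, day, session) {
    generate_recording(config, subject_id, day, session)
  })
  cfg_for_hash <- config
  manifest <- structure(
    list(
      fs = config$fs, channels = config$channels,
      classes = movement_classes(), sessions = grid,
      provenance = list(seed = config$seed,
                        config_hash = rlang::hash(cfg_for_hash))
    ),
    class = "emg_manifest"
  )
  if (!is.null(root)) {
    prefixes <- purrr::map_chr(grid$recording, write_session, root = root)
    manifest$sessions$prefix <- prefixes
    write_manifest(manifest, root)
  }
  manifest
}

#' Sweep the day-shift magnitude and measure between-day error
#'
#' For each value in `shift_values`, regenerates a dataset with that
#' `day_shift_sd`, runs the full preprocessing + feature pipeline and the
#' pairs-of-days protocol with the LDA baseline, and records the mean pairwise
#' classification error. Used to characterize how electrode-shift drift
#' degrades between-day performance.
#'
#' @param config Base [synth_config()] (its `day_shift_sd` is overridden).
#' @param shift_values Nonnegative, ascending shift SDs (channel units).
#' @param seeds Integer seeds; the sweep is replicated per seed.
#' @return A tibble (class `emg_drift_sweep`) with columns `shift_sd`, `seed`,
#'   `mean_pair_ce`.
#' @export
drift_sweep <- function(config, shift_values, seeds = config$seed) {
  if (length(shift_values) == 0) {
    abort_field("shift_values", "must be non-empty")
  }
  if (any(shift_values < 0) || is.unsorted(shift_values)) {
    abort_field("shift_values", "must be nonnegative and ascending")
  }
  res <- tidyr::expand_grid(shift_sd = shift_values, seed = seeds)
  res$mean_pair_ce <- purrr::pmap_dbl(res, function(shift_sd, seed) {
    cfg <- config
    cfg$day_shift_sd <- shift_sd
    cfg$seed <- as.integer(seed)
    man <- generate_dataset(cfg)
    ws <- dataset_windows(man)
    pw <- pairwise_days_cv(ws, classifier_lda(), seed = seed)
    mean(pw$ce)
  })
  structure(res, class = c("emg_drift_sweep", class(res)))
}
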