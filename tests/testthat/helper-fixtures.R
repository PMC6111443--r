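# Shared fixtures. Heavy objects are built lazily and cached for the session.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# Small study configuration: reduced days/reps/durations (problem size only;
# drift parameters are the package defaults).
small_config <- function(...) {
  synth_config(
    n_days = 2, reps_per_movement = 3, contraction_s = 2, relax_s = 0.5,
    seed = 101, ...
  )
}

# Windows from a small drifted dataset (package-default drift).
small_drift_windows <- function() {
  fixture("small_drift_windows", function() {
    dataset_windows(generate_dataset(small_config()))
  })
}

# Windows from the matching zero-drift dataset.
small_nodrift_windows <- function() {
  fixture("small_nodrift_windows", function() {
    dataset_windows(generate_dataset(small_config(
      day_shift_sd = 0, day_gain_sd = 0, session_jitter_scale = 0
    )))
  })
}

# A synthetic provenance grid (no signal), for fold-structure tests.
meta_grid <- function(n_days = 2, n_sessions = 2, n_reps = 3,
                      windows_per_rep = 4, subject = 1) {
  g <- tidyr::expand_grid(
    subject_id = subject, day = seq_len(n_days),
    session = seq_len(n_sessions),
    movement = movement_classes(), repetition = seq_len(n_reps),
    w = seq_len(windows_per_rep)
  )
  g$start_sample <- seq_len(nrow(g))
  g$w <- NULL
  g
}

# Random valid recording for round-trip tests.
random_recording <- function(seed = 1, T = 400, C = 4) {
  withr::with_seed(seed, {
    n_seg <- 4
    bounds <- sort(sample(seq(10, T - 10), 2 * n_seg))
    ann <- tibble::tibble(
      movement = sample(movement_classes(), n_seg, replace = TRUE),
      repetition = 1:n_seg,
      start_sample = bounds[seq(1, 8, 2)],
      end_sample = bounds[seq(2, 8, 2)]
    )
    emg_recording(matrix(rnorm(T * C), T, C), fs = 200, annotations = ann,
                  subject_id = 3, day = 2, session = 1)
  })
}
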