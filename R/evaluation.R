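#' Classification error
#'
#' The fraction of windows wrongly classified; classification accuracy is
#' `1 - classification_error(...)`.
#'
#' @param pred Predicted labels.
#' @param truth True labels (same length).
#' @return Scalar in `[0, 1]`.
#' @export
classification_error <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop("pred and truth must have equal length", call. = FALSE)
  }
  if (length(pred) == 0) stop("cannot score zero samples", call. = FALSE)
  mean(as.character(pred) != as.character(truth))
}

# --- fold builders (provenance-based, leakage-safe) ------------------------

#' Cross-validation fold builders
#'
#' Each builder turns the provenance metadata of a window set into a list of
#' folds, where a fold is `list(train, test)` of row indices. Partitioning is
#' always at the provenance level (repetition, session, or day) so that
#' overlapping windows from one repetition can never straddle the train/test
#' boundary.
#'
#' * `within_session_folds()`: one fold per repetition index (10 folds in the
#'   study protocol); requires a single session with every movement having
#'   the same repetitions.
#' * `between_sessions_folds()`: the two folds of a same-day session swap.
#' * `pairwise_days_folds()`: for every unordered day pair (i, j), the two
#'   folds train-i/test-j and train-j/test-i (105 pairs for 15 days).
#' * `leave_one_day_out_folds()`: one fold per day, training on all others.
#'
#' @param meta Window metadata tibble (columns `subject_id`, `day`,
#'   `session`, `movement`, `repetition`).
#' @return A list of folds; pairwise folds carry `day_i`/`day_j` fields,
#'   the others a `fold` identifier.
#' @name cv_folds
NULL

#' @rdname cv_folds
#' @export
within_session_folds <- function(meta) {
  key <- unique(meta[c("subject_id", "day", "session")])
  if (nrow(key) != 1) {
    stop("within-session folds need windows from exactly one session",
         call. = FALSE)
  }
  reps <- sort(unique(meta$repetition))
  grid <- table(meta$movement, meta$repetition)
  missing <- which(grid == 0, arr.ind = TRUE)
  if (nrow(missing) > 0) {
    stop("missing repetition(s): ", paste(
      sprintf("(%s, rep %s)", rownames(grid)[missing[, 1]],
              colnames(grid)[missing[, 2]]),
      collapse = ", "
    ), call. = FALSE)
  }
  lapply(reps, function(r) {
    list(fold = r,
         train = which(meta$repetition != r),
         test = which(meta$repetition == r))
  })
}

#' @rdname cv_folds
#' @export
between_sessions_folds <- function(meta) {
  key <- unique(meta[c("subject_id", "day")])
  if (nrow(key) != 1) {
    stop("between-sessions folds need windows from exactly one day",
         call. = FALSE)
  }
  sess <- sort(unique(meta$session))
  if (length(sess) != 2) {
    stop(sprintf("between-sessions folds need exactly 2 sessions, got %d",
                 length(sess)), call. = FALSE)
  }
  lapply(seq_along(sess), function(i) {
    tr <- sess[i]; te <- sess[-i]
    list(fold = sprintf("train%d_test%d", tr, te),
         train = which(meta$session == tr),
         test = which(meta$session == te))
  })
}

#' @rdname cv_folds
#' @export
pairwise_days_folds <- function(meta) {
  days <- sort(unique(meta$day))
  if (length(days) < 2) {
    stop("pairwise-days folds need at least 2 days", call. = FALSE)
  }
  pairs <- utils::combn(days, 2)
  out <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    out[[length(out) + 1]] <- list(
      day_i = i, day_j = j, direction = "ij",
      train = which(meta$day == i), test = which(meta$day == j)
    )
    out[[length(out) + 1]] <- list(
      day_i = i, day_j = j, direction = "ji",
      train = which(meta$day == j), test = which(meta$day == i)
    )
  }
  out
}

#' @rdname cv_folds
#' @export
leave_one_day_out_folds <- function(meta) {
  days <- sort(unique(meta$day))
  if (length(days) < 2) {
    stop("leave-one-day-out needs at least 2 days", call. = FALSE)
  }
  lapply(days, function(d) {
    list(fold = d,
         train = which(meta$day != d),
         test = which(meta$day == d))
  })
}

# Train/score a classifier over a list of folds; retrains from scratch per
# fold with a fold-derived seed.
run_folds <- function(ws, clf, folds, seed = 1) {
  inputs <- classifier_inputs(ws, clf)
  y <- factor(ws$meta$movement, levels = movement_classes())
  vapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    model <- clf$fit(subset_inputs(inputs, f$train),
                     droplevels(y[f$train]),
                     seed = derive_seed(seed, clf$name, "fold", i))
    pred <- clf$predict(model, subset_inputs(inputs, f$test))
    classification_error(pred, y[f$test])
  }, numeric(1))
}

# --- the four protocols ----------------------------------------------------

#' Within-session cross-validation
#'
#' k-fold validation inside one session, one fold per repetition (10 folds
#' when there are 10 repetitions): train on all other repetitions, test on
#' the held-out one.
#'
#' @param ws An `emg_windows` restricted to one session.
#' @param clf A `classifier_spec`.
#' @param seed Integer seed for per-fold retraining.
#' @return Tibble with columns `fold` (repetition) and `ce`.
#' @export
within_session_cv <- function(ws, clf, seed = 1) {
  folds <- within_session_folds(ws$meta)
  tibble::tibble(
    fold = vapply(folds, `[[`, numeric(1), "fold"),
    ce = run_folds(ws, clf, folds, seed)
  )
}

#' Between-sessions cross-validation
#'
#' Two-fold validation across the two sessions of one day: train on one
#' session, test on the other, and swap.
#'
#' @param ws An `emg_windows` restricted to one day (2 sessions).
#' @inheritParams within_session_cv
#' @return Tibble with columns `fold` and `ce` (2 rows).
#' @export
between_sessions_cv <- function(ws, clf, seed = 1) {
  folds <- between_sessions_folds(ws$meta)
  tibble::tibble(
    fold = vapply(folds, `[[`, character(1), "fold"),
    ce = run_folds(ws, clf, folds, seed)
  )
}

#' Pairs-of-days cross-validation
#'
#' For every unordered pair of days (i, j), two-fold validation: train on all
#' of day i, test on day j, and swap; the pair's error is the mean of the two
#' folds. 15 days give 105 unique pairs.
#'
#' @param ws An `emg_windows` for one subject spanning >= 2 days.
#' @inheritParams within_session_cv
#' @return Tibble with columns `day_i`, `day_j`, `ce_ij`, `ce_ji` and `ce`
#'   (the pair mean).
#' @export
pairwise_days_cv <- function(ws, clf, seed = 1) {
  folds <- pairwise_days_folds(ws$meta)
  ce <- run_folds(ws, clf, folds, seed)
  res <- tibble::tibble(
    day_i = vapply(folds, `[[`, numeric(1), "day_i"),
    day_j = vapply(folds, `[[`, numeric(1), "day_j"),
    direction = vapply(folds, `[[`, character(1), "direction"),
    ce = ce
  )
  wide <- tidyr::pivot_wider(res, names_from = "direction",
                             values_from = "ce", names_prefix = "ce_")
  wide$ce <- (wide$ce_ij + wide$ce_ji) / 2
  wide
}

#' Leave-one-day-out cross-validation
#'
#' One fold per day: train on every other day (both sessions), test on the
#' held-out day. 15 days give 15 folds.
#'
#' @param ws An `emg_windows` for one subject spanning >= 2 days.
#' @inheritParams within_session_cv
#' @return Tibble with columns `fold` (held-out day) and `ce`.
#' @export
leave_one_day_out_cv <- function(ws, clf, seed = 1) {
  folds <- leave_one_day_out_folds(ws$meta)
  tibble::tibble(
    fold = vapply(folds, `[[`, numeric(1), "fold"),
    ce = run_folds(ws, clf, folds, seed)
  )
}

# --- dataset-level evaluation ----------------------------------------------

#' Run the full protocol x classifier evaluation grid
#'
#' Applies the selected cross-validation protocols to every subject (and
#' every session/day where the protocol is local) for every classifier,
#' returning the long-format record structure used by the statistics stage.
#'
#' @param ws An `emg_windows` spanning the whole dataset (see
#'   [dataset_windows()]).
#' @param classifiers List of `classifier_spec`s (default the four families).
#' @param analyses Subset of `c("within_session", "between_sessions",
#'   "pair_of_days", "leave_one_day_out")`.
#' @param seed Integer seed; per-fold training seeds derive from it.
#' @return An `emg_eval` tibble: columns `subject_id`, `analysis`,
#'   `classifier`, `fold`, `ce`.
#' @export
evaluate_protocols <- function(ws, classifiers = default_classifiers(),
                               analyses = c("within_session",
                                            "between_sessions",
                                            "pair_of_days",
                                            "leave_one_day_out"),
                               seed = 1) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  meta <- ws$meta
  out <- list()
  add <- function(subject, analysis, clf_name, fold, ce) {
    out[[length(out) + 1]] <<- tibble::tibble(
      subject_id = subject, analysis = analysis, classifier = clf_name,
      fold = as.character(fold), ce = ce
    )
  }
  for (subject in unique(meta$subject_id)) {
    sub_idx <- which(meta$subject_id == subject)
    ws_sub <- subset_windows(ws, sub_idx)
    for (clf in classifiers) {
      if ("within_session" %in% analyses) {
        keys <- unique(ws_sub$meta[c("day", "session")])
        for (r in seq_len(nrow(keys))) {
          idx <- which(ws_sub$meta$day == keys$day[r] &
                         ws_sub$meta$session == keys$session[r])
          res <- within_session_cv(subset_windows(ws_sub, idx), clf,
                                   seed = derive_seed(seed, subject,
                                                      keys$day[r],
                                                      keys$session[r]))
          add(subject, "within_session", clf$name,
              sprintf("d%02d_s%d_rep%s", keys$day[r], keys$session[r],
                      res$fold), res$ce)
        }
      }
      if ("between_sessions" %in% analyses) {
        for (d in unique(ws_sub$meta$day)) {
          idx <- which(ws_sub$meta$day == d)
          res <- between_sessions_cv(subset_windows(ws_sub, idx), clf,
                                     seed = derive_seed(seed, subject, d))
          add(subject, "between_sessions", clf$name,
              sprintf("d%02d_%s", d, res$fold), res$ce)
        }
      }
      if ("pair_of_days" %in% analyses) {
        res <- pairwise_days_cv(ws_sub, clf, seed = derive_seed(seed, subject))
        add(subject, "pair_of_days", clf$name,
            sprintf("d%02d_d%02d", res$day_i, res$day_j), res$ce)
      }
      if ("leave_one_day_out" %in% analyses) {
        res <- leave_one_day_out_cv(ws_sub, clf,
                                    seed = derive_seed(seed, subject, "lodo"))
        add(subject, "leave_one_day_out", clf$name,
            sprintf("d%02d", res$fold), res$ce)
      }
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("emg_eval", class(res))
  res
}

#' Aggregate an evaluation report
#'
#' Mean and SD of the classification error at the requested grouping,
#' mirroring the study's summary tables (subjects x classifiers x analyses).
#'
#' @param report An `emg_eval` tibble (see [evaluate_protocols()]).
#' @param by Grouping columns.
#' @return Tibble with `mean_ce`, `sd_ce` and `n_folds` per group.
#' @export
aggregate_report <- function(report, by = c("classifier", "analysis")) {
  if (nrow(report) == 0) stop("empty report", call. = FALSE)
  report |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean_ce = mean(.data$ce),
      sd_ce = stats::sd(.data$ce),
      n_folds = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(sd_ce = ifelse(is.na(.data$sd_ce), 0, .data$sd_ce))
}

#' Render a pairs-of-days result as a triangle table
#'
#' Lays out two classifiers' pair errors in one day x day matrix: classifier
#' `upper` fills the upper triangle, `lower` the lower triangle, the diagonal
#' stays empty — the layout of the study's pairwise-day comparison tables.
#'
#' @param report An `emg_eval` containing `pair_of_days` records.
#' @param upper,lower Classifier names for the two triangles.
#' @return A day x day numeric matrix with `NA` on the diagonal.
#' @export
pair_triangle_table <- function(report, upper, lower) {
  pw <- report[report$analysis == "pair_of_days", ]
  if (nrow(pw) == 0) stop("report has no pair_of_days records", call. = FALSE)
  ij <- do.call(rbind, regmatches(pw$fold,
                                  regexec("d([0-9]+)_d([0-9]+)", pw$fold)))
  pw$day_i <- as.integer(ij[, 2])
  pw$day_j <- as.integer(ij[, 3])
  days <- sort(unique(c(pw$day_i, pw$day_j)))
  M <- matrix(NA_real_, length(days), length(days),
              dimnames = list(paste0("day", days), paste0("day", days)))
  cell_means <- pw |>
    dplyr::group_by(.data$classifier, .data$day_i, .data$day_j) |>
    dplyr::summarise(ce = mean(.data$ce), .groups = "drop")
  for (r in seq_len(nrow(cell_means))) {
    i <- match(cell_means$day_i[r], days)
    j <- match(cell_means$day_j[r], days)
    if (cell_means$classifier[r] == upper) M[i, j] <- cell_means$ce[r]
    if (cell_means$classifier[r] == lower) M[j, i] <- cell_means$ce[r]
  }
  M
}
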