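test_that("classification error is the fraction of wrong windows", {
  expect_equal(classification_error(c(2, 2, 1, 1, 1, 1, 1, 1, 1, 1),
                                    rep(1, 10)), 0.2)
  x <- sample(movement_classes(), 25, replace = TRUE)
  expect_equal(classification_error(x, x), 0)
  expect_equal(classification_error(rep("CH", 5), rep("OH", 5)), 1)
  expect_error(classification_error(1:3, 1:4), "equal length")
  expect_error(classification_error(character(0), character(0)), "zero")
})

test_that("fold structure matches each protocol's arithmetic", {
  # 15 days -> 105 unique pairs, 15 leave-one-day-out folds
  meta15 <- meta_grid(n_days = 15, n_sessions = 2, n_reps = 2,
                      windows_per_rep = 1)
  pf <- pairwise_days_folds(meta15)
  expect_equal(length(pf) / 2, 15 * 14 / 2)        # two directions per pair
  expect_equal(length(leave_one_day_out_folds(meta15)), 15)
  # training set of each leave-one-day-out fold spans 14 days x 2 sessions
  lodo <- leave_one_day_out_folds(meta15)
  tr_days <- unique(meta15$day[lodo[[1]]$train])
  expect_equal(length(tr_days), 14)
  expect_equal(length(unique(meta15$session[lodo[[1]]$train])), 2)
  # 3 days -> 3 pairs
  expect_equal(length(pairwise_days_folds(meta_grid(n_days = 3))) / 2, 3)
  # 10 repetitions -> 10 within-session folds, each holding out one
  # repetition of every movement
  m1 <- meta_grid(n_days = 1, n_sessions = 1, n_reps = 10)
  wf <- within_session_folds(m1)
  expect_equal(length(wf), 10)
  for (f in wf[c(1, 10)]) {
    held <- m1[f$test, ]
    expect_equal(sort(unique(held$movement)), sort(movement_classes()))
    expect_equal(unique(held$repetition), f$fold)
  }
  # degenerate: with 2 days, leave-one-day-out equals the pair's two folds
  m2 <- meta_grid(n_days = 2)
  l2 <- leave_one_day_out_folds(m2)
  p2 <- pairwise_days_folds(m2)
  expect_setequal(l2[[1]]$test, p2[[2]]$test)
  expect_setequal(l2[[1]]$train, p2[[2]]$train)
})

test_that("fold precondition violations are informative", {
  m <- meta_grid(n_days = 1, n_sessions = 1, n_reps = 3)
  m <- m[!(m$movement == "WF" & m$repetition == 2), ]
  expect_error(within_session_folds(m), "WF.*2|missing repetition")
  expect_error(within_session_folds(meta_grid(n_days = 2)), "one session")
  expect_error(between_sessions_folds(
    meta_grid(n_days = 1, n_sessions = 3)), "exactly 2")
  expect_error(pairwise_days_folds(meta_grid(n_days = 1)), "2 days")
  expect_error(leave_one_day_out_folds(meta_grid(n_days = 1)), "2 days")
})

test_that("no test repetition/session/day leaks into its training set", {
  meta <- meta_grid(n_days = 4, n_sessions = 2, n_reps = 3,
                    windows_per_rep = 5)
  one_ses <- meta[meta$day == 1 & meta$session == 1, ]
  for (f in within_session_folds(one_ses)) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(unique(one_ses$repetition[f$train]),
                            unique(one_ses$repetition[f$test])), 0)
  }
  one_day <- meta[meta$day == 2, ]
  for (f in between_sessions_folds(one_day)) {
    expect_length(intersect(unique(one_day$session[f$train]),
                            unique(one_day$session[f$test])), 0)
  }
  for (f in pairwise_days_folds(meta)) {
    expect_length(intersect(unique(meta$day[f$train]),
                            unique(meta$day[f$test])), 0)
  }
  for (f in leave_one_day_out_folds(meta)) {
    expect_length(intersect(unique(meta$day[f$train]),
                            unique(meta$day[f$test])), 0)
    expect_equal(sort(unique(c(f$train, f$test))), seq_len(nrow(meta)))
  }
})

test_that("stub classifiers bound the protocols: memorizer 0, random ~ 6/7", {
  ws <- small_drift_windows()
  one <- subset_windows(ws, which(ws$meta$day == 1 & ws$meta$session == 1))
  fe_one <- featurize(one)
  mem <- within_session_cv(one, classifier_memorize(fe_one$x,
                                                    fe_one$meta$movement))
  expect_equal(mem$ce, rep(0, 3))
  # uniform-random over the 7 classes: mean CE ~ 6/7
  ces <- unlist(lapply(1:5, function(s) {
    within_session_cv(one, classifier_random(), seed = s)$ce
  }))
  n_test <- sum(one$meta$repetition == 1)
  expect_lt(abs(mean(ces) - 6 / 7), 3 * sqrt(6 / 49 / (n_test * 15)) + 0.01)
  # majority stub errs on everything outside the majority class
  maj <- within_session_cv(one, classifier_majority())
  share <- max(table(one$meta$movement)) / nrow(one$meta)
  expect_lt(abs(mean(maj$ce) - (1 - share)), 0.05)
})

test_that("between-sessions folds are symmetric and duplicated sessions give equal CEs", {
  ws <- small_drift_windows()
  day1 <- subset_windows(ws, which(ws$meta$day == 1))
  # duplicate session 1 as a fake session 2
  s1 <- which(day1$meta$session == 1)
  dup <- day1
  dup$windows <- dup$windows[c(s1, s1), , ]
  dup$meta <- dup$meta[c(s1, s1), ]
  dup$meta$session <- rep(c(1L, 2L), each = length(s1))
  res <- between_sessions_cv(dup, classifier_lda())
  expect_equal(nrow(res), 2)
  expect_equal(res$ce[1], res$ce[2])
  # and equals the resubstitution error of one session
  fe <- featurize(subset_windows(day1, s1))
  fit <- lda_train(fe$x, fe$meta$movement)
  resub <- classification_error(predict(fit, fe$x), fe$meta$movement)
  expect_equal(res$ce[1], resub)
})

test_that("the evaluation grid is complete and leakage-audited end to end", {
  ws <- small_drift_windows()
  rep_grid <- evaluate_protocols(
    ws, classifiers = list(classifier_lda(), classifier_majority()),
    seed = 4
  )
  agg <- aggregate_report(rep_grid)
  expect_equal(nrow(agg), 2 * 4)   # 2 classifiers x 4 analyses, no missing cells
  expect_true(all(agg$mean_ce >= 0 & agg$mean_ce <= 1))
  counts <- dplyr::count(rep_grid, .data$analysis, .data$classifier)
  # 2 days x 2 sessions x 3 reps within folds; 2 days x 2 swaps; 1 pair; 2 lodo
  expect_setequal(counts$n[counts$analysis == "within_session"], 12)
  expect_setequal(counts$n[counts$analysis == "between_sessions"], 4)
  expect_setequal(counts$n[counts$analysis == "pair_of_days"], 1)
  expect_setequal(counts$n[counts$analysis == "leave_one_day_out"], 2)
  # single record aggregates to mean = value, sd = 0
  one <- aggregate_report(rep_grid[1, ])
  expect_equal(one$mean_ce, rep_grid$ce[1])
  expect_equal(one$sd_ce, 0)
  expect_error(aggregate_report(rep_grid[0, ]), "empty")
})

test_that("pairwise triangle table has the two-classifier layout", {
  ws <- small_drift_windows()
  rep_grid <- evaluate_protocols(
    ws, classifiers = list(classifier_lda(), classifier_majority()),
    analyses = "pair_of_days", seed = 9
  )
  M <- pair_triangle_table(rep_grid, upper = "LDA", lower = "majority")
  expect_equal(dim(M), c(2, 2))
  expect_true(all(is.na(diag(M))))
  expect_false(is.na(M[1, 2]))
  expect_false(is.na(M[2, 1]))
  lda_pair <- rep_grid$ce[rep_grid$classifier == "LDA"]
  expect_equal(M[1, 2], mean(lda_pair))
})
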