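balanced_table <- function(a_levels, b_levels, reps, fn) {
  g <- tidyr::expand_grid(classifier = a_levels, time = b_levels,
                          rep = seq_len(reps))
  g$ce <- fn(nrow(g), g)
  g
}

test_that("sums of squares equal the hand decomposition on a 2x2 design", {
  # 2x2 balanced, 2 replicates, cell means {10, 12; 20, 22}, offsets {0, 1}
  tab <- tidyr::expand_grid(classifier = c("a", "b"), time = c("t1", "t2"),
                            rep = 1:2)
  base <- c(10, 10, 12, 12, 20, 20, 22, 22)
  tab$ce <- base + rep(c(0, 1), 4)
  fit <- anova_two_way(tab)
  ora <- oracle_two_way_ss(tab$ce, tab$classifier, tab$time)
  tb <- tidy(fit)
  expect_equal(tb$sumsq[tb$term == "classifier"], ora$A)
  expect_equal(tb$sumsq[tb$term == "time"], ora$B)
  expect_equal(tb$sumsq[tb$term == "interaction"], ora$AB)
  expect_equal(tb$sumsq[tb$term == "residual"], ora$resid)
  expect_equal(sum(tb$sumsq), ora$total)
  expect_equal(sum(tb$df), nrow(tab) - 1)
})

test_that("SS decomposition sums to total on random balanced tables", {
  set.seed(1)
  for (i in 1:20) {
    tab <- balanced_table(letters[1:4], paste0("d", 1:5), 3,
                          function(n, g) rnorm(n))
    tb <- tidy(anova_two_way(tab))
    ora <- oracle_two_way_ss(tab$ce, tab$classifier, tab$time)
    expect_lt(abs(sum(tb$sumsq) - ora$total) / ora$total, 1e-8)
    expect_lt(abs(tb$sumsq[tb$term == "classifier"] - ora$A) /
                max(ora$A, 1e-12), 1e-8)
  }
})

test_that("consistent relabeling of factor levels leaves F unchanged", {
  set.seed(2)
  tab <- balanced_table(c("a", "b", "c"), c("t1", "t2"), 4,
                        function(n, g) rnorm(n))
  f1 <- tidy(anova_two_way(tab))
  tab2 <- tab
  tab2$classifier <- chartr("abc", "zyx", tab2$classifier)
  tab2$time <- chartr("12", "98", tab2$time)
  f2 <- tidy(anova_two_way(tab2))
  expect_equal(f1$statistic, f2$statistic)
  expect_equal(f1$p.value, f2$p.value)
})

test_that("single replicate drops the interaction; unbalance is an error", {
  tab <- balanced_table(c("a", "b"), c("t1", "t2", "t3"), 1,
                        function(n, g) rnorm(n))
  fit <- anova_two_way(tab)
  expect_false("interaction" %in% tidy(fit)$term)
  expect_equal(sum(tidy(fit)$df), nrow(tab) - 1)
  expect_error(anova_two_way(tab[-1, ]), "unbalanced")
  expect_error(anova_two_way(tab[tab$classifier == "a", ]), "2 levels")
})

test_that("an all-equal table is flagged degenerate, not significant", {
  tab <- balanced_table(c("a", "b"), c("t1", "t2"), 3,
                        function(n, g) rep(0.25, n))
  fit <- anova_two_way(tab)
  expect_true(fit$degenerate)
  expect_true(all(is.na(tidy(fit)$p.value[tidy(fit)$term != "residual"])))
  expect_equal(tidy(fit)$sumsq[1:2], c(0, 0))
  ph <- posthoc_pairwise(fit)
  expect_false(any(ph$significant))
})

test_that("Tukey post hoc finds a planted classifier effect and only it", {
  set.seed(3)
  tab <- balanced_table(c("a", "b", "c", "d"), paste0("t", 1:5), 4,
                        function(n, g) rnorm(n, sd = 0.01))
  tab$ce[tab$classifier == "d"] <- tab$ce[tab$classifier == "d"] + 0.1  # 10x SD
  fit <- anova_two_way(tab)
  ph <- posthoc_pairwise(fit)
  expect_equal(nrow(ph), choose(4, 2))
  has_d <- grepl("d", ph$pair)
  expect_true(all(ph$significant[has_d]))
  expect_false(any(ph$significant[!has_d]))
  # significance consistent with the CI excluding zero
  expect_equal(ph$significant, ph$conf.low > 0 | ph$conf.high < 0)
  # duplicated classifiers differ by ~0 and are not significant
  tab2 <- tab
  tab2$ce[tab2$classifier == "b"] <- tab2$ce[tab2$classifier == "a"]
  ph2 <- posthoc_pairwise(anova_two_way(tab2))
  ab <- ph2[ph2$pair == "b-a", ]
  expect_lt(abs(ab$estimate), 1e-12)
  expect_false(ab$significant)
  expect_match(posthoc_summary(ph)[1], "CE difference")
})

test_that("tidiers expose the fit in broom style", {
  set.seed(4)
  tab <- balanced_table(c("a", "b"), c("t1", "t2"), 3,
                        function(n, g) rnorm(n))
  fit <- anova_two_way(tab)
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$replicates, 3)
  expect_s3_class(tidy(posthoc_pairwise(fit)), "tbl_df")
})
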