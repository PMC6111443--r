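#' Two-way ANOVA on classification errors
#'
#' Fixed-effects two-way analysis of variance with the classifier as factor
#' A and the time level (days or sessions) as factor B, applied to a
#' balanced table of classification errors. With more than one replicate per
#' cell the interaction is estimated; with exactly one replicate the
#' additive model is fitted. Subjects enter as replicates.
#'
#' @param data Data frame of observations.
#' @param response,factor_a,factor_b Column names of the CE response, the
#'   classifier factor, and the time factor.
#' @param alpha Significance level.
#' @return An `emg_anova`: list with the decomposition `table` (term, df,
#'   sumsq, meansq, statistic, p.value), the underlying `aov` fit,
#'   `replicates`, `alpha` and a `degenerate` flag (zero variance anywhere).
#' @export
anova_two_way <- function(data, response = "ce", factor_a = "classifier",
                          factor_b = "time", alpha = 0.05) {
  for (col in c(response, factor_a, factor_b)) {
    if (!col %in% names(data)) {
      stop("column not found: ", col, call. = FALSE)
    }
  }
  df <- data.frame(
    y = data[[response]],
    A = factor(data[[factor_a]]),
    B = factor(data[[factor_b]])
  )
  if (nlevels(df$A) < 2 || nlevels(df$B) < 2) {
    stop("both factors need at least 2 levels", call. = FALSE)
  }
  cell_n <- table(df$A, df$B)
  if (length(unique(as.vector(cell_n))) != 1 || any(cell_n == 0)) {
    stop(paste(
      "unbalanced design: every classifier x time cell needs the same",
      "number of replicates (the study protocol is balanced; aggregate or",
      "subset accordingly)"
    ), call. = FALSE)
  }
  reps <- unname(cell_n[1, 1])
  form <- if (reps > 1) y ~ A * B else y ~ A + B
  fit <- stats::aov(form, data = df)
  sm <- summary(fit)[[1]]
  term_map <- c("A" = "classifier", "B" = "time", "A:B" = "interaction",
                "Residuals" = "residual")
  tab <- tibble::tibble(
    term = term_map[trimws(rownames(sm))],
    df = sm$Df,
    sumsq = sm$`Sum Sq`,
    meansq = sm$`Mean Sq`,
    statistic = sm$`F value`,
    p.value = sm$`Pr(>F)`
  )
  degenerate <- stats::var(df$y) < .Machine$double.eps
  if (degenerate) {
    tab$statistic[tab$term != "residual"] <- NA_real_
    tab$p.value[tab$term != "residual"] <- NA_real_
  }
  structure(
    list(table = tab, fit = fit, replicates = reps, alpha = alpha,
         degenerate = degenerate,
         factor_labels = c(A = factor_a, B = factor_b)),
    class = "emg_anova"
  )
}

#' @export
print.emg_anova <- function(x, ...) {
  cat(sprintf("<emg_anova> %s x %s, %d replicate(s) per cell%s\n",
              x$factor_labels["A"], x$factor_labels["B"], x$replicates,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  print(x$table)
  invisible(x)
}

#' Tukey HSD post hoc comparison of classifiers
#'
#' Tukey-Kramer honestly-significant-difference comparisons on the
#' classifier factor of a fitted two-way ANOVA, using the residual mean
#' square; returns simultaneous confidence intervals and adjusted p-values
#' for every classifier pair.
#'
#' @param anova An `emg_anova` from [anova_two_way()].
#' @return An `emg_posthoc` tibble: `pair`, `estimate` (mean difference),
#'   `conf.low`, `conf.high`, `adj.p.value`, `significant`.
#' @export
posthoc_pairwise <- function(anova) {
  stopifnot(inherits(anova, "emg_anova"))
  mod <- anova$fit
  if (nlevels(mod$model$A) < 2) {
    stop("need at least 2 classifiers to compare", call. = FALSE)
  }
  if (anova$degenerate) {
    lev <- levels(mod$model$A)
    pairs <- utils::combn(lev, 2)
    res <- tibble::tibble(
      pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
      estimate = 0, conf.low = 0, conf.high = 0,
      adj.p.value = NA_real_, significant = FALSE
    )
  } else {
    tk <- stats::TukeyHSD(mod, which = "A", conf.level = 1 - anova$alpha)$A
    res <- tibble::tibble(
      pair = rownames(tk),
      estimate = tk[, "diff"],
      conf.low = tk[, "lwr"],
      conf.high = tk[, "upr"],
      adj.p.value = tk[, "p adj"],
      significant = tk[, "p adj"] < anova$alpha
    )
  }
  class(res) <- c("emg_posthoc", class(res))
  res
}

#' Human-readable post hoc summary
#'
#' @param posthoc An `emg_posthoc` tibble.
#' @return A character vector, one statement per pair.
#' @export
posthoc_summary <- function(posthoc) {
  vapply(seq_len(nrow(posthoc)), function(i) {
    p <- posthoc$adj.p.value[i]
    pstr <- if (is.na(p)) "p = NA" else if (p < 0.001) "p < 0.001" else
      sprintf("p = %.3f", p)
    sprintf("%s: mean CE difference %+.4f (%s)%s",
            posthoc$pair[i], posthoc$estimate[i], pstr,
            if (isTRUE(posthoc$significant[i])) " *" else "")
  }, character(1))
}
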