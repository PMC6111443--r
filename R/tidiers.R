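#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the ANOVA decomposition
#'
#' @param x An `emg_anova`.
#' @param ... Unused.
#' @return A tibble with one row per term (`term`, `df`, `sumsq`, `meansq`,
#'   `statistic`, `p.value`).
#' @method tidy emg_anova
#' @export
tidy.emg_anova <- function(x, ...) x$table

#' One-row ANOVA summary
#'
#' @param x An `emg_anova`.
#' @param ... Unused.
#' @return A one-row tibble with the classifier-factor F statistic and
#'   p-value, the replicate count and the degenerate flag.
#' @method glance emg_anova
#' @export
glance.emg_anova <- function(x, ...) {
  row <- x$table[x$table$term == "classifier", ]
  tibble::tibble(
    statistic = row$statistic, p.value = row$p.value,
    df_classifier = row$df,
    df_residual = x$table$df[x$table$term == "residual"],
    replicates = x$replicates, degenerate = x$degenerate
  )
}

#' Tidy the post hoc comparisons
#'
#' @param x An `emg_posthoc`.
#' @param ... Unused.
#' @return The comparisons tibble (`pair`, `estimate`, `conf.low`,
#'   `conf.high`, `adj.p.value`, `significant`).
#' @method tidy emg_posthoc
#' @export
tidy.emg_posthoc <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "emg_posthoc")
  out
}

#' Tidy an LDA model
#'
#' @param x An `emg_lda`.
#' @param ... Unused.
#' @return Long tibble of class means: `class`, `feature`, `mean`.
#' @method tidy emg_lda
#' @export
tidy.emg_lda <- function(x, ...) {
  m <- x$class_means
  tibble::tibble(
    class = rep(rownames(m), times = ncol(m)),
    feature = rep(colnames(m) %||% paste0("x", seq_len(ncol(m))),
                  each = nrow(m)),
    mean = as.vector(m)
  )
}

#' One-row model summaries
#'
#' @param x An `emg_lda`, `emg_ssae` or `emg_cnn` model.
#' @param ... Unused.
#' @return A one-row tibble of model dimensions and fit diagnostics.
#' @method glance emg_lda
#' @export
glance.emg_lda <- function(x, ...) {
  tibble::tibble(
    n_classes = length(x$classes),
    n_features = ncol(x$class_means),
    ridge = x$ridge
  )
}

#' @rdname glance.emg_lda
#' @method glance emg_ssae
#' @export
glance.emg_ssae <- function(x, ...) {
  tibble::tibble(
    layer1 = x$config$layer_sizes[1],
    layer2 = x$config$layer_sizes[2],
    n_classes = length(x$classes),
    head_loss = x$head_value,
    scale = x$scaler$type
  )
}

#' @rdname glance.emg_lda
#' @method glance emg_cnn
#' @export
glance.emg_cnn <- function(x, ...) {
  tibble::tibble(
    n_filters = ncol(x$conv_w),
    n_parameters = length(x$conv_w) + length(x$conv_b) +
      length(x$fc_w) + length(x$fc_b),
    n_classes = length(x$classes),
    final_loss = x$epoch_losses[length(x$epoch_losses)]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
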