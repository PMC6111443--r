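#' Flatten raw windows into a matrix
#'
#' Each window becomes one row, channel-major (all 30 samples of channel 1,
#' then channel 2, ...), giving the 240-dimensional raw input of SSAE-r.
#'
#' @param ws An `emg_windows` object.
#' @return List with `x` (W x L*C matrix) and `channel_index` (channel id per
#'   column).
#' @export
flatten_windows <- function(ws) {
  dims <- dim(ws$windows)
  W <- dims[1]; L <- dims[2]; C <- dims[3]
  x <- matrix(aperm(ws$windows, c(1, 2, 3)), W, L * C)
  list(x = x, channel_index = rep(seq_len(C), each = L))
}

#' Classifier specifications for the evaluation protocols
#'
#' Each specification bundles a name, the input representation it consumes
#' (TD features, flattened raw windows, or raw window arrays), and
#' `fit`/`predict` closures, so the four classifier families are
#' interchangeable in every cross-validation protocol. `seed` is re-derived
#' per fold by the protocols so each fold retrains from a fresh
#' initialization.
#'
#' @param feature_threshold SSC/ZC amplitude threshold for the feature-based
#'   classifiers.
#' @param ... Configuration overrides passed to the underlying constructor
#'   ([ssae_config()] / [cnn_config()]).
#' @return A `classifier_spec` list with elements `name`, `input`
#'   (`"features"`, `"flat"` or `"windows"`), `fit(x, y, seed)` and
#'   `predict(model, x)`.
#' @name classifier_specs
NULL

new_classifier_spec <- function(name, input, fit, predict) {
  structure(list(name = name, input = input, fit = fit, predict = predict),
            class = "classifier_spec")
}

#' @rdname classifier_specs
#' @param ridge Ridge coefficient for the pooled covariance.
#' @export
classifier_lda <- function(ridge = 1e-6, feature_threshold = 0) {
  new_classifier_spec(
    "LDA", "features",
    fit = function(x, y, seed) lda_train(x, y, ridge = ridge),
    predict = function(model, x) predict(model, x)
  )
}

#' @rdname classifier_specs
#' @export
classifier_ssae_f <- function(..., feature_threshold = 0) {
  args <- list(...)
  new_classifier_spec(
    "SSAE-f", "features",
    fit = function(x, y, seed) {
      cfg <- do.call(ssae_config, utils::modifyList(
        list(layer_sizes = c(32, 16), scale = "minmax", seed = seed), args
      ))
      ssae_train(x, y, cfg)
    },
    predict = function(model, x) predict(model, x)
  )
}

#' @rdname classifier_specs
#' @export
classifier_ssae_r <- function(...) {
  args <- list(...)
  new_classifier_spec(
    "SSAE-r", "flat",
    fit = function(x, y, seed) {
      cfg <- do.call(ssae_config, utils::modifyList(
        list(layer_sizes = c(100, 50), scale = "zscore", seed = seed), args
      ))
      ssae_train(x$x, y, cfg, channel_index = x$channel_index)
    },
    predict = function(model, x) predict(model, x$x)
  )
}

#' @rdname classifier_specs
#' @export
classifier_cnn <- function(...) {
  args <- list(...)
  new_classifier_spec(
    "CNN", "windows",
    fit = function(x, y, seed) {
      cfg <- do.call(cnn_config, utils::modifyList(list(seed = seed), args))
      cnn_train(x, y, cfg)
    },
    predict = function(model, x) predict(model, x)
  )
}

#' The default classifier battery
#'
#' @param ssae_iters,cnn_epochs Optional reduced training budgets.
#' @return Named list of the four classifier specs (LDA, SSAE-f, SSAE-r,
#'   CNN).
#' @export
default_classifiers <- function(ssae_iters = 400, cnn_epochs = 25) {
  list(
    classifier_lda(),
    classifier_ssae_f(max_iters = ssae_iters),
    classifier_ssae_r(max_iters = ssae_iters),
    classifier_cnn(max_epochs = cnn_epochs)
  )
}

# --- test stubs ------------------------------------------------------------

#' Degenerate classifier stubs for protocol testing
#'
#' `classifier_memorize()` is an oracle stub that memorizes the label of
#' every window it was constructed with and answers by exact row lookup
#' (so it scores CE = 0 under any leakage-free protocol run on that data);
#' `classifier_majority()` always predicts the most frequent training class;
#' `classifier_random()` predicts uniformly at random. These exercise the
#' protocols independently of any real model.
#'
#' @param x,y Optional full feature matrix and labels to memorize at
#'   construction; when omitted, only the per-fold training windows are
#'   memorized (unseen rows fall back to the first class).
#' @return A `classifier_spec`.
#' @export
classifier_memorize <- function(x = NULL, y = NULL) {
  key <- function(m) apply(round(m, 10), 1, paste, collapse = ",")
  global_map <- if (!is.null(x)) {
    map <- as.character(y)
    names(map) <- key(as.matrix(x))
    map
  }
  new_classifier_spec(
    "memorize", "features",
    fit = function(x, y, seed) {
      map <- as.character(y)
      names(map) <- key(x)
      if (!is.null(global_map)) map <- c(map, global_map)
      list(map = map, levels = levels(factor(y)))
    },
    predict = function(model, x) {
      hit <- model$map[key(x)]
      hit[is.na(hit)] <- model$levels[1]
      factor(unname(hit), levels = model$levels)
    }
  )
}

#' @rdname classifier_memorize
#' @export
classifier_majority <- function() {
  new_classifier_spec(
    "majority", "features",
    fit = function(x, y, seed) {
      tab <- table(y)
      list(label = names(tab)[which.max(tab)], levels = names(tab))
    },
    predict = function(model, x) {
      factor(rep(model$label, nrow(x)), levels = model$levels)
    }
  )
}

#' @rdname classifier_memorize
#' @export
classifier_random <- function() {
  new_classifier_spec(
    "random", "features",
    fit = function(x, y, seed) list(levels = levels(factor(y)), seed = seed),
    predict = function(model, x) {
      with_seed(model$seed, factor(
        sample(model$levels, nrow(x), replace = TRUE), levels = model$levels
      ))
    }
  )
}

# Build the representation a classifier consumes, once per window set.
classifier_inputs <- function(ws, clf) {
  switch(clf$input,
    features = featurize(ws)$x,
    flat = flatten_windows(ws),
    windows = ws$windows,
    stop("unknown classifier input kind: ", clf$input, call. = FALSE)
  )
}

# Row-subset a prepared representation.
subset_inputs <- function(inputs, idx) {
  if (is.matrix(inputs)) return(inputs[idx, , drop = FALSE])
  if (is.list(inputs) && !is.null(inputs$channel_index)) {
    return(list(x = inputs$x[idx, , drop = FALSE],
                channel_index = inputs$channel_index))
  }
  inputs[idx, , , drop = FALSE]
}
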