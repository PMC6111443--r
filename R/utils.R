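#' @keywords internal
#' @importFrom rlang .data
#' @importFrom stats predict
"_PACKAGE"

#' The seven hand-movement classes
#'
#' Class labels used throughout the package, in canonical order:
#' rest (RT), close hand (CH), open hand (OH), wrist flexion (WF),
#' wrist extension (WE), pronation (PRO) and supination (SUP).
#'
#' @return Character vector of length 7.
#' @export
movement_classes <- function() {
  c("RT", "CH", "OH", "WF", "WE", "PRO", "SUP")
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic fan-out of one global seed to component streams.
# Kept below 2^31 so the result is always a valid R integer seed.
derive_seed <- function(seed, ...) {
  parts <- c(as.character(seed), vapply(list(...), as.character, character(1)))
  key <- paste(parts, collapse = "/")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# round-half-up (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
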