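# Classed conditions so callers and tests can discriminate failure modes.
stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("trfspeech_config_error", "trfspeech_error")))
}
stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("trfspeech_data_error", "trfspeech_error")))
}
stop_fit <- function(...) {
  stop(errorCondition(paste0(...), class = c("trfspeech_fit_error", "trfspeech_error")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# One master seed; per-subject/per-condition/per-stream seeds are derived by
# a fixed integer mix kept below 2^31 so they are valid set.seed() inputs.
derive_seed <- function(seed, subject = 0L, condition = 0L, stream = 0L) {
  m <- 2147483629
  s <- (as.double(seed) %% m)
  s <- (s * 48271 + subject * 6151 + condition * 239 + stream * 7) %% m
  as.integer(s)
}

msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
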