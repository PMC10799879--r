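#' Derive a stage-specific RNG seed from a global seed
#'
#' Deterministically folds a character tag into a base seed so that every
#' pipeline stage draws from its own reproducible stream. The result is
#' always a positive integer below 2^31.
#'
#' @param seed Integer base seed.
#' @param tag Character scalar naming the consumer of the derived seed.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag))) %% m
  as.integer(((abs(seed) %% m) * 1000003 + h + 1) %% m)
}

# half-open interval membership [start, end)
`%within_ho%` <- function(x, range) x >= range[1] & x < range[2]

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# log-odds from a probability, clamped away from 0/1 so scores stay finite
safe_qlogis <- function(p, eps = 1e-6) qlogis(clamp(p, eps, 1 - eps))

config_error <- function(msg) abort(msg, class = "riskpipe_config_error")
input_error <- function(msg) abort(msg, class = "riskpipe_input_error")

assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    config_error(paste0(what, " must be probabilities in [0, 1]"))
  }
  invisible(x)
}

# stable integer rank of dates with patient-id tie-break
dob_rank <- function(dob, id) {
  o <- order(dob, id)
  r <- integer(length(dob))
  r[o] <- seq_along(o)
  r
}
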