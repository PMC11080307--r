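# Classed error helpers so callers (and the command-line wrapper) can
# distinguish configuration, data and convergence failures.
abort_config <- function(msg, ...) {
  stop(structure(class = c("parasurv_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

abort_data <- function(msg, ...) {
  stop(structure(class = c("parasurv_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

abort_convergence <- function(msg, last_iterate = NULL) {
  stop(structure(class = c("parasurv_convergence_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      last_iterate = last_iterate)))
}

#' Derive a deterministic sub-seed for a named random stream
#'
#' A single user-facing integer seed drives several independent draws
#' (covariates, event times, censoring, bootstrap resampling).  Each draw uses
#' a sub-seed derived from the global seed and a stream name, so adding one
#' more covariate stream never perturbs the event-time draws.
#'
#' @param seed integer global seed.
#' @param stream character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
stream_seed <- function(seed, stream) {
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# Evaluate `code` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# z quantile for a two-sided confidence level
z_crit <- function(conf_level) qnorm(1 - (1 - conf_level) / 2)
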