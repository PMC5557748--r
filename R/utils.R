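# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific seed from a master seed
#'
#' All stochastic stages of the pipeline draw their seed deterministically
#' from a single master seed keyed by the stage name, so a stage can be
#' re-run in isolation and still reproduce its in-pipeline output.
#'
#' @param seed Master integer seed.
#' @param stage Character stage label (e.g. `"trait"`, `"counts"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  key <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + key * 16807) %% 2147483647)
}

# stop() with a class so callers/tests can distinguish validation failures
stop_symh2 <- function(msg, class = "symh2_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
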