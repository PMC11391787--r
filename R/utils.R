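#' Derive a stage-specific random seed from a master seed
#'
#' All randomness in the package flows from one integer seed; each pipeline
#' stage (training, corruption, simulation, sweep) draws from its own stream
#' whose seed is a stable hash of the master seed and the stage name. This
#' keeps stages reorderable without changing each other's draws.
#'
#' @param seed master integer seed.
#' @param stage character stage name, e.g. `"train"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1L, "train")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  # polynomial rolling hash of the stage string, folded with the seed;
  # kept below 2^31 so it is a valid R integer everywhere
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(h)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

stopf <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "prescsim_error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
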