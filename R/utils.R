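#' Evaluate code under a fixed RNG seed
#'
#' Every stochastic operation in quadnet takes an explicit `seed` and uses a
#' private RNG stream; global RNG state is saved and restored so callers are
#' never affected.
#'
#' @param seed integer scalar.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

#' Derive a per-stage seed from the pipeline seed
#'
#' Deterministic derivation: the stage name is hashed with a small
#' polynomial rolling hash and folded into the base seed modulo 2^31 - 1,
#' so every randomized stage consumes an independent, documented stream.
#'
#' @param seed base integer seed.
#' @param stage stage name, e.g. `"lr_test"`.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (v in utf8ToInt(stage)) h <- (h * 131 + v) %% 2147483.0
  as.integer((as.numeric(seed) %% 2147480000 + h * 1000) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

check_conditions <- function(x) {
  bad <- setdiff(unique(x), CONDITIONS)
  if (length(bad) > 0L) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         "; vocabulary is {", paste(CONDITIONS, collapse = ", "), "}",
         call. = FALSE)
  }
  invisible(x)
}
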