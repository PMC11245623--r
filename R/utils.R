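#' Derive a child RNG seed from a top-level seed
#'
#' Stages of the pipeline each draw their own seed from the experiment seed
#' with a fixed integer recurrence, so that e.g. changing the number of
#' tournament sessions does not perturb seed generation upstream.
#'
#' @param seed integer top-level seed.
#' @param stage integer stage index (>= 1) or a known stage name.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, stage) {
  if (is.character(stage)) {
    stage <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  # 32-bit LCG-style mix kept in double precision (exact below 2^53)
  h <- (abs(seed) %% 2147483647) + 1
  for (k in c(stage %% 65521, stage %/% 65521 + 1)) {
    h <- (h * 48271 + k) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_carposort <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "carposort_error")))
}
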