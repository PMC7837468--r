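# internal helpers shared across modules

#' Derive a reproducible sub-seed from a master seed and a stage label
#'
#' One global seed deterministically fans out to per-stage seeds so that,
#' e.g., the weight initialization of head 1 does not depend on whether a
#' second head exists. The hash is a small polynomial rolling hash of the
#' label, kept below 2^31.
#'
#' @param seed integer master seed.
#' @param label character stage label, e.g. "trunk", "shuffle".
#' @return an integer seed.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (cp in utf8ToInt(label)) h <- (h * 131 + cp) %% 1013904223
  as.integer((abs(seed) + h) %% (.Machine$integer.max - 1L)) + 1L
}

# run code under a local RNG seed, restoring global RNG state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(..., call. = FALSE)
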