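# Internal helpers: classed conditions, seed derivation, small numerics.

eegdfc_condition <- function(class, message, call = sys.call(-1)) {
  structure(
    class = c(class, "eegdfc_error", "error", "condition"),
    list(message = message, call = call)
  )
}

stop_config <- function(...) stop(eegdfc_condition("eegdfc_config_error", paste0(...)))
stop_data   <- function(...) stop(eegdfc_condition("eegdfc_data_error", paste0(...)))
stop_key    <- function(...) stop(eegdfc_condition("eegdfc_key_error", paste0(...)))
stop_dependency <- function(...) stop(eegdfc_condition("eegdfc_dependency_error", paste0(...)))

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a base seed and integer coordinates
#'
#' All randomness in the package flows through seeds derived with this hash,
#' so that per-record or per-stage substreams are reproducible independently
#' of evaluation order. The result is always in `[0, 2^31 - 2]`.
#'
#' @param seed integer base seed.
#' @param ... further integer coordinates (e.g. subject, trial).
#' @return a single integer usable with [set.seed()].
#' @export
derive_seed <- function(seed, ...) {
  v <- c(seed, ...)
  stopifnot(length(v) >= 1, all(is.finite(v)))
  h <- 0
  for (x in as.numeric(v)) {
    h <- (h * 1000003 + (x %% 2147483647) + 12345) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG stream afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

is_count <- function(x, min = 1) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x)
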