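# Internal helpers shared across modules.

#' Derive a reproducible sub-stream seed from a master seed
#'
#' Each stochastic stage (taxonomy, sampling, forest fitting, permutations,
#' bootstraps) consumes its own named stream so that every analysis stage is
#' independently reproducible under one master seed.
#'
#' @param seed master seed (integer).
#' @param ... character/numeric labels naming the stream.
#' @return an integer seed < 2^31, suitable for [set.seed()].
#' @keywords internal
derive_seed <- function(seed, ...) {
  key <- paste(c(...), collapse = "/")
  codes <- utf8ToInt(key)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

#' Evaluate an expression with a temporary RNG state
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == round(x)
}

# message channel for exclusion/bookkeeping logs; stage-scoped prefix
log_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}
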