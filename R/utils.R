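#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never perturbs the
#' caller's RNG stream. All stochastic operations in the package route
#' through this.
#'
#' @param seed integer seed (must be below 2^31).
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Deterministic fan-out so each pipeline stage is independently
#' reproducible from one global seed. Result is always in [1, 2^31 - 2].
#'
#' @param seed master seed.
#' @param offset stage index or a stage name (hashed).
#' @export
derive_seed <- function(seed, offset) {
  if (is.character(offset)) {
    offset <- sum(utf8ToInt(offset) * seq_along(utf8ToInt(offset)))
  }
  m <- 2147483647  # 2^31 - 1, Mersenne prime; Lehmer-style mix
  s <- (as.double(seed) %% m) + 1
  s <- (s * 48271 + as.double(offset) * 16807) %% m
  as.integer(s + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sigcorr_log <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}
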