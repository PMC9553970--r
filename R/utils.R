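#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a per-trial seed from a master seed
#'
#' Counter-based derivation so each trial is reproducible independently of
#' execution order. Result is always a positive integer below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param index Trial counter (>= 0).
#' @return Integer seed.
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1,
            is.numeric(index), length(index) == 1, index >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(master) %% m)
  # two rounds of a multiplicative mix keep nearby (master, index) pairs apart
  s <- (s * 48271 + index * 16807 + 12345) %% m
  s <- (s * 69621 + 7919) %% m
  as.integer(if (s == 0) 1 else s)
}

# stop() with a consistent prefix for config/field errors
field_error <- function(field, msg) {
  stop(sprintf("config field `%s`: %s", field, msg), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == round(x)
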