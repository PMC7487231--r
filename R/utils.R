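# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a deterministic per-stage child seed
#'
#' All randomness in the pipeline flows from a single run seed; each stage
#' (bootstrap, MCMC, null model, simulation) draws from its own child
#' stream so that reordering stages does not change any stage's results.
#' The child seed is a deterministic hash of the run seed and the stage
#' label, kept within the 32-bit integer range R requires.
#'
#' @param seed Integer run seed.
#' @param stage Character stage label (e.g. `"mcmc"`, `"vaznull"`).
#' @return A single integer usable with [set.seed()].
#' @examples
#' child_seed(1L, "mcmc")
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(seed) %% 1000003) * 1009 + h * 97 + 1) %% 2147483587L
}

stop_bad_column <- function(missing, where) {
  stop(sprintf("%s: missing required column(s): %s", where,
               paste(missing, collapse = ", ")), call. = FALSE)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
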