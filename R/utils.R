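# internal RNG plumbing: every stochastic entry point takes an integer seed and
# restores the caller's RNG state afterwards, so library code never perturbs
# the global stream.

#' Derive a stage-specific seed from a global seed
#'
#' Deterministically maps a (seed, label) pair to an integer in
#' `[0, 2^31 - 2]`, so that one global seed can drive many independent
#' stochastic stages (session building, choice simulation, gaze simulation,
#' fitting) without reusing the same stream.
#'
#' @param seed Integer global seed.
#' @param label Character stage label, e.g. `"choices-7"`.
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "choices-3")
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps results in integer range
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% m
  as.integer((abs(seed) %% m * 48271 + h * 69621 + 12345) %% m)
}

# run `code` under a temporary RNG state; restores .Random.seed on exit
with_seed <- function(seed, code) {
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
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recursive modifyList that ignores NULL overrides
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  utils::modifyList(base, override)
}
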