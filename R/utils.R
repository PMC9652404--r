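#' Derive a reproducible child seed from a master seed and stream name
#'
#' All randomness in the package flows from one master seed; each stage draws
#' from its own named stream so that adding draws to one stage never perturbs
#' another. The child seed is a deterministic 31-bit hash of (seed, name).
#'
#' @param seed integer master seed.
#' @param name character stream name, e.g. `"cohort"`, `"grids"`.
#' @return An integer seed in `[0, 2^31 - 1]`.
#' @export
child_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed) %% 2147483647
  for (k in utf8ToInt(name)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Run expr with a locally set RNG state; restores the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Geometric mean of strictly positive values.
geometric_mean <- function(x) {
  stopifnot(all(x > 0))
  exp(mean(log(x)))
}
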