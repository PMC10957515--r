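# Internal numerical helpers shared across modules.

sigmoidFn <- function(x) 1 / (1 + exp(-x))

reluFn <- function(x) pmax(x, 0)

#' Derive named sub-seeds from one run seed
#'
#' All randomness in the package flows from a single run seed fanned out
#' to named sub-streams so that e.g. the data split and the weight
#' initialization cannot interfere with each other's reproducibility.
#'
#' @param seed Integer master seed.
#' @param what Character name of the sub-stream (e.g. `"split"`,
#'   `"init"`, `"sampler"`, `"generator"`).
#' @return A single integer seed in `[0, 2^31)`.
#' @export
#' @examples
#' subSeed(1L, "split")
subSeed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(what))
  h <- stableStringHash(paste0(what, ":", format(seed, scientific = FALSE)))
  as.integer(h)
}

# Deterministic polynomial rolling hash of a string into [0, 2^31 - 62].
# Used for sub-seed fan-out and for the deterministic embedding stub; must
# not depend on R's RNG or on locale.
stableStringHash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  mod <- 2147483587  # largest prime below 2^31 - 60
  h <- 7
  for (b in bytes) {
    h <- (h * 131 + b) %% mod
  }
  h
}

# Evaluate expr with a locally-seeded RNG, restoring the caller's RNG
# state afterwards so deterministic helpers do not perturb user code.
withLocalSeed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

# Glorot-style uniform init for a fan_in x fan_out matrix.
glorotMatrix <- function(nin, nout) {
  r <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -r, r), nin, nout)
}

oneHot <- function(index, n) {
  v <- numeric(n)
  v[index] <- 1
  v
}
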