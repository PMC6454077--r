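#' @importFrom stats rnorm runif approx median quantile cor wilcox.test
#'   smooth.spline predict var
#' @importFrom utils read.csv write.csv
NULL

# Evaluate expr with a locally set RNG seed; the caller's RNG state is
# restored afterwards so simulation helpers never perturb the session stream.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old))
        rm(".Random.seed", envir = globalenv())
      else
        assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

stopInvalid <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

# Deterministic sub-seed table: one master seed fans out to n reproducible
# 31-bit sub-seeds so independent noise/timing draws never share a stream.
subSeeds <- function(seed, n)
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
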