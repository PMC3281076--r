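#' Derive a per-stage random seed from a master seed
#'
#' All randomized stages draw their seeds from one master seed, keyed by a
#' stage-name string, so that a single integer reproduces a full run while
#' stages remain statistically independent streams.
#'
#' @param master integer master seed.
#' @param stage character stage key, e.g. `"consensus:17"`.
#' @return An integer in `[0, 2^31 - 2]`, deterministic in `(master, stage)`.
#' @export
#' @examples
#' stage_seed(1, "sam") != stage_seed(1, "consensus")
stage_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage),
            length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps seeds in 32-bit range
  h <- as.numeric(master) %% m
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% m
  }
  as.integer(h)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# Internal: keeps package functions from clobbering the global stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
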