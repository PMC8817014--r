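#' Derive a named sub-stream seed from a master seed
#'
#' One master seed drives every source of randomness in a run. Each logical
#' stream (population, outcome noise, each policy's assignment draws per
#' period, ...) gets its own derived seed, so that toggling one component
#' (e.g. adding a policy) never perturbs the draws of another.
#'
#' The derivation is a small string hash folded with the master seed modulo
#' 2^31 - 1, so results are identical across platforms and R sessions.
#'
#' @param seed Integer master seed.
#' @param name Character stream label, e.g. `"population"` or
#'   `"policy/rita/period/12"`.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @examples
#' substream_seed(1L, "population")
#' substream_seed(1L, "noise")
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name),
            length(name) == 1L)
  m <- 2147483647
  h <- abs(as.double(seed)) %% m
  for (ch in utf8ToInt(name)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG state is restored afterwards.
with_stream <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}
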