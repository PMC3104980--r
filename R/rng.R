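#' Derive a reproducible child seed from a root seed
#'
#' All randomness in the simulation engine flows from one root seed; batches
#' (and any other parallel streams) get their own substream seeds through this
#' deterministic mixer, so changing the number of batches never alters the
#' draws of earlier batches.
#'
#' The mixer is a short Lehmer-style walk modulo the Mersenne prime
#' \eqn{2^{31}-1}: multiplications by 48271 stay below \eqn{2^{53}} so the
#' arithmetic is exact in doubles, and the result is always a valid
#' \code{set.seed()} input strictly below \eqn{2^{31}}.
#'
#' @param root integer root seed.
#' @param index nonnegative integer stream index.
#' @return an integer seed in \code{[1, 2^31 - 2]}.
#' @examples
#' child_seed(42, 1)
#' child_seed(42, 2)
#' @export
child_seed <- function(root, index) {
  stopifnot(is.numeric(root), length(root) == 1L, is.finite(root),
            is.numeric(index), length(index) == 1L, is.finite(index), index >= 0)
  m <- 2147483647
  x <- (abs(root) %% (m - 1)) + 1
  x <- (x + (index %% (m - 1))) %% m
  if (x == 0) x <- 1
  for (i in 1:3) x <- (x * 48271) %% m
  as.integer(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL means "use the ambient RNG".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
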