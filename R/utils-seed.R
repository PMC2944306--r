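#' Derive a child seed from a root seed and a stream path
#'
#' Deterministically mixes a root seed with an arbitrary sequence of integer
#' identifiers (scenario index, replication index, chain index, ...) into a
#' new seed, so that any sub-computation of a run can be reproduced in
#' isolation without replaying the whole random stream.
#'
#' @param root integer root seed.
#' @param ... further integer identifiers naming the stream.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @examples
#' child_seed(1, 3, 42)
#' @export
child_seed <- function(root, ...) {
  ids <- c(as.numeric(root), as.numeric(unlist(list(...))))
  if (any(!is.finite(ids))) stop("seed path must be finite numbers")
  h <- 17
  # LCG-style mixing; multipliers kept small so all products stay < 2^53
  for (x in ids) {
    h <- (h * 69069 + (x %% 2147483647) * 12345 + 1) %% 2147483647
    h <- (h * 40014) %% 2147483563
  }
  as.integer(h %% 2147483645 + 1)
}

# Evaluate `expr` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  expr
}
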