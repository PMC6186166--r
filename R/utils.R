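#' Derive a reproducible child seed from a master seed and a tag
#'
#' One master seed drives the whole analysis; every stochastic component
#' (count simulation, each thinning cell, each permutation null) draws its
#' own child seed from the master via this splitting rule, so any single
#' stage can be re-run in isolation and reproduce its output exactly.
#'
#' The rule is a Lehmer-style mix: the tag is hashed to an integer by
#' iterated `h <- (31 * h + byte) mod (2^31 - 1)` over its UTF-8 bytes, and
#' the child is `(48271 * (master mod p) + h) mod p` with `p = 2^31 - 1`,
#' mapped away from zero. All arithmetic stays below 2^53 so the result is
#' exact in double precision.
#'
#' @param master integer master seed.
#' @param tag character label of the component (e.g. `"counts"`,
#'   `"f0.5_iter3"`).
#' @return a single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' child_seed(1, "counts")
#' child_seed(1, "f0.5_iter3")
child_seed <- function(master, tag) {
  stopifnot(length(master) == 1L, is.finite(master), length(tag) == 1L)
  p <- 2147483647
  h <- 0
  for (b in utf8ToInt(as.character(tag))) h <- (31 * h + b) %% p
  s <- (48271 * (as.numeric(master) %% p) + h) %% p
  if (s == 0) s <- 1
  as.integer(s)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Abort with a classed condition so callers/tests can distinguish error kinds.
stop_connstab <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "connstab_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

geometric_mean <- function(x) exp(mean(log(x)))
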