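# Self-contained RNG streams so generator functions are deterministic per
# seed without clobbering the caller's .Random.seed.

make_rng <- function(seed) {
  if (is.null(seed) || !is.finite(seed)) {
    stop("an explicit integer `seed` is required", call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  expr
}

# Uniform random proper rotation via a normalized Gaussian quaternion.
random_rotation <- function(rng) {
  q <- with_rng(rng, stats::rnorm(4))
  rotmat_from_quat(q)
}
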