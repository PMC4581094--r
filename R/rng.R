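# Seed hygiene: every stochastic operation takes an explicit seed and leaves
# the caller's RNG stream untouched.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# uniform point in a 3D ball of radius r around center
runif_ball <- function(n, r, center = c(0, 0, 0)) {
  u <- matrix(stats::rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  rad <- r * stats::runif(n)^(1 / 3)
  sweep(u * rad, 2, center, `+`)
}

unit3 <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) c(1, 0, 0) else v / nv
}
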