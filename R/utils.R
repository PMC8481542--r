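# internal geometry / RNG helpers

# rotation matrix from a unit quaternion (w, x, y, z)
.quatToRotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# uniform random rotation over SO(3) (Shoemake's subgroup algorithm)
.randomRotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  .quatToRotation(q)
}

# rotation about a random axis by an angle drawn uniformly in [0, maxDeg]
.smallRandomRotation <- function(maxDeg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, maxDeg) * pi / 180
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# evaluate an expression with a locally-seeded RNG, restoring global state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed from a parent seed and a stream index, kept < 2^31
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647L)
}

.centroid <- function(m) colMeans(m)

.stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
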