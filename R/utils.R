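# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulations never leak global state.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Euclidean distances between every row of a (n x 3) and every row of b (m x 3).
cross_distances <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vec_norm <- function(v) sqrt(sum(v * v))

# Angle at vertex b of the triangle a-b-c, in degrees.
angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / (vec_norm(u) * vec_norm(v))
  cosang <- max(-1, min(1, cosang))
  acos(cosang) * 180 / pi
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)
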