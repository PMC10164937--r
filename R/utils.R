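# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Centroid of a k x 2 coordinate matrix.
configCentroid <- function(x) colMeans(x)

# Center a configuration at the origin.
centerConfig <- function(x) sweep(x, 2, colMeans(x))

# Flatten a k x 2 matrix to a length-2k vector (x1, y1, x2, y2, ...).
flattenConfig <- function(x) as.vector(t(x))

# Inverse of flattenConfig.
unflattenConfig <- function(v) matrix(v, ncol = 2, byrow = TRUE)

# Optimal rotation in SO(2) aligning A onto B (no reflection): returns R
# minimizing ||A %*% R - B||_F subject to det(R) = +1.
optimalRotation <- function(A, B) {
  C <- crossprod(A, B)
  s <- svd(C)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, d)) %*% t(s$v)
}

# Signed polygon area (shoelace); positive for counter-clockwise traversal.
signedArea <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Polygon perimeter including the closing edge.
polygonPerimeter <- function(pts) {
  d <- sqrt(rowSums((pts[c(2:nrow(pts), 1), , drop = FALSE] - pts)^2))
  sum(d)
}

stopifnotScalarCount <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < 1)
    stop(sprintf("'%s' must be a single positive integer", name), call. = FALSE)
  as.integer(x)
}
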