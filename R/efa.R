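# Elliptic Fourier analysis of closed contours: arc-length resampling,
# Kuhl-Giardina decomposition, first-harmonic normalization (NEF),
# outline size measures and inverse synthesis.

#' Resample a closed contour equally by arc length
#'
#' The polygonal contour is forced counter-clockwise (positive shoelace
#' area), then \code{m} points are placed at equal arc-length spacing along
#' the polygon, starting at the original first point (the anchor landmark).
#'
#' @param pts \code{m0 x 2} matrix of contour coordinates; a repeated final
#'   point is dropped.
#' @param m target point count (>= 8).
#' @return \code{m x 2} matrix of resampled coordinates.
#' @examples
#' sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
#' resampleContour(sq, 8)
#' @export
resampleContour <- function(pts, m) {
  m <- stopifnotScalarCount(m, "m")
  if (m < 8L) stop("m must be at least 8")
  pts <- as.matrix(pts)
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (nrow(pts) < 3L) stop("degenerate contour")
  if (signedArea(pts) < 0)  # clockwise input: reverse, keeping start point
    pts <- pts[c(1L, nrow(pts):2L), , drop = FALSE]
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  if (sum(seg) == 0) stop("degenerate contour: zero perimeter")
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  target <- total * (seq_len(m) - 1) / m
  out <- matrix(0, m, 2)
  j <- 1L
  for (i in seq_len(m)) {
    while (cum[j + 1L] < target[i]) j <- j + 1L
    w <- if (seg[j] > 0) (target[i] - cum[j]) / seg[j] else 0
    out[i, ] <- (1 - w) * closed[j, ] + w * closed[j + 1L, ]
  }
  out
}

# Raw Kuhl-Giardina elliptic Fourier coefficients of a closed polygon.
efaRaw <- function(pts, H) {
  closed <- rbind(pts, pts[1, ])
  dxy <- diff(closed)
  dt <- sqrt(rowSums(dxy^2))
  keep <- dt > 0
  dxy <- dxy[keep, , drop = FALSE]
  dt <- dt[keep]
  T <- sum(dt)
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  harm <- matrix(0, H, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(H)) {
    w <- 2 * pi * n / T
    cosd <- cos(w * t1) - cos(w * t0)
    sind <- sin(w * t1) - sin(w * t0)
    cf <- T / (2 * pi^2 * n^2)
    harm[n, "a"] <- cf * sum(dxy[, 1] / dt * cosd)
    harm[n, "b"] <- cf * sum(dxy[, 1] / dt * sind)
    harm[n, "c"] <- cf * sum(dxy[, 2] / dt * cosd)
    harm[n, "d"] <- cf * sum(dxy[, 2] / dt * sind)
  }
  # DC components (A0, C0)
  xi <- c(0, cumsum(dxy[, 1]))[-(length(dt) + 1)]
  delta <- c(0, cumsum(dxy[, 2]))[-(length(dt) + 1)]
  A0 <- sum(dxy[, 1] / (2 * dt) * (t1^2 - t0^2) +
              (xi - dxy[, 1] / dt * t0) * dt) / T + pts[1, 1]
  C0 <- sum(dxy[, 2] / (2 * dt) * (t1^2 - t0^2) +
              (delta - dxy[, 2] / dt * t0) * dt) / T + pts[1, 2]
  list(harm = harm, dc = c(A0, C0))
}

# Apply a starting-point shift (angle theta per harmonic order) and a rigid
# rotation psi to a harmonic matrix.
rotateHarmonics <- function(harm, theta = 0, psi = 0) {
  H <- nrow(harm)
  out <- harm
  for (n in seq_len(H)) {
    M <- matrix(harm[n, ], 2, 2, byrow = TRUE)  # [a b; c d]
    S <- matrix(c(cos(n * theta), -sin(n * theta),
                  sin(n * theta),  cos(n * theta)), 2, 2, byrow = TRUE)
    R <- matrix(c(cos(psi), sin(psi),
                  -sin(psi), cos(psi)), 2, 2, byrow = TRUE)
    out[n, ] <- as.vector(t(R %*% M %*% S))
  }
  out
}

#' Elliptic Fourier decomposition of a closed contour
#'
#' Computes the elliptic Fourier coefficients of the arc-length
#' parameterization x(t), y(t) of a closed polygonal contour.  With
#' \code{normalize = TRUE} the classic first-harmonic normalization is
#' applied: the starting point is rotated to the first ellipse's major axis
#' and the shape is rotated so that axis lies along x, making the
#' coefficients invariant to translation, rotation and starting point; size
#' is removed by dividing by the semi-major axis length, so \code{a1 = 1}
#' and \code{b1 = c1 = 0}.  Size itself is reported separately by
#' [outlineSizeMeasures()].
#'
#' @param pts \code{m x 2} matrix; a resampled closed contour (see
#'   [resampleContour()]).
#' @param H number of harmonics; must not exceed m/2 (aliasing).
#' @param normalize logical; return normalized (NEF) coefficients.
#' @return An [EFACoefficients-class] object.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 65)[-65]
#' circ <- cbind(cos(th), sin(th))
#' efaDecompose(circ, H = 4)
#' @export
efaDecompose <- function(pts, H = 7L, normalize = TRUE) {
  H <- stopifnotScalarCount(H, "H")
  pts <- as.matrix(pts)
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (H > nrow(pts) / 2)
    stop("H = ", H, " exceeds m/2 = ", nrow(pts) / 2, " (aliasing)")
  raw <- efaRaw(pts, H)
  if (!normalize)
    return(new("EFACoefficients", harmonics = raw$harm, dc = raw$dc,
               normalized = FALSE))
  harm <- normalizeHarmonics(raw$harm)
  new("EFACoefficients", harmonics = harm, dc = c(0, 0), normalized = TRUE)
}

# First-harmonic normalization with canonical resolution of the axis and
# orientation ambiguities: among the four candidate starting-point angles
# theta0 + c*pi/2 the one maximizing the normalized a1 is kept.
normalizeHarmonics <- function(harm) {
  a1 <- harm[1, "a"]; b1 <- harm[1, "b"]
  c1 <- harm[1, "c"]; d1 <- harm[1, "d"]
  theta0 <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                        a1^2 + c1^2 - b1^2 - d1^2)
  cands <- lapply(0:3, function(cc) {
    h1 <- rotateHarmonics(harm, theta = theta0 + cc * pi / 2)
    psi <- atan2(h1[1, "c"], h1[1, "a"])
    rotateHarmonics(h1, psi = psi)
  })
  # keep candidates whose a1 is the semi-major axis; the two survivors are
  # the 180-degree pair (even harmonics sign-flipped) -- break the tie by
  # the sign of the first significant later coefficient
  a1s <- vapply(cands, function(h) h[1, "a"], 0)
  cands <- cands[a1s >= max(a1s) - 1e-9 * max(a1s)]
  best <- cands[[1]]
  for (h in cands[-1]) {
    va <- as.vector(t(best / best[1, "a"]))
    vb <- as.vector(t(h / h[1, "a"]))
    d <- which(abs(va - vb) > 1e-9)
    if (length(d) && vb[d[1]] > va[d[1]]) best <- h
  }
  out <- best / best[1, "a"]
  out[1, c("b", "c")] <- 0  # zero by construction; remove rounding dust
  out
}

#' Outline size measures
#'
#' Three size variables of a closed contour: the square root of the
#' enclosed (shoelace) area, the perimeter, and the semi-major axis of the
#' first Fourier ellipse.  The semi-major axis serves as the outline
#' analogue of centroid size in downstream size statistics.
#'
#' @param pts \code{m x 2} closed-contour coordinate matrix (mm).
#' @return list with \code{sqrtArea}, \code{perimeter} and
#'   \code{semiMajor1}, all in mm.  A self-intersecting contour triggers a
#'   warning and the absolute area is used.
#' @export
outlineSizeMeasures <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ]))
    pts <- pts[-nrow(pts), , drop = FALSE]
  A <- signedArea(pts)
  raw <- efaRaw(pts, 1L)
  semi <- svd(matrix(raw$harm[1, ], 2, 2, byrow = TRUE))$d
  list(sqrtArea = sqrt(abs(A)),
       perimeter = polygonPerimeter(pts),
       semiMajor1 = semi[1])
}

#' Reconstruct a contour from elliptic Fourier coefficients
#'
#' Inverse Fourier synthesis at \code{m} equally spaced parameter values.
#'
#' @param coeffs an [EFACoefficients-class].
#' @param m number of points to synthesize.
#' @return \code{m x 2} coordinate matrix.
#' @export
reconstructContour <- function(coeffs, m = 128L) {
  stopifnot(is(coeffs, "EFACoefficients"))
  m <- stopifnotScalarCount(m, "m")
  t <- 2 * pi * (seq_len(m) - 1) / m
  H <- nrow(coeffs@harmonics)
  x <- rep(coeffs@dc[1], m)
  y <- rep(coeffs@dc[2], m)
  for (n in seq_len(H)) {
    x <- x + coeffs@harmonics[n, "a"] * cos(n * t) +
      coeffs@harmonics[n, "b"] * sin(n * t)
    y <- y + coeffs@harmonics[n, "c"] * cos(n * t) +
      coeffs@harmonics[n, "d"] * sin(n * t)
  }
  cbind(x, y)
}

#' Normalized elliptic Fourier feature matrix for an outline dataset
#'
#' Resamples every contour, decomposes it to \code{H} harmonics with
#' normalization, and flattens the coefficients into one row per specimen.
#' The three coefficients fixed by the normalization (a1 = 1, b1 = c1 = 0)
#' are omitted, leaving \code{4H - 3} shape variables.
#'
#' @param x an [OutlineDataset-class].
#' @param H harmonic count (default 7, capturing >= 99\\% of harmonic power
#'   on smooth wing-cell contours).
#' @param m resampling density before decomposition.
#' @return numeric matrix, specimens x (4H - 3), with rownames = specimen
#'   ids and an attribute \code{"sizes"} holding the per-specimen
#'   [outlineSizeMeasures()] semi-major axes (mm).
#' @export
efaFeatures <- function(x, H = 7L, m = 256L) {
  stopifnot(is(x, "OutlineDataset"))
  n <- nSpecimens(x)
  feats <- matrix(0, n, 4 * H - 3)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    rc <- resampleContour(x@contours[[i]], m)
    cf <- efaDecompose(rc, H = H, normalize = TRUE)
    h <- cf@harmonics
    feats[i, ] <- c(h[1, "d"], if (H > 1) as.vector(t(h[-1, , drop = FALSE])))
    sizes[i] <- outlineSizeMeasures(rc)$semiMajor1
  }
  rownames(feats) <- specimenIds(x)
  cn <- c("d1")
  if (H > 1)
    cn <- c(cn, as.vector(t(outer(2:H, c("a", "b", "c", "d"),
                                  function(n, l) paste0(l, n)))))
  colnames(feats) <- cn
  attr(feats, "sizes") <- setNames(sizes, specimenIds(x))
  feats
}

#' Outline size table for a dataset
#'
#' @param x an [OutlineDataset-class].
#' @param m resampling density.
#' @return data.frame with id, population, sqrtArea, perimeter, semiMajor1.
#' @export
outlineSizes <- function(x, m = 256L) {
  stopifnot(is(x, "OutlineDataset"))
  res <- lapply(x@contours, function(p) outlineSizeMeasures(resampleContour(p, m)))
  data.frame(id = specimenIds(x),
             population = x@specimens$population,
             sqrtArea = vapply(res, `[[`, 0, "sqrtArea"),
             perimeter = vapply(res, `[[`, 0, "perimeter"),
             semiMajor1 = vapply(res, `[[`, 0, "semiMajor1"),
             row.names = NULL)
}
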