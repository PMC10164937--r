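# Generalized least-squares Procrustes superimposition and relative warps.

#' @rdname centroidSize
setMethod("centroidSize", "matrix", function(x) {
  if (nrow(x) < 3L) stop("at least 3 landmarks are required")
  if (!all(is.finite(x))) stop("coordinates must be finite")
  cs <- sqrt(sum(centerConfig(x)^2))
  if (cs == 0) stop("degenerate configuration: all landmarks coincide")
  cs
})

#' @rdname centroidSize
setMethod("centroidSize", "WingDataset", function(x) {
  setNames(apply(x@coords, 3, function(m) centroidSize(m)), specimenIds(x))
})

#' Generalized Procrustes superimposition
#'
#' Iteratively translates, scales and rotates every configuration onto the
#' evolving consensus: each configuration is centred and scaled to unit
#' centroid size, rotated to the consensus by the least-squares optimal
#' rotation, and the consensus (unit-size mean shape) is recomputed until its
#' root-mean-square change falls below \code{tol}.  Reflections are never
#' used (rotation determinants are constrained to +1), appropriate when all
#' specimens are digitized on the same body side.
#'
#' @param x a [WingDataset-class] with at least two configurations.
#' @param tol convergence tolerance on the RMS change of the consensus.
#' @param maxIterations iteration cap; when reached without convergence the
#'   fit is returned with \code{converged = FALSE} and a warning.
#' @return A [ProcrustesFit-class]: superimposed unit-size coordinates, the
#'   consensus shape, original centroid sizes (mm) and convergence info.
#' @seealso [relativeWarps()], [centroidSize()]
#' @examples
#' cfg <- wingSimConfig(nPerGroup = c(5, 5, 5))
#' fit <- gpaAlign(simulateLandmarkDataset(cfg, seed = 1))
#' fit
#' @export
gpaAlign <- function(x, tol = 1e-10, maxIterations = 100L) {
  stopifnot(is(x, "WingDataset"))
  n <- nSpecimens(x)
  if (n < 2L) stop("at least two configurations are required")
  k <- landmarkCount(x)
  cs <- unname(centroidSize(x))
  scaled <- array(0, dim = c(k, 2, n))
  for (i in seq_len(n))
    scaled[, , i] <- centerConfig(x@coords[, , i]) / cs[i]

  consensus <- scaled[, , 1]
  consensus <- consensus / sqrt(sum(consensus^2))
  aligned <- scaled
  converged <- FALSE
  iter <- 0L
  while (iter < maxIterations) {
    iter <- iter + 1L
    for (i in seq_len(n))
      aligned[, , i] <- scaled[, , i] %*% optimalRotation(scaled[, , i], consensus)
    newCons <- apply(aligned, c(1, 2), mean)
    newCons <- newCons / sqrt(sum(newCons^2))
    delta <- sqrt(mean((newCons - consensus)^2))
    consensus <- newCons
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Procrustes superimposition did not converge in ",
            maxIterations, " iterations")
  dimnames(aligned) <- dimnames(x@coords)
  # reported consensus is the arithmetic mean of the aligned shapes (the
  # unit-size rescaling is only the scale gauge of the iteration), so
  # residuals sum to zero and their sum of squares is the minimized
  # Procrustes sum of squares
  new("ProcrustesFit", aligned = aligned,
      consensus = apply(aligned, c(1, 2), mean),
      cs = cs, specimens = x@specimens, iterations = iter,
      converged = converged)
}

# Components of a Procrustes fit: alignedCoords (superimposed array),
# consensusShape (unit-size mean), residualCoords (aligned minus consensus),
# centroidSizes (original sizes in mm).

#' @rdname gpaAlign
setMethod("alignedCoords", "ProcrustesFit", function(x) x@aligned)

#' @rdname gpaAlign
setMethod("consensusShape", "ProcrustesFit", function(x) x@consensus)

#' @rdname gpaAlign
setMethod("residualCoords", "ProcrustesFit", function(x) {
  sweep(x@aligned, c(1, 2), x@consensus)
})

#' @rdname gpaAlign
#' @export
centroidSizes <- function(x) {
  stopifnot(is(x, "ProcrustesFit"))
  setNames(x@cs, x@specimens$id)
}

#' Relative warps: principal components of superimposed shapes
#'
#' Performs an (unweighted) principal-component decomposition of the
#' specimen-by-coordinate matrix of superimposed shapes.  With no
#' bending-energy weighting the score space is isometric to the space of
#' Procrustes residuals, so between-specimen distances are preserved
#' exactly when all axes are retained.
#'
#' @param fit a [ProcrustesFit-class].
#' @param nAxes number of axes to retain; \code{NULL} keeps all with
#'   positive variance.  Requests beyond the matrix rank are truncated with
#'   a warning.
#' @return A [ShapeScores-class] with per-specimen scores and explained
#'   variance fractions.
#' @export
relativeWarps <- function(fit, nAxes = NULL) {
  stopifnot(is(fit, "ProcrustesFit"))
  n <- dim(fit@aligned)[3]
  X <- t(apply(fit@aligned, 3, flattenConfig))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  total <- sum(ev)
  rank <- sum(ev > max(ev) * 1e-12)
  if (is.null(nAxes)) nAxes <- rank
  if (nAxes > rank) {
    warning("nAxes = ", nAxes, " exceeds rank ", rank, "; truncated")
    nAxes <- rank
  }
  idx <- seq_len(nAxes)
  scores <- pc$x[, idx, drop = FALSE]
  rownames(scores) <- fit@specimens$id
  new("ShapeScores",
      scores = scores,
      explained = if (total > 0) ev[idx] / total else rep(0, nAxes),
      rotation = pc$rotation[, idx, drop = FALSE],
      center = pc$center)
}

#' Full Procrustes distance between two configurations
#'
#' Shapes are centred, scaled to unit centroid size and optimally rotated
#' (no reflection); the root summed squared difference is returned.
#'
#' @param a,b \code{k x 2} coordinate matrices with matching landmarks.
#' @return non-negative numeric distance.
#' @export
procrustesDistance <- function(a, b) {
  A <- centerConfig(a); A <- A / sqrt(sum(A^2))
  B <- centerConfig(b); B <- B / sqrt(sum(B^2))
  sqrt(sum((A %*% optimalRotation(A, B) - B)^2))
}
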