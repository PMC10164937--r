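# Discriminant analysis of shape variables: canonical variates, Mahalanobis
# distances with permutation significance, leave-one-out reclassification,
# allometry quantification and UPGMA dendrograms.

# Reduce a feature matrix to principal components covering `coverage` of the
# variance when the pooled within-group covariance would be singular (or
# p >= n - g).  Returns the (possibly reduced) matrix.
reduceIfSingular <- function(X, groups, coverage = 0.99) {
  n <- nrow(X); p <- ncol(X)
  g <- length(unique(groups))
  W <- pooledWithinCov(X, groups)
  ok <- p < n - g && rcond(W) > 1e-10
  if (ok) return(X)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  keep <- which(cumsum(ev) / sum(ev) >= coverage)[1]
  keep <- min(keep, n - g - 1L)
  keep <- max(keep, 1L)
  message("singular pooled covariance: reduced to ", keep,
          " principal components")
  pc$x[, seq_len(keep), drop = FALSE]
}

# g x p matrix of group means, robust to p = 1.
groupMeansMatrix <- function(X, groups, labs) {
  out <- do.call(rbind, lapply(labs, function(gl)
    colMeans(X[groups == gl, , drop = FALSE])))
  rownames(out) <- labs
  out
}

pooledWithinCov <- function(X, groups) {
  labs <- unique(groups)
  n <- nrow(X)
  S <- matrix(0, ncol(X), ncol(X))
  for (gl in labs) {
    Xi <- X[groups == gl, , drop = FALSE]
    S <- S + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  S / (n - length(labs))
}

#' Canonical variate (discriminant) analysis
#'
#' Finds the axes maximizing between-group relative to pooled within-group
#' variance.  Scores are scaled so the pooled within-group covariance of
#' the discriminant factors is the identity; per-factor contributions are
#' eigenvalue fractions of the retained factors and sum to 100 percent.
#' A singular pooled covariance triggers automatic reduction to principal
#' components covering 99 percent of the variance.
#'
#' @param X numeric matrix, specimens x shape variables (relative-warp
#'   scores or normalized Fourier coefficients).
#' @param groups group label per row (>= 2 groups).
#' @return list of class \code{"cva"}: \code{scores} (n x nDF),
#'   \code{contributions} (percent per DF), \code{groupMeans} (group x nDF),
#'   \code{eigenvalues}, \code{axes} (loadings in the analysis space).
#' @examples
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' cva(X, rep(c("a", "b"), each = 20))$contributions
#' @export
cva <- function(X, groups) {
  groups <- as.character(groups)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(groups))
  labs <- unique(groups)
  g <- length(labs)
  if (g < 2L) stop("at least two groups are required")
  X <- reduceIfSingular(X, groups)
  p <- ncol(X)
  W <- pooledWithinCov(X, groups)
  gm <- groupMeansMatrix(X, groups, labs)
  grand <- colMeans(X)
  sizes <- as.vector(table(groups)[labs])
  Bm <- crossprod(sweep(gm, 2, grand) * sqrt(sizes)) / (g - 1)

  eW <- eigen(W, symmetric = TRUE)
  pos <- eW$values > max(eW$values) * 1e-10
  Wih <- eW$vectors[, pos, drop = FALSE] %*%
    diag(1 / sqrt(eW$values[pos]), sum(pos)) %*%
    t(eW$vectors[, pos, drop = FALSE])
  M <- Wih %*% Bm %*% Wih
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  nDF <- min(g - 1L, p)
  axes <- Wih %*% ee$vectors[, seq_len(nDF), drop = FALSE]
  scores <- sweep(X, 2, grand) %*% axes
  colnames(scores) <- paste0("DF", seq_len(nDF))
  rownames(scores) <- rownames(X)
  ev <- pmax(ee$values[seq_len(nDF)], 0)
  gmScores <- groupMeansMatrix(scores, groups, labs)
  structure(list(scores = scores,
                 contributions = 100 * ev / sum(ev),
                 groupMeans = gmScores, eigenvalues = ev, axes = axes,
                 groups = groups),
            class = "cva")
}

#' @export
print.cva <- function(x, ...) {
  cat("Canonical variate analysis:", ncol(x$scores), "discriminant factors\n")
  cat("  contributions:",
      paste(sprintf("%.1f%%", x$contributions), collapse = ", "), "\n")
  invisible(x)
}

# Mahalanobis distance between the means of two row-subsets under a pooled
# covariance.
mahalanobisPair <- function(X, ia, ib) {
  ma <- colMeans(X[ia, , drop = FALSE])
  mb <- colMeans(X[ib, , drop = FALSE])
  S <- (crossprod(sweep(X[ia, , drop = FALSE], 2, ma)) +
          crossprod(sweep(X[ib, , drop = FALSE], 2, mb))) /
    (length(ia) + length(ib) - 2)
  d <- ma - mb
  sqrt(as.numeric(d %*% solve(S, d)))
}

#' Pairwise Mahalanobis distances with permutation significance
#'
#' Distances between group means are computed under the pooled
#' within-group covariance of each pair; per-pair p-values come from
#' permuting the labels of the two groups' specimens and recomputing the
#' distance (add-one convention).  Permutations are seeded per pair from
#' \code{(seed, pair index)}.  Singular covariances trigger the same
#' principal-component reduction as [cva()].
#'
#' @param X numeric feature matrix (specimens x variables).
#' @param groups group label per row.
#' @param nPerm permutations per pair (default 1000).
#' @param seed integer RNG seed.
#' @return list of class \code{"mahalanobisMatrix"}: \code{distances}
#'   (symmetric, zero diagonal), \code{pValues}, \code{nPermutations},
#'   \code{seed}.
#' @export
mahalanobisMatrix <- function(X, groups, nPerm = 1000L, seed = 1L) {
  groups <- as.character(groups)
  X <- as.matrix(X)
  X <- reduceIfSingular(X, groups)
  labs <- unique(groups)
  g <- length(labs)
  D <- matrix(0, g, g, dimnames = list(labs, labs))
  P <- matrix(NA_real_, g, g, dimnames = list(labs, labs))
  pairs <- combn(seq_len(g), 2)
  for (p in seq_len(ncol(pairs))) {
    a <- labs[pairs[1, p]]; b <- labs[pairs[2, p]]
    ia <- which(groups == a); ib <- which(groups == b)
    obs <- mahalanobisPair(X, ia, ib)
    D[a, b] <- D[b, a] <- obs
    P[a, b] <- P[b, a] <- withSeed(seed + p, {
      both <- c(ia, ib)
      null <- vapply(seq_len(nPerm), function(i) {
        perm <- sample(both)
        mahalanobisPair(X, perm[seq_along(ia)], perm[-seq_along(ia)])
      }, 0)
      (sum(null >= obs - 1e-12) + 1) / (nPerm + 1)
    })
  }
  structure(list(distances = D, pValues = P,
                 nPermutations = as.integer(nPerm), seed = as.integer(seed)),
            class = "mahalanobisMatrix")
}

#' @export
print.mahalanobisMatrix <- function(x, ...) {
  cat("Pairwise Mahalanobis distances (", x$nPermutations,
      " permutations)\n", sep = "")
  print(round(x$distances, 3))
  cat("p-values:\n")
  print(round(x$pValues, 4))
  invisible(x)
}

#' Leave-one-out Mahalanobis reclassification
#'
#' Each specimen is held out in turn; group means and the pooled
#' within-group covariance are recomputed from the remaining specimens and
#' the held-out specimen is assigned to the nearest group mean in
#' Mahalanobis distance.
#'
#' @param X numeric feature matrix.
#' @param groups group label per row.
#' @return list of class \code{"classification"} (see [mlSizeClassify()]),
#'   with \code{method = "mahalanobis_shape"}.
#' @export
crossvalReclassify <- function(X, groups) {
  groups <- as.character(groups)
  X <- as.matrix(X)
  X <- reduceIfSingular(X, groups)
  labs <- unique(groups)
  n <- nrow(X)
  conf <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    gtr <- groups[-i]
    S <- pooledWithinCov(Xtr, gtr)
    Si <- tryCatch(solve(S), error = function(e) {
      # fold-singular covariance: ridge fallback keeps the fold usable
      message("fold ", i, ": singular pooled covariance, ridge applied")
      solve(S + diag(1e-8 * mean(diag(S)), ncol(S)))
    })
    d2 <- vapply(labs, function(gl) {
      mg <- colMeans(Xtr[gtr == gl, , drop = FALSE])
      dd <- X[i, ] - mg
      as.numeric(dd %*% Si %*% dd)
    }, 0)
    assigned <- labs[which.min(d2)]
    conf[groups[i], assigned] <- conf[groups[i], assigned] + 1L
  }
  classificationResult(conf, method = "mahalanobis_shape")
}

#' Allometry: determination coefficient of shape on size
#'
#' Ordinary least-squares regression of the first discriminant factor (or
#' any shape score) on centroid size; the r-squared quantifies how much of
#' the discriminant shape axis is still explained by size.  Additional
#' score columns yield \code{perDfR2}.
#'
#' @param scores numeric vector (DF1) or matrix of score columns.
#' @param cs centroid sizes, one per specimen.
#' @return list of class \code{"allometry"}: \code{r2}, \code{slope},
#'   \code{intercept} for the first column; \code{perDfR2} for all columns.
#' @examples
#' cs <- rnorm(50, 1.6, 0.1)
#' allometryR2(2 * cs, cs)$r2  # exactly 1
#' @export
allometryR2 <- function(scores, cs) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(cs))
  if (var(cs) == 0) stop("constant size: allometric slope undefined")
  fits <- lapply(seq_len(ncol(scores)), function(j) lm(scores[, j] ~ cs))
  r2 <- vapply(fits, function(f) summary(f)$r.squared, 0)
  structure(list(r2 = r2[1],
                 slope = unname(coef(fits[[1]])[2]),
                 intercept = unname(coef(fits[[1]])[1]),
                 perDfR2 = r2),
            class = "allometry")
}

#' @export
print.allometry <- function(x, ...) {
  cat(sprintf("Allometry: r2(DF1 ~ CS) = %.3f (slope %.3g)\n",
              x$r2, x$slope))
  if (length(x$perDfR2) > 1)
    cat("  further axes:",
        paste(sprintf("%.3f", x$perDfR2[-1]), collapse = ", "), "\n")
  invisible(x)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomeration of a symmetric distance matrix (typically
#' pairwise Mahalanobis distances between populations).  Merge heights are
#' ultrametric (half the average linkage distance, the conventional
#' dendrogram height), and the tree is exportable as Newick.
#'
#' @param D symmetric distance matrix with labelled rows, or a
#'   \code{"mahalanobisMatrix"} result.
#' @return list of class \code{"upgma"}: \code{hclust}, \code{phylo}
#'   (an [ape::as.phylo()] tree), \code{heights} (ultrametric merge
#'   heights), \code{merges}.
#' @examples
#' D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' upgmaTree(D)$heights  # 1, 3
#' @export
upgmaTree <- function(D) {
  if (inherits(D, "mahalanobisMatrix")) D <- D$distances
  D <- as.matrix(D)
  if (nrow(D) < 2L) stop("at least two groups are required")
  hc <- hclust(as.dist(D), method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 heights = hc$height / 2, merges = hc$merge),
            class = "upgma")
}

#' @export
print.upgma <- function(x, ...) {
  cat("UPGMA dendrogram over", length(x$hclust$labels), "groups\n")
  cat("  newick:", ape::write.tree(x$phylo), "\n")
  invisible(x)
}

#' Export a dendrogram or NJ tree as a Newick string or file
#'
#' @param tree an \code{"upgma"} result or an [ape::phylo] object.
#' @param path optional file path; when given the string is also written.
#' @return the Newick string, invisibly when writing to file.
#' @export
writeNewick <- function(tree, path = NULL) {
  phy <- if (inherits(tree, "upgma")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"))
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}
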