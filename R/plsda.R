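# Machine-learning classification of shape features: PCA exploration,
# Kennard-Stone splitting, NIPALS PLS-DA with balanced-error-rate tuning,
# and per-class ROC/AUC with rank-based significance.

#' Principal component summary of a feature matrix
#'
#' @param X numeric matrix, specimens x variables; centred internally.
#' @return list with \code{scores} and \code{explained} (per-axis variance
#'   fractions, non-increasing, summing to <= 1).
#' @examples
#' X <- matrix(rnorm(60), 20)
#' sum(pcaSummary(X)$explained)  # 1
#' @export
pcaSummary <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3L) stop("at least 3 specimens are required")
  if (all(apply(X, 2, var) == 0)) stop("constant feature matrix")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  list(scores = pc$x, explained = ev / sum(ev))
}

#' Kennard-Stone representative training split
#'
#' Deterministic max-min selection on standardized Euclidean distances:
#' the first two training points are the most distant pair; each further
#' point maximizes its minimum distance to the points already selected.
#' Ties break to the lowest row index.
#'
#' @param X numeric feature matrix; columns are standardized internally
#'   (constant columns are dropped).
#' @param trainFraction fraction of rows assigned to training, in (0, 1).
#' @return list with integer vectors \code{train} and \code{test} (row
#'   indices in selection order for \code{train}).
#' @examples
#' kennardStoneSplit(cbind(c(0, 1, 10)), 2 / 3)$train  # rows 1 and 3
#' @export
kennardStoneSplit <- function(X, trainFraction = 0.7) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("at least 3 rows are required")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must be in (0, 1)")
  keep <- apply(X, 2, sd) > 0
  Xs <- scale(X[, keep, drop = FALSE])
  D <- as.matrix(dist(Xs))
  nTrain <- max(2L, round(trainFraction * n))
  # initial pair: maximum distance, lexicographic tie-break
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- sort(unname(best[1, ]))
  while (length(sel) < nTrain) {
    rest <- setdiff(seq_len(n), sel)
    minD <- apply(D[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(minD)])
  }
  list(train = sel, test = setdiff(seq_len(n), sel))
}

# One NIPALS-style PLS2 fit of standardized X against centred one-hot Y.
# Components via the dominant singular vector of X'Y per deflation step.
plsFit <- function(X, Y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp)   # X weights
  P <- matrix(0, p, ncomp)   # X loadings
  Q <- matrix(0, ncol(Y), ncomp)  # Y loadings
  TT <- matrix(0, n, ncomp)
  Xd <- X
  for (h in seq_len(ncomp)) {
    s <- svd(crossprod(Xd, Y), nu = 1, nv = 0)
    w <- s$u[, 1]
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) { W <- W[, seq_len(h - 1), drop = FALSE]
      P <- P[, seq_len(h - 1), drop = FALSE]
      Q <- Q[, seq_len(h - 1), drop = FALSE]
      TT <- TT[, seq_len(h - 1), drop = FALSE]
      break }
    p_ <- crossprod(Xd, t) / tt
    q_ <- crossprod(Y, t) / tt
    Xd <- Xd - t %*% t(p_)
    W[, h] <- w; P[, h] <- p_; Q[, h] <- q_; TT[, h] <- t
  }
  R <- W %*% solve(crossprod(P, W))   # projection for new data
  list(W = W, P = P, Q = Q, scores = TT, R = R)
}

# Project new standardized data into component space.
plsProject <- function(fit, Xs, ncomp) {
  Xs %*% fit$R[, seq_len(ncomp), drop = FALSE]
}

#' Fit a PLS-DA classifier with balanced-error-rate tuning
#'
#' Partial least squares regression of standardized features onto centred
#' one-hot class indicators (NIPALS components).  Prediction assigns a
#' specimen to the nearest class centroid in component space.  The number
#' of components is tuned by stratified cross-validated balanced error
#' rate (mean over classes of the class-wise error); the chosen count is
#' the smallest whose BER is within one standard error of the minimum.
#'
#' @param X numeric feature matrix.
#' @param groups class label per row (>= 2 classes).
#' @param maxComponents largest component count scanned.
#' @param folds stratified cross-validation folds (default 5).
#' @param seed integer seed for the fold assignment.
#' @return list of class \code{"plsda"}: \code{nComponents},
#'   \code{tuningCurve} (data.frame: ncomp, BER, SE), \code{centroids},
#'   fitted projection matrices, scaling vectors and fold assignment.
#' @seealso [plsdaPredict()], [aucPerClass()]
#' @export
fitPLSDA <- function(X, groups, maxComponents = 10L, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  if (length(labs) < 2L) stop("at least two classes are required")
  n <- nrow(X)
  keep <- apply(X, 2, sd) > 0
  X <- X[, keep, drop = FALSE]
  maxComponents <- min(maxComponents, ncol(X), n - 2L)

  Y <- outer(groups, labs, `==`) * 1
  colnames(Y) <- labs

  foldId <- withSeed(seed, {
    id <- integer(n)
    for (gl in labs) {
      ig <- which(groups == gl)
      if (length(ig) < folds)
        stop("class ", gl, " has fewer members than folds")
      id[ig] <- sample(rep_len(seq_len(folds), length(ig)))
    }
    id
  })

  berFold <- matrix(NA_real_, folds, maxComponents)
  for (f in seq_len(folds)) {
    tr <- foldId != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    Xtr <- scale(X[tr, , drop = FALSE], mu, sg)
    Xte <- scale(X[!tr, , drop = FALSE], mu, sg)
    Ytr <- scale(Y[tr, , drop = FALSE], scale = FALSE)
    fit <- plsFit(Xtr, Ytr, maxComponents)
    hmax <- ncol(fit$W)
    for (h in seq_len(hmax)) {
      Ttr <- fit$scores[, seq_len(h), drop = FALSE]
      Tte <- plsProject(fit, Xte, h)
      cent <- groupMeansMatrix(Ttr, groups[tr], labs)
      pred <- labs[apply(Tte, 1, function(z)
        which.min(colSums((t(cent) - z)^2)))]
      truth <- groups[!tr]
      errs <- vapply(labs, function(gl) {
        ig <- truth == gl
        if (!any(ig)) return(NA_real_)
        mean(pred[ig] != gl)
      }, 0)
      berFold[f, h] <- mean(errs, na.rm = TRUE)
    }
  }
  ber <- colMeans(berFold, na.rm = TRUE)
  se <- apply(berFold, 2, function(v) sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  hmin <- which.min(ber)
  nComp <- which(ber <= ber[hmin] + se[hmin])[1]

  mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
  Xs <- scale(X, mu, sg)
  yMean <- colMeans(Y)
  fit <- plsFit(Xs, scale(Y, scale = FALSE), max(nComp, 1L))
  Tfull <- fit$scores[, seq_len(nComp), drop = FALSE]
  centroids <- groupMeansMatrix(Tfull, groups, labs)
  structure(list(nComponents = nComp,
                 tuningCurve = data.frame(ncomp = seq_along(ber),
                                          BER = ber, SE = se),
                 chosenBy = "min_BER_1se",
                 labels = labs, centroids = centroids, fit = fit,
                 mu = mu, sigma = sg, yMean = yMean, keep = keep,
                 foldId = foldId, seed = as.integer(seed)),
            class = "plsda")
}

#' Predict classes and class scores from a fitted PLS-DA model
#'
#' @param model a \code{"plsda"} fit.
#' @param X new feature matrix (same columns as training).
#' @return list with \code{class} (assigned labels), \code{scores}
#'   (component coordinates) and \code{yhat} (per-class regression scores,
#'   used for ROC/AUC).
#' @export
plsdaPredict <- function(model, X) {
  X <- as.matrix(X)[, model$keep, drop = FALSE]
  Xs <- scale(X, model$mu, model$sigma)
  TT <- plsProject(model$fit, Xs, model$nComponents)
  cent <- model$centroids
  cls <- model$labels[apply(TT, 1, function(z)
    which.min(colSums((t(cent) - z)^2)))]
  yhat <- sweep(TT %*% t(model$fit$Q[, seq_len(model$nComponents),
                                     drop = FALSE]), 2, -model$yMean)
  colnames(yhat) <- model$labels
  list(class = cls, scores = TT, yhat = yhat)
}

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA model:", x$nComponents, "components (min-BER within 1 SE)\n")
  cat("  tuning BER:",
      paste(sprintf("%.3f", x$tuningCurve$BER), collapse = ", "), "\n")
  invisible(x)
}

#' Per-class AUC with rank-based significance
#'
#' One-vs-rest area under the ROC curve for each class, computed from a
#' per-class numeric score via the rank (Mann-Whitney) identity, with a
#' one-sided Wilcoxon rank-sum p-value for the hypothesis that in-class
#' scores exceed out-of-class scores.
#'
#' @param scores numeric matrix, specimens x classes, higher = more
#'   class-like (e.g. \code{plsdaPredict()$yhat}).
#' @param labels true class per row.
#' @return data.frame with class, auc, p, nIn, nOut.  Classes absent from
#'   \code{labels} are reported with NA.
#' @examples
#' y <- rep(c("a", "b"), each = 20)
#' s <- cbind(a = (y == "a") * 1, b = (y == "b") * 1)
#' aucPerClass(s, y)$auc  # 1, 1
#' @export
aucPerClass <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  cls <- colnames(scores)
  if (is.null(cls)) stop("scores must have class-named columns")
  out <- data.frame(class = cls, auc = NA_real_, p = NA_real_,
                    nIn = 0L, nOut = 0L)
  for (j in seq_along(cls)) {
    pos <- labels == cls[j]
    n1 <- sum(pos); n0 <- sum(!pos)
    out$nIn[j] <- n1; out$nOut[j] <- n0
    if (n1 == 0L || n0 == 0L) next
    r <- rank(scores[, j])
    out$auc[j] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    out$p[j] <- suppressWarnings(
      wilcox.test(scores[pos, j], scores[!pos, j],
                  alternative = "greater")$p.value)
  }
  out
}
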