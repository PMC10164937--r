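# Group comparisons of centroid size: one-way ANOVA, pairwise permutation
# tests with Bonferroni correction, and leave-one-out maximum-likelihood
# size-based classification.

#' Pairwise permutation tests of centroid size with Bonferroni correction
#'
#' For every pair of groups the observed statistic is the absolute
#' difference of group mean sizes; the null distribution is built by
#' permuting group labels, and the p-value uses the add-one convention
#' \eqn{p = (\#\{permuted \ge observed\} + 1) / (nPerm + 1)}, so the
#' smallest attainable p is \code{1/(nPerm + 1)}.  Significance is flagged
#' at the Bonferroni-adjusted level \code{alpha / nPairs}.  A one-way ANOVA
#' over all groups is reported alongside.  Permutations are seeded per pair
#' from \code{(seed, pair index)} so results do not depend on pair order.
#'
#' @param cs numeric vector of sizes (mm).
#' @param groups group label per element of \code{cs} (>= 2 groups, each
#'   with >= 2 members).
#' @param nPerm permutation count (default 1000).
#' @param seed integer RNG seed.
#' @param alpha nominal significance level before Bonferroni adjustment.
#' @return list of class \code{"sizeTest"}: \code{anovaF}, \code{anovaP},
#'   \code{pairwiseP} (symmetric matrix, NA diagonal), \code{significant}
#'   (logical matrix at the adjusted level), \code{bonferroniAlpha},
#'   \code{nPermutations}, \code{seed}.
#' @examples
#' cs <- c(rnorm(10, 1.4, 0.08), rnorm(10, 1.9, 0.08))
#' grp <- rep(c("a", "b"), each = 10)
#' pairwiseSizeTests(cs, grp, nPerm = 199, seed = 1)$pairwiseP
#' @export
pairwiseSizeTests <- function(cs, groups, nPerm = 1000L, seed = 1L,
                              alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(cs) == length(groups))
  labs <- unique(groups)
  g <- length(labs)
  if (g < 2L) stop("at least two groups are required")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 members")
  if (var(cs) == 0) warning("constant size values: all p-values are 1")

  fit <- anova(lm(cs ~ factor(groups)))
  pairs <- combn(labs, 2)
  nPairs <- ncol(pairs)
  P <- matrix(NA_real_, g, g, dimnames = list(labs, labs))
  for (p in seq_len(nPairs)) {
    a <- pairs[1, p]; b <- pairs[2, p]
    xa <- cs[groups == a]; xb <- cs[groups == b]
    P[a, b] <- P[b, a] <- permMeanDiffP(xa, xb, nPerm, seed + p)
  }
  badj <- alpha / nPairs
  sig <- !is.na(P) & P < badj
  structure(list(anovaF = fit$`F value`[1], anovaP = fit$`Pr(>F)`[1],
                 pairwiseP = P, significant = sig, bonferroniAlpha = badj,
                 nPermutations = as.integer(nPerm), seed = as.integer(seed)),
            class = "sizeTest")
}

# Add-one permutation p-value for |mean(xa) - mean(xb)| under label
# exchange.  Vectorized over permutations.
permMeanDiffP <- function(xa, xb, nPerm, seed) {
  x <- c(xa, xb)
  n <- length(x); n1 <- length(xa)
  obs <- abs(mean(xa) - mean(xb))
  total <- sum(x)
  withSeed(seed, {
    s1 <- vapply(seq_len(nPerm),
                 function(i) sum(x[sample.int(n, n1)]), 0)
    null <- abs(s1 / n1 - (total - s1) / (n - n1))
    (sum(null >= obs - 1e-12) + 1) / (nPerm + 1)
  })
}

#' @export
print.sizeTest <- function(x, ...) {
  cat("Pairwise size permutation tests (", x$nPermutations,
      " permutations)\n", sep = "")
  cat(sprintf("  one-way ANOVA: F = %.3f, p = %.4g\n", x$anovaF, x$anovaP))
  cat(sprintf("  Bonferroni-adjusted alpha: %.4g\n", x$bonferroniAlpha))
  print(round(x$pairwiseP, 4))
  invisible(x)
}

#' Leave-one-out maximum-likelihood classification on size
#'
#' Each specimen is held out in turn; a Normal density is fitted to every
#' group's remaining sizes (per-group mean and SD) and the specimen is
#' assigned to the group with the highest density at its size.  This is the
#' validated reclassification used to judge whether global size alone
#' separates the groups.
#'
#' @param cs numeric vector of sizes.
#' @param groups group label per specimen (>= 2 groups, each n >= 3).
#' @return list of class \code{"classification"}: \code{confusion} (true x
#'   assigned count matrix), \code{perGroupAccuracy}, \code{totalAccuracy},
#'   \code{method = "ml_size"}, \code{validation = "leave_one_out"}.
#' @examples
#' cs <- c(rnorm(20, 10, 1), rnorm(20, 30, 1))
#' mlSizeClassify(cs, rep(c("a", "b"), each = 20))$totalAccuracy
#' @export
mlSizeClassify <- function(cs, groups) {
  groups <- as.character(groups)
  labs <- unique(groups)
  if (length(labs) < 2L) stop("at least two groups are required")
  if (any(table(groups) < 3L)) stop("each group needs at least 3 members")
  n <- length(cs)
  conf <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
  for (i in seq_len(n)) {
    dens <- vapply(labs, function(gl) {
      tr <- cs[groups == gl & seq_len(n) != i]
      s <- sd(tr)
      if (!is.finite(s) || s == 0) {
        warning("zero training variance in group ", gl, "; fold skipped")
        return(NA_real_)
      }
      dnorm(cs[i], mean(tr), s)
    }, 0)
    if (all(is.na(dens))) next
    assigned <- labs[which.max(dens)]
    conf[groups[i], assigned] <- conf[groups[i], assigned] + 1L
  }
  classificationResult(conf, method = "ml_size")
}

classificationResult <- function(conf, method) {
  total <- sum(conf)
  structure(list(confusion = conf,
                 perGroupAccuracy = diag(conf) / rowSums(conf),
                 totalAccuracy = sum(diag(conf)) / total,
                 method = method, validation = "leave_one_out"),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat("Leave-one-out classification (", x$method, ")\n", sep = "")
  print(x$confusion)
  cat(sprintf("  total accuracy: %.1f%%\n", 100 * x$totalAccuracy))
  cat("  per group:",
      paste(sprintf("%s %.1f%%", names(x$perGroupAccuracy),
                    100 * x$perGroupAccuracy), collapse = ", "), "\n")
  invisible(x)
}
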