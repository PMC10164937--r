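test_that("CVA yields g-1 factors whose contributions sum to 100%", {
  set.seed(3)
  X <- rbind(matrix(rnorm(80), 20), matrix(rnorm(80, 1), 20),
             matrix(rnorm(80, -1), 20))
  g <- rep(c("a", "b", "c"), each = 20)
  r <- cva(X, g)
  expect_equal(ncol(r$scores), 2L)
  expect_equal(sum(r$contributions), 100)
  # pooled within-group covariance of DF scores is the identity
  W <- wingmorph:::pooledWithinCov(r$scores, g)
  expect_equal(unname(W), diag(2), tolerance = 1e-8)

  # identical distributions: standardized DF1 group gap near zero
  X0 <- matrix(rnorm(2 * 200 * 4), 400)
  g0 <- rep(c("a", "b"), each = 200)
  r0 <- cva(X0, g0)
  gap <- abs(diff(r0$groupMeans[, 1]))
  expect_lt(gap, 3 / sqrt(100))

  # collinear group means: DF1 carries > 99% of the contribution
  mu <- rbind(c(0, 0), c(5, 0), c(10, 0))
  Xc <- do.call(rbind, lapply(1:3, function(j)
    sweep(matrix(rnorm(60), 30), 2, mu[j, ], `+`)))
  rc <- cva(Xc, rep(c("a", "b", "c"), each = 30))
  expect_gt(rc$contributions[1], 99)
})

test_that("Mahalanobis distances match the closed form and direct inversion", {
  # univariate means 0 and 1, pooled variance 1 -> D = 1
  set.seed(10)
  x <- c(rnorm(2000), rnorm(2000, 1))
  x <- c(scale(x[1:2000]), scale(x[2001:4000]) + 1)  # exact moments
  g <- rep(c("a", "b"), each = 2000)
  r <- mahalanobisMatrix(cbind(x), g, nPerm = 9, seed = 1)
  expect_equal(r$distances["a", "b"], 1, tolerance = 1e-10)

  # small multivariate instance vs explicit-inversion oracle
  X <- matrix(rnorm(120), 30, 4)
  g3 <- rep(c("a", "b", "c"), each = 10)
  r3 <- mahalanobisMatrix(X, g3, nPerm = 9, seed = 1)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    ia <- which(g3 == pair[1]); ib <- which(g3 == pair[2])
    Xa <- X[ia, ]; Xb <- X[ib, ]
    S <- (cov(Xa) * 9 + cov(Xb) * 9) / 18
    d <- colMeans(Xa) - colMeans(Xb)
    oracle <- sqrt(as.numeric(t(d) %*% solve(S) %*% d))
    expect_equal(r3$distances[pair[1], pair[2]], oracle, tolerance = 1e-10)
  }
  expect_true(isSymmetric(r3$distances))
  expect_equal(unname(diag(r3$distances)), rep(0, 3))
})

test_that("Mahalanobis and CVA are invariant to invertible linear maps", {
  set.seed(17)
  X <- rbind(matrix(rnorm(100), 20), matrix(rnorm(100, 0.8), 20),
             matrix(rnorm(100, -0.5), 20))
  g <- rep(c("a", "b", "c"), each = 20)
  base <- mahalanobisMatrix(X, g, nPerm = 9, seed = 1)$distances
  baseC <- cva(X, g)$contributions
  for (r in 1:3) {
    A <- matrix(rnorm(25), 5) + diag(5) * 2  # well-conditioned
    Xt <- X %*% A + matrix(rnorm(5), 60, 5, byrow = TRUE)
    expect_equal(mahalanobisMatrix(Xt, g, nPerm = 9, seed = 1)$distances,
                 base, tolerance = 1e-6)
    expect_equal(cva(Xt, g)$contributions, baseC, tolerance = 1e-6)
  }
})

test_that("LOO Mahalanobis reclassification is calibrated", {
  set.seed(23)
  # well separated: perfect
  Xs <- rbind(matrix(rnorm(60, 0, 0.1), 15), matrix(rnorm(60, 3, 0.1), 15))
  gs <- rep(c("a", "b"), each = 15)
  expect_equal(crossvalReclassify(Xs, gs)$totalAccuracy, 1)

  # identical groups, g = 3: chance level
  X0 <- matrix(rnorm(3 * 120 * 3), 360, 3)
  g0 <- rep(c("a", "b", "c"), each = 120)
  r0 <- crossvalReclassify(X0, g0)
  expect_lt(abs(r0$totalAccuracy - 1 / 3), 0.07)
  expect_equal(r0$totalAccuracy, sum(diag(r0$confusion)) / sum(r0$confusion))

  # LOO does not exceed resubstitution on average (single seeded check
  # over several replicates)
  diffs <- vapply(1:10, function(r) {
    set.seed(100 + r)
    X <- rbind(matrix(rnorm(48), 12), matrix(rnorm(48, 0.5), 12))
    g <- rep(c("a", "b"), each = 12)
    loo <- crossvalReclassify(X, g)$totalAccuracy
    # resubstitution oracle
    S <- wingmorph:::pooledWithinCov(X, g)
    Si <- solve(S)
    pred <- apply(X, 1, function(z) {
      d2 <- vapply(c("a", "b"), function(gl) {
        m <- colMeans(X[g == gl, ]); as.numeric((z - m) %*% Si %*% (z - m))
      }, 0)
      names(which.min(d2))
    })
    mean(pred == g) - loo
  }, 0)
  expect_gte(mean(diffs), 0)
})

test_that("allometry r2 is exact for linear shape and null for noise", {
  set.seed(31)
  cs <- rnorm(100, 1.6, 0.1)
  r <- suppressWarnings(allometryR2(2 * cs - 1, cs))  # exact fit warns
  expect_equal(r$r2, 1)
  expect_equal(r$slope, 2)
  r0 <- allometryR2(rnorm(500), rnorm(500, 1.6, 0.1))
  expect_lt(r0$r2, 0.02)
  expect_error(allometryR2(rnorm(5), rep(1, 5)), "constant")
  # matrix input: per-DF r2
  rm <- suppressWarnings(allometryR2(cbind(2 * cs, rnorm(100)), cs))
  expect_equal(length(rm$perDfR2), 2L)
  expect_equal(rm$perDfR2[1], 1)
})

test_that("UPGMA reproduces the hand-computed case and cophenetic input", {
  D <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgmaTree(D)
  expect_equal(t3$heights, c(1, 3))
  # A and B merge first
  expect_true(all(t3$merges[1, ] < 0))

  # ultrametric input: cophenetic round trip is exact
  phy <- t3$phylo
  expect_equal(cophenetic(phy)[rownames(D), colnames(D)], D)

  set.seed(2)
  # random ultrametric matrix via a random dendrogram
  h <- hclust(dist(matrix(rnorm(40), 10)), method = "average")
  Du <- cophenetic(h)
  tu <- upgmaTree(as.matrix(Du))
  expect_equal(cophenetic(tu$phylo)[labels(Du), labels(Du)],
               as.matrix(Du)[labels(Du), labels(Du)], tolerance = 1e-10)
})

test_that("dendrogram groups the shape-similar populations together", {
  hits <- vapply(1:20, function(r) {
    d <- simulateLandmarkDataset(wingSimConfig(), seed = 400 + r)
    X <- shapeScoreMatrix(relativeWarps(gpaAlign(d)))
    mm <- mahalanobisMatrix(X, populations(d), nPerm = 3, seed = 1)
    tr <- upgmaTree(mm)
    m1 <- tr$merges[1, ]
    all(m1 < 0) &&
      setequal(rownames(mm$distances)[-m1], c("pop1", "pop3"))
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})
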