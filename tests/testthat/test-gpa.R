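test_that("centroid size matches hand computation and scaling laws", {
  sq <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), ncol = 2, byrow = TRUE)
  expect_equal(centroidSize(sq), sqrt(8))
  # translation invariance, homogeneity
  expect_equal(centroidSize(sweep(sq, 2, c(-5, 3))), sqrt(8))
  expect_equal(centroidSize(sq * 2.5), 2.5 * sqrt(8))
  expect_error(centroidSize(matrix(1, 4, 2)), "degenerate")
})

test_that("GPA recovers a shape from its similarity-transformed copies", {
  set.seed(21)
  copies <- lapply(1:10, function(i) randomSimilarity(triangleFix))
  d <- WingDataset(copies, data.frame(id = paste0("s", 1:10),
                                      population = "p"))
  fit <- gpaAlign(d)
  expect_true(fit@converged)
  expect_lt(max(abs(residualCoords(fit))), 1e-8)
  expect_lt(procrustesDistance(consensusShape(fit), triangleFix), 1e-8)
  # residuals sum to the zero configuration
  expect_lt(max(abs(apply(residualCoords(fit), c(1, 2), sum))), 1e-9)
})

test_that("reflected shapes are not aligned away (rotations only)", {
  mirror <- triangleFix %*% diag(c(-1, 1))
  d <- WingDataset(list(triangleFix, mirror),
                   data.frame(id = c("a", "b"), population = "p"))
  fit <- gpaAlign(d)
  expect_gt(sum(residualCoords(fit)^2), 0.01)
})

test_that("pairwise optimal rotation matches a brute-force grid search", {
  set.seed(8)
  for (r in 1:5) {
    A <- wingmorph:::centerConfig(matrix(rnorm(6), 3, 2))
    A <- A / sqrt(sum(A^2))
    B <- wingmorph:::centerConfig(randomSimilarity(matrix(rnorm(6), 3, 2)))
    B <- B / sqrt(sum(B^2))
    R <- wingmorph:::optimalRotation(A, B)
    angBest <- gridSearchRotation(A, B)
    angClosed <- atan2(R[1, 2], R[1, 1]) %% (2 * pi)
    dAng <- min(abs(angClosed - angBest), 2 * pi - abs(angClosed - angBest))
    expect_lt(dAng, 1e-3)
  }
})

test_that("GPA sum of squares beats single-reference superimposition", {
  d <- simulateLandmarkDataset(wingSimConfig(nPerGroup = c(6, 6, 6)),
                               seed = 14)
  fit <- gpaAlign(d)
  gpaSS <- sum(residualCoords(fit)^2)
  expect_lte(gpaSS, singleReferenceSS(d) + 1e-10)
})

test_that("GPA shape variables are invariant to input position and order", {
  set.seed(31)
  d <- simulateLandmarkDataset(wingSimConfig(nPerGroup = c(5, 5, 5)),
                               seed = 4)
  arr <- landmarkCoords(d)
  moved <- lapply(seq_len(dim(arr)[3]), function(i)
    randomSimilarity(arr[, , i], scl = 1))  # rotate + translate only
  dMoved <- WingDataset(moved, specimenTable(d))
  f1 <- gpaAlign(d); f2 <- gpaAlign(dMoved)
  expect_equal(centroidSizes(f2), centroidSizes(f1), tolerance = 1e-9)
  # pairwise aligned distances agree (output fixed up to global rotation)
  pd1 <- dist(t(apply(f1@aligned, 3, wingmorph:::flattenConfig)))
  pd2 <- dist(t(apply(f2@aligned, 3, wingmorph:::flattenConfig)))
  expect_equal(as.vector(pd2), as.vector(pd1), tolerance = 1e-7)
  # specimen order: permuting input permutes output consistently
  perm <- sample(nSpecimens(d))
  dPerm <- WingDataset(lapply(perm, function(i) arr[, , i]),
                       specimenTable(d)[perm, ])
  f3 <- gpaAlign(dPerm)
  pd3 <- as.matrix(dist(t(apply(f3@aligned, 3, wingmorph:::flattenConfig))))
  ids <- specimenIds(d)
  expect_equal(pd3[ids, ids], as.matrix(pd1)[ids, ids], tolerance = 1e-7)
  # CS scales linearly with input scale
  dBig <- WingDataset(lapply(seq_len(dim(arr)[3]), function(i) arr[, , i] * 3),
                      specimenTable(d))
  expect_equal(unname(centroidSize(dBig)), unname(3 * centroidSize(d)))
})

test_that("relative warps are an isometric coordinate change of residuals", {
  d <- simulateLandmarkDataset(wingSimConfig(nPerGroup = c(8, 8, 8)),
                               seed = 12)
  fit <- gpaAlign(d)
  rw <- relativeWarps(fit)
  expect_equal(sum(explainedVariance(rw)), 1, tolerance = 1e-9)
  ev <- explainedVariance(rw)
  expect_true(all(diff(ev) <= 1e-12))
  # score-space distances equal aligned-coordinate distances (full rank)
  dScores <- dist(shapeScoreMatrix(rw))
  dCoords <- dist(t(apply(fit@aligned, 3, wingmorph:::flattenConfig)))
  expect_equal(as.vector(dScores), as.vector(dCoords), tolerance = 1e-9)
  # scores are centred
  expect_lt(max(abs(colMeans(shapeScoreMatrix(rw)))), 1e-10)

  # noise-free copies: all eigenvalues ~ 0
  copies <- lapply(1:6, function(i) randomSimilarity(triangleFix))
  d0 <- WingDataset(copies, data.frame(id = paste0("s", 1:6),
                                       population = "p"))
  rw0 <- relativeWarps(gpaAlign(d0))
  expect_lt(max(rw0@scores^2), 1e-14)

  expect_warning(relativeWarps(fit, nAxes = 1000), "rank")
})
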