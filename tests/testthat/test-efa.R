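test_that("arc-length resampling spaces points equally and fixes orientation", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  r8 <- resampleContour(sq, 8)
  gaps <- sqrt(rowSums((r8[c(2:8, 1), ] - r8)^2))
  expect_equal(gaps, rep(0.5, 8))
  expect_equal(r8[1, ], sq[1, ])  # starts at the anchor point

  # perimeter preserved at refining density: exactly when samples land on
  # vertices (square), to O(1/m^2) corner-cutting on a smooth blob
  sq64 <- resampleContour(sq, 64)
  expect_equal(wingmorph:::polygonPerimeter(sq64), 4, tolerance = 1e-12)
  blob <- resampleContour(blobContour(100), 100)
  p0 <- wingmorph:::polygonPerimeter(blob)
  expect_equal(wingmorph:::polygonPerimeter(resampleContour(blob, 400)), p0,
               tolerance = 1e-4)

  # clockwise input is reversed to counter-clockwise
  cw <- sq[c(1, 4, 3, 2), ]
  rcw <- resampleContour(cw, 16)
  expect_gt(wingmorph:::signedArea(rcw), 0)
  expect_equal(rcw[1, ], cw[1, ])
})

test_that("a circle decomposes into a single harmonic with its radius", {
  th <- seq(0, 2 * pi, length.out = 513)[-513]
  r <- 2.5
  circ <- cbind(-1 + r * cos(th), 4 + r * sin(th))
  cf <- efaDecompose(circ, H = 8, normalize = FALSE)
  h <- harmonicMatrix(cf)
  expect_equal(unname(h[1, c("a", "d")]), c(r, r), tolerance = 1e-4)
  expect_lt(max(abs(h[1, c("b", "c")])), 1e-6 * r)
  expect_lt(max(abs(h[-1, ])), 1e-6 * r)
  expect_equal(unname(cf@dc), c(-1, 4), tolerance = 1e-6)

  sz <- outlineSizeMeasures(circ)
  expect_equal(sz$sqrtArea, sqrt(pi) * r, tolerance = 1e-4)
  expect_equal(sz$perimeter, 2 * pi * r, tolerance = 1e-4)
  expect_equal(sz$semiMajor1, r, tolerance = 1e-4)
})

test_that("raw coefficients match an independent FFT oracle", {
  pts <- resampleContour(blobContour(128), 512)
  cf <- harmonicMatrix(efaDecompose(pts, H = 5, normalize = FALSE))
  # oracle: DFT of the equally spaced x(t), y(t) series
  fx <- stats::fft(pts[, 1]) / nrow(pts)
  fy <- stats::fft(pts[, 2]) / nrow(pts)
  oracle <- cbind(a = 2 * Re(fx[2:6]), b = -2 * Im(fx[2:6]),
                  c = 2 * Re(fy[2:6]), d = -2 * Im(fy[2:6]))
  expect_lt(max(abs(cf - oracle)), 5e-3)
})

test_that("normalized coefficients are similarity and start-point invariant", {
  set.seed(77)
  rp <- resampleContour(blobContour(128), 256)
  base <- harmonicMatrix(efaDecompose(rp, H = 7))
  for (rep in 1:10) {
    tp <- randomSimilarity(rp)
    sh <- sample(nrow(tp), 1)
    tp <- tp[c(sh:nrow(tp), seq_len(sh - 1))[seq_len(nrow(tp))], , drop = FALSE]
    tr <- harmonicMatrix(efaDecompose(tp, H = 7))
    expect_lt(max(abs(base - tr)), 1e-6)
  }
  expect_equal(unname(base[1, "a"]), 1)
  expect_equal(unname(base[1, c("b", "c")]), c(0, 0))
})

test_that("outline sizes scale homogeneously and respect the isoperimetric bound", {
  blob <- resampleContour(blobContour(96), 192)
  s1 <- outlineSizeMeasures(blob)
  s3 <- outlineSizeMeasures(blob * 3)
  expect_equal(s3$sqrtArea, 3 * s1$sqrtArea)
  expect_equal(s3$perimeter, 3 * s1$perimeter)
  expect_equal(s3$semiMajor1, 3 * s1$semiMajor1)
  expect_gte(s1$perimeter^2, 4 * pi * s1$sqrtArea^2)

  # unit square closed form
  sq <- resampleContour(matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2,
                               byrow = TRUE), 64)
  ssq <- outlineSizeMeasures(sq)
  expect_equal(ssq$sqrtArea, 1)
  expect_equal(ssq$perimeter, 4)

  # 2:1 ellipse: semi-major between the semi-axes, aspect ordering kept
  th <- seq(0, 2 * pi, length.out = 257)[-257]
  ell <- cbind(2 * cos(th), sin(th))
  se <- outlineSizeMeasures(resampleContour(ell, 512))
  expect_gt(se$semiMajor1, 1)
  expect_lt(se$semiMajor1, 2)
})

test_that("reconstruction error shrinks monotonically with harmonics", {
  pts <- resampleContour(blobContour(128), 256)
  rmse <- function(H) {
    cf <- efaDecompose(pts, H = H, normalize = FALSE)
    rec <- reconstructContour(cf, nrow(pts))
    sqrt(mean((rec - pts)^2))
  }
  e2 <- rmse(2); e8 <- rmse(8); e32 <- rmse(32)
  expect_gte(e2, e8)
  expect_gte(e8, e32)
  # near-Nyquist round trip: coefficients are exact Fourier integrals of
  # the polygon, so truncation at m/2 leaves only the tiny O(1/H^2) tail
  e128 <- rmse(128)
  expect_lt(e128, 1e-3)
  expect_lt(e128, e32)
  # circle at H = 1 reproduces its 128-gon to polygonal accuracy
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  circ <- cbind(cos(th), sin(th))
  cfc <- efaDecompose(circ, H = 1, normalize = FALSE)
  expect_lt(max(abs(reconstructContour(cfc, 128) - circ)), 1e-3)

  expect_error(efaDecompose(pts, H = 200), "aliasing")
})

test_that("EFA feature matrix drops the fixed coefficients and keeps size", {
  o <- simulateOutlineDataset(outlineSimConfig(nPerGroup = c(4, 4, 4)),
                              seed = 8)
  f <- efaFeatures(o, H = 7)
  expect_equal(dim(f), c(12L, 25L))
  expect_equal(colnames(f)[1:5], c("d1", "a2", "b2", "c2", "d2"))
  expect_true(all(attr(f, "sizes") > 0))
})
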