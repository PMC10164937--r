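# Shared fixtures and independent oracles used across test files.

# Random similarity transform (rotation + scale + translation) of a k x 2
# configuration.  Never reflects.
randomSimilarity <- function(pts, rot = runif(1, 0, 2 * pi),
                             scl = runif(1, 0.2, 5),
                             shift = runif(2, -10, 10)) {
  R <- matrix(c(cos(rot), -sin(rot), sin(rot), cos(rot)), 2, 2)
  pts %*% R * scl + matrix(shift, nrow(pts), 2, byrow = TRUE)
}

# Small irregular triangle / polygon fixtures.
triangleFix <- matrix(c(0, 0, 3, 0.2, 1, 2), ncol = 2, byrow = TRUE)

# Brute-force best rotation angle aligning unit-size centred A onto B by
# grid search (oracle for the closed-form SVD rotation).
gridSearchRotation <- function(A, B, step = 1e-4) {
  angles <- seq(0, 2 * pi, by = step)
  err <- vapply(angles, function(t) {
    R <- matrix(c(cos(t), -sin(t), sin(t), cos(t)), 2, 2)
    sum((A %*% R - B)^2)
  }, 0)
  angles[which.min(err)]
}

# Ordinary (single-reference) superimposition: align everything onto the
# first configuration only; its total sum of squares upper-bounds the GPA
# optimum.
singleReferenceSS <- function(dataset) {
  arr <- landmarkCoords(dataset)
  n <- dim(arr)[3]
  ref <- wingmorph:::centerConfig(arr[, , 1])
  ref <- ref / sqrt(sum(ref^2))
  aligned <- lapply(seq_len(n), function(i) {
    A <- wingmorph:::centerConfig(arr[, , i])
    A <- A / sqrt(sum(A^2))
    A %*% wingmorph:::optimalRotation(A, ref)
  })
  cons <- Reduce(`+`, aligned) / n
  sum(vapply(aligned, function(a) sum((a - cons)^2), 0))
}

# Brute-force Kennard-Stone oracle for small n: checks the greedy max-min
# property at every step.
ksGreedyOk <- function(X, split) {
  keep <- apply(X, 2, sd) > 0
  D <- as.matrix(dist(scale(X[, keep, drop = FALSE])))
  sel <- split$train
  if (max(D) - D[sel[1], sel[2]] > 1e-12) return(FALSE)
  for (s in seq_along(sel))
    if (s > 2) {
      prev <- sel[seq_len(s - 1)]
      rest <- setdiff(seq_len(nrow(X)), prev)
      minD <- vapply(rest, function(r) min(D[r, prev]), 0)
      if (min(D[sel[s], prev]) < max(minD) - 1e-12) return(FALSE)
    }
  TRUE
}

# Site-counting K2P oracle for a pair of character vectors.
k2pOracle <- function(a, b) {
  good <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[good]; b <- b[good]
  ts <- sum((a == "A" & b == "G") | (a == "G" & b == "A") |
              (a == "C" & b == "T") | (a == "T" & b == "C"))
  tv <- sum(a != b) - ts
  P <- ts / length(a); Q <- tv / length(a)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

# Closed smooth test contour (polygonal, counter-clockwise).
blobContour <- function(m = 128, a = 1, b = 0.6) {
  th <- seq(0, 2 * pi, length.out = m + 1)[-(m + 1)]
  cbind(a * (1 + 0.2 * cos(3 * th)) * cos(th),
        b * (1 + 0.15 * sin(2 * th)) * sin(th))
}

# Is `tips` a clade of the (possibly unrooted) tree?
isClade <- function(phy, tips) {
  other <- setdiff(phy$tip.label, tips)
  rooted <- ape::root(phy, outgroup = other[1], resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}
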