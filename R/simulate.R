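# Synthetic wing and barcode generators.  Defaults mirror a three-population
# study design: ~20 wings per population, 11 landmarks, population centroid
# sizes 1.363 +/- 0.074, 1.887 +/- 0.096 and 1.6 +/- 0.08 mm (population 2
# largest, population 1 smallest), populations 1 and 3 shape-similar with
# population 2 divergent, and Cox1-like 401-bp sequences under the K2P model.

# Reference 11-landmark wing template (arbitrary units; centred and scaled
# to unit centroid size below).  Landmark numbering follows the standard
# Culicoides wing scheme: 1-4 around the basal cells, 5-7 along the anterior
# margin, 8-10 around cell m4, 11 at the wing tip.
wingTemplateRaw <- matrix(c(
  0.20,  0.10,
  0.45,  0.17,
  0.38, -0.02,
  0.05,  0.00,
  0.85,  0.20,
  1.00,  0.08,
  1.35,  0.14,
  0.70, -0.18,
  1.10, -0.16,
  0.93, -0.26,
  1.60,  0.00), ncol = 2, byrow = TRUE)

# Unit-size, centred template.
wingTemplate <- function(k = 11L) {
  if (k == 11L) tmpl <- wingTemplateRaw
  else {
    th <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
    tmpl <- cbind(cos(th), 0.5 * sin(th))
  }
  tmpl <- centerConfig(tmpl)
  tmpl / sqrt(sum(tmpl^2))
}

# A fixed displacement field supported on the given landmarks, orthogonalized
# against translation and the template direction and scaled to unit norm, so
# group divergence magnitudes are comparable across fields.
displacementField <- function(template, landmarks, pattern) {
  k <- nrow(template)
  D <- matrix(0, k, 2)
  D[landmarks, ] <- pattern
  D <- centerConfig(D)
  tv <- as.vector(template) / sqrt(sum(template^2))
  D <- D - sum(as.vector(D) * tv) * matrix(tv, k, 2)
  D / sqrt(sum(D^2))
}

defaultShapeFields <- function(template) {
  k <- nrow(template)
  lm <- if (k == 11L) c(3L, 4L, 5L, 7L, 8L, 9L, 10L, 11L) else seq_len(min(8L, k))
  p <- length(lm)
  # Deterministic, distinct patterns: outward y-displacements for the
  # divergent population, an oblique pattern for population 3.
  pat2 <- cbind(rep(0, p), rep(c(1, -1), length.out = p))
  pat3 <- cbind(rep(c(1, -1), length.out = p), rep(c(-0.5, 0.5), length.out = p))
  patA <- cbind(seq(-1, 1, length.out = p), rep(c(0.5, -0.5), length.out = p))
  list(g2 = displacementField(template, lm, pat2),
       g3 = displacementField(template, lm, pat3),
       allometry = displacementField(template, lm, patA))
}

#' Configuration for the synthetic landmark/outline generators
#'
#' Defaults encode the emulated study design: three populations of 20, 22
#' and 23 wings; 11 landmarks; centroid size Normal(1.363, 0.074),
#' Normal(1.887, 0.096) and Normal(1.6, 0.08) mm so population 2 has the
#' largest and population 1 the smallest wings; populations 1 and 3
#' shape-similar and population 2 divergent; a linear allometric shape
#' displacement; isotropic Gaussian landmark noise.
#'
#' @param nPerGroup integer vector of group sizes (each >= 3).
#' @param k landmark count (>= 3).
#' @param groupNames character labels, one per group.
#' @param csMean,csSd per-group centroid-size mean and SD in mm (SD >= 0).
#' @param shapeDivergence per-group magnitude (shape units, i.e. fractions
#'   of unit centroid size) of the fixed displacement field separating the
#'   group mean shape from the base template.
#' @param allometricSlope shape displacement per mm of centroid-size
#'   deviation from the group mean, applied along a fixed field.
#' @param noiseSd isotropic Gaussian landmark noise SD in shape units.
#' @param outlinePoints points per simulated contour.
#' @param outlineAspect per-group minor/major aspect ratio of the template
#'   cell outline.
#' @param outlineBump per-group amplitude of the fixed third-order radial
#'   modulation of the template outline.
#' @return a list of class \code{"wingSimConfig"}.
#' @seealso [simulateLandmarkDataset()], [simulateOutlineDataset()]
#' @export
wingSimConfig <- function(nPerGroup = c(20L, 22L, 23L),
                          k = 11L,
                          groupNames = paste0("pop", seq_along(nPerGroup)),
                          csMean = c(1.363, 1.887, 1.6),
                          csSd = c(0.074, 0.096, 0.08),
                          shapeDivergence = c(0, 0.05, 0.02),
                          allometricSlope = 0.125,
                          noiseSd = 0.01,
                          outlinePoints = 120L,
                          outlineAspect = c(0.55, 0.72, 0.58),
                          outlineBump = c(0.03, 0.08, 0.035)) {
  g <- length(nPerGroup)
  stopifnot(g >= 1, all(nPerGroup >= 3), k >= 3,
            length(groupNames) == g, length(csMean) == g,
            length(csSd) == g, all(csSd >= 0), all(csMean > 0),
            length(shapeDivergence) == g, all(shapeDivergence >= 0),
            noiseSd >= 0, outlinePoints >= 8)
  structure(list(nPerGroup = as.integer(nPerGroup), k = as.integer(k),
                 groupNames = groupNames, csMean = csMean, csSd = csSd,
                 shapeDivergence = shapeDivergence,
                 allometricSlope = allometricSlope, noiseSd = noiseSd,
                 outlinePoints = as.integer(outlinePoints),
                 outlineAspect = rep_len(outlineAspect, g),
                 outlineBump = rep_len(outlineBump, g)),
            class = "wingSimConfig")
}

#' Simulate a landmark dataset
#'
#' Each wing is built as: group mean shape (base template plus the group's
#' divergence displacement), plus an allometric displacement proportional to
#' the wing's centroid-size deviation from its group mean, plus i.i.d.
#' isotropic Gaussian landmark noise; the shape is then scaled to a centroid
#' size drawn from the group's Normal size distribution and randomly rotated
#' and translated.  Reproducible from \code{seed}.
#'
#' @param config a [wingSimConfig()] list.
#' @param seed integer RNG seed.
#' @return A [WingDataset-class].
#' @examples
#' d <- simulateLandmarkDataset(wingSimConfig(nPerGroup = c(5, 5, 5)), seed = 7)
#' tapply(centroidSize(d), populations(d), mean)
#' @export
simulateLandmarkDataset <- function(config = wingSimConfig(), seed = 1L) {
  stopifnot(inherits(config, "wingSimConfig"))
  tmpl <- wingTemplate(config$k)
  if (centroidSize(tmpl) == 0) stop("degenerate template")
  fields <- defaultShapeFields(tmpl)
  g <- length(config$nPerGroup)
  groupShape <- vector("list", g)
  for (j in seq_len(g)) {
    field <- switch(((j - 1L) %% 3L) + 1L,
                    matrix(0, config$k, 2), fields$g2, fields$g3)
    groupShape[[j]] <- tmpl + config$shapeDivergence[j] * field
  }
  withSeed(seed, {
    confs <- list(); ids <- character(); pops <- character()
    idx <- 0L
    for (j in seq_len(g)) {
      for (i in seq_len(config$nPerGroup[j])) {
        idx <- idx + 1L
        cs <- rnorm(1, config$csMean[j], config$csSd[j])
        if (cs <= 0) cs <- config$csMean[j]
        shape <- groupShape[[j]] +
          config$allometricSlope * (cs - config$csMean[j]) * fields$allometry +
          matrix(rnorm(2 * config$k, 0, config$noiseSd), config$k, 2)
        shape <- centerConfig(shape)
        shape <- shape * (cs / sqrt(sum(shape^2)))
        ang <- runif(1, 0, 2 * pi)
        R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
        shape <- shape %*% R +
          matrix(runif(2, -5, 5), config$k, 2, byrow = TRUE)
        confs[[idx]] <- shape
        ids[idx] <- sprintf("%s_%03d", config$groupNames[j], i)
        pops[idx] <- config$groupNames[j]
      }
    }
    WingDataset(confs, data.frame(id = ids, population = pops))
  })
}

# Group template outline: ellipse of unit semi-major axis with aspect b and
# a fixed low-order radial bump, evaluated at m parameter values.
outlineTemplate <- function(m, aspect, bump, phase = 0) {
  th <- 2 * pi * (seq_len(m) - 1) / m
  r <- 1 + bump * cos(3 * th + phase)
  cbind(r * cos(th), aspect * r * sin(th))
}

#' Simulate an outline dataset
#'
#' Per-group template contours are smooth radial perturbations of an
#' ellipse (populations 1 and 3 similar, population 2 divergent in aspect
#' ratio and modulation).  Each specimen adds low-frequency Gaussian radial
#' noise, is scaled so the first-harmonic semi-major axis equals a size
#' drawn from the group Normal distribution, and is randomly rotated and
#' translated.  Contours are counter-clockwise and start at the anchor
#' point.  Specimens whose perturbed radius would collapse (r <= 0) are
#' redrawn; generation fails after 20 attempts.
#'
#' @param config a [wingSimConfig()]; \code{csMean}/\code{csSd} are
#'   interpreted as the outline semi-major-axis size distribution (mm).
#' @param seed integer RNG seed.
#' @param outlineSet \code{"outlines1"}, \code{"outlines2"} or
#'   \code{"custom"} (metadata only).
#' @return An [OutlineDataset-class].
#' @export
simulateOutlineDataset <- function(config = outlineSimConfig(), seed = 1L,
                                   outlineSet = "outlines1") {
  stopifnot(inherits(config, "wingSimConfig"))
  g <- length(config$nPerGroup)
  m <- config$outlinePoints
  withSeed(seed, {
    contours <- list(); ids <- character(); pops <- character()
    idx <- 0L
    for (j in seq_len(g)) {
      tmpl <- outlineTemplate(m, config$outlineAspect[j], config$outlineBump[j],
                              phase = if ((j - 1L) %% 3L == 1L) pi / 2 else 0)
      for (i in seq_len(config$nPerGroup[j])) {
        idx <- idx + 1L
        ok <- FALSE
        for (attempt in 1:20) {
          th <- 2 * pi * (seq_len(m) - 1) / m
          pert <- rep(0, m)
          if (config$noiseSd > 0)
            for (f in 2:5)
              pert <- pert + rnorm(1, 0, config$noiseSd) * cos(f * th) +
                rnorm(1, 0, config$noiseSd) * sin(f * th)
          if (all(1 + pert > 0.05)) { ok <- TRUE; break }
        }
        if (!ok) stop("could not generate a simple contour after 20 attempts")
        pts <- tmpl * (1 + pert)
        size <- rnorm(1, config$csMean[j], config$csSd[j])
        if (size <= 0) size <- config$csMean[j]
        s0 <- outlineSizeMeasures(pts)$semiMajor1
        pts <- pts * (size / s0)
        ang <- runif(1, 0, 2 * pi)
        R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
        pts <- pts %*% R + matrix(runif(2, -5, 5), m, 2, byrow = TRUE)
        contours[[idx]] <- pts
        ids[idx] <- sprintf("%s_%03d", config$groupNames[j], i)
        pops[idx] <- config$groupNames[j]
      }
    }
    OutlineDataset(contours, data.frame(id = ids, population = pops),
                   anchorLandmarks = if (outlineSet == "outlines1") 1:4
                   else if (outlineSet == "outlines2") 8:10 else integer(),
                   outlineSet = outlineSet)
  })
}

#' Outline generator configuration with wing-cell size defaults
#'
#' Same structure as [wingSimConfig()] but with size moments matching a
#' small wing cell (semi-major axis 0.161 +/- 0.014, 0.227 +/- 0.012 and
#' 0.19 +/- 0.013 mm for the three populations).
#'
#' @param ... overrides passed to [wingSimConfig()].
#' @return a \code{"wingSimConfig"} list.
#' @export
outlineSimConfig <- function(...) {
  args <- list(...)
  defaults <- list(csMean = c(0.161, 0.227, 0.19),
                   csSd = c(0.014, 0.012, 0.013))
  for (nm in names(defaults))
    if (is.null(args[[nm]])) args[[nm]] <- defaults[[nm]]
  do.call(wingSimConfig, args)
}

#' Configuration for the K2P sequence simulator
#'
#' @param groupSizes integer vector of sequences per population.
#' @param groupNames labels, one per population.
#' @param length alignment length in bp (default 401).
#' @param withinDivergence expected within-population K2P distance; scalar
#'   or one value per population.
#' @param betweenDivergence expected between-population K2P distance;
#'   scalar or a symmetric g x g matrix.
#' @param tsTvRatio transition/transversion ratio R = ts/tv.
#' @return a list of class \code{"seqSimConfig"}.
#' @export
seqSimConfig <- function(groupSizes = c(10L, 10L, 10L),
                         groupNames = paste0("pop", seq_along(groupSizes)),
                         length = 401L,
                         withinDivergence = 0.005,
                         betweenDivergence = 0.025,
                         tsTvRatio = 2) {
  g <- length(groupSizes)
  stopifnot(g >= 1, all(groupSizes >= 1), length >= 1,
            all(withinDivergence >= 0), all(betweenDivergence >= 0),
            tsTvRatio > 0)
  if (is.matrix(betweenDivergence))
    stopifnot(nrow(betweenDivergence) == g, isSymmetric(betweenDivergence))
  structure(list(groupSizes = as.integer(groupSizes),
                 groupNames = groupNames, length = as.integer(length),
                 withinDivergence = rep_len(withinDivergence, g),
                 betweenDivergence = betweenDivergence,
                 tsTvRatio = tsTvRatio),
            class = "seqSimConfig")
}

# K2P substitution probabilities after evolutionary distance d (expected
# substitutions/site) with ts/tv ratio R: returns P(transition) and
# P(each specific transversion).
k2pSiteProbs <- function(d, R) {
  bt <- d / (2 * (R + 1))   # beta * t
  at <- d * R / (R + 1)     # alpha * t
  pTs <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  pTvEach <- 0.25 - 0.25 * exp(-4 * bt)
  c(ts = pTs, tv = pTvEach)
}

NUC <- c("A", "C", "G", "T")
transitionOf <- c(A = "G", G = "A", C = "T", T = "C")
transversionsOf <- list(A = c("C", "T"), G = c("C", "T"),
                        C = c("A", "G"), T = c("A", "G"))

# Evolve a nucleotide vector over branch length d under K2P.
evolveK2P <- function(seq, d, R) {
  if (d <= 0) return(seq)
  p <- k2pSiteProbs(d, R)
  n <- length(seq)
  u <- runif(n)
  out <- seq
  ts <- u < p["ts"]
  tv1 <- !ts & u < p["ts"] + p["tv"]
  tv2 <- !ts & !tv1 & u < p["ts"] + 2 * p["tv"]
  out[ts] <- transitionOf[seq[ts]]
  out[tv1] <- vapply(seq[tv1], function(b) transversionsOf[[b]][1], "")
  out[tv2] <- vapply(seq[tv2], function(b) transversionsOf[[b]][2], "")
  out
}

#' Simulate population-structured sequences under the K2P model
#'
#' Sequences evolve on a star phylogeny: a random root sequence, one
#' ancestor per population at a root distance chosen so expected pairwise
#' between-population K2P distances match \code{betweenDivergence}, and
#' tips at half the within-population divergence from their ancestor.
#' Substitutions are i.i.d. per site with the configured
#' transition/transversion ratio.  K2P distances are additive in
#' expectation along branches, so the estimator applied to the output
#' recovers the configured divergences.
#'
#' @param config a [seqSimConfig()].
#' @param seed integer RNG seed.
#' @return A [BarcodeSet-class] of aligned sequences.
#' @examples
#' bs <- simulateK2PSequences(seqSimConfig(groupSizes = c(4, 4)), seed = 3)
#' groupDistanceSummary(bs, nBoot = 20, seed = 1)$barcodeGapPercent
#' @export
simulateK2PSequences <- function(config = seqSimConfig(), seed = 1L) {
  stopifnot(inherits(config, "seqSimConfig"))
  g <- length(config$groupSizes)
  R <- config$tsTvRatio
  B <- config$betweenDivergence
  if (!is.matrix(B)) B <- matrix(B, g, g)
  diag(B) <- 0
  if (any(B[upper.tri(B)] >= 0.7))
    stop("requested between-group divergence approaches K2P saturation")
  w <- config$withinDivergence
  # Root-to-ancestor branch lengths r_j solving d(j,h) ~ r_j + r_h, then
  # reduced by the tip half-branches (clamped at zero).
  if (g == 1L) r <- 0
  else if (g == 2L) r <- rep(B[1, 2] / 2, 2)
  else {
    A <- matrix(0, g * (g - 1) / 2, g)
    b <- numeric(nrow(A))
    row <- 0L
    for (j in seq_len(g - 1)) for (h in (j + 1):g) {
      row <- row + 1L
      A[row, c(j, h)] <- 1
      b[row] <- B[j, h]
    }
    r <- as.vector(qr.solve(A, b))
  }
  r <- pmax(r - w / 2, 0)
  withSeed(seed, {
    root <- sample(NUC, config$length, replace = TRUE)
    seqs <- character(sum(config$groupSizes))
    pops <- character(length(seqs))
    ids <- character(length(seqs))
    idx <- 0L
    for (j in seq_len(g)) {
      anc <- evolveK2P(root, r[j], R)
      for (i in seq_len(config$groupSizes[j])) {
        idx <- idx + 1L
        tip <- evolveK2P(anc, w[j] / 2, R)
        seqs[idx] <- paste(tip, collapse = "")
        ids[idx] <- sprintf("%s_%03d", config$groupNames[j], i)
        pops[idx] <- config$groupNames[j]
      }
    }
    names(seqs) <- ids
    BarcodeSet(seqs, pops)
  })
}
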