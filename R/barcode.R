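# Cox1 barcode analysis: Kimura two-parameter distances with pairwise
# deletion, within/between-population summaries with site-bootstrap
# standard errors, barcode gap, and neighbor-joining trees with bootstrap
# support.

# Character matrix (n x L) from a BarcodeSet; ambiguity codes other than
# the four bases and '-' are treated as 'N'.
barcodeMatrix <- function(x) {
  stopifnot(is(x, "BarcodeSet"))
  if (!isAligned(x)) stop("sequences must be aligned (equal lengths)")
  m <- do.call(rbind, strsplit(toupper(as.character(x@sequences)), ""))
  rownames(m) <- names(x@sequences)
  m[!m %in% c("A", "C", "G", "T", "-")] <- "N"
  m
}

# Transition/transversion/comparable counts for two base vectors.
pairSiteCounts <- function(a, b) {
  ok <- a %in% NUC & b %in% NUC
  a <- a[ok]; b <- b[ok]
  diffs <- a != b
  purine <- c("A", "G")
  isTs <- diffs & ((a %in% purine) == (b %in% purine))
  c(sites = sum(ok), ts = sum(isTs), tv = sum(diffs & !isTs))
}

k2pFromCounts <- function(sites, ts, tv) {
  if (sites == 0) return(NA_real_)
  P <- ts / sites; Q <- tv / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)  # saturated
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' With P and Q the transition and transversion proportions over the
#' comparable sites (pairwise deletion of positions where either sequence
#' has a gap or N), the distance is
#' \eqn{d = -\frac{1}{2}\ln(1 - 2P - Q) - \frac{1}{4}\ln(1 - 2Q)}.
#'
#' @param a,b nucleotide strings (or DNAString) of equal length.
#' @return list with \code{distance} and \code{comparableSites}.  Saturated
#'   pairs (non-positive log argument) or pairs with no comparable sites
#'   raise an error.
#' @examples
#' a <- paste(rep("A", 100), collapse = "")
#' b <- paste(c(rep("G", 10), rep("A", 90)), collapse = "")
#' k2pDistance(a, b)$distance  # -log(0.8)/2
#' @export
k2pDistance <- function(a, b) {
  av <- strsplit(toupper(as.character(a)), "")[[1]]
  bv <- strsplit(toupper(as.character(b)), "")[[1]]
  if (length(av) != length(bv)) stop("sequences must have equal length")
  cnt <- pairSiteCounts(av, bv)
  if (cnt["sites"] == 0) stop("no comparable sites between the sequences")
  d <- k2pFromCounts(cnt["sites"], cnt["ts"], cnt["tv"])
  if (is.na(d)) stop("K2P distance undefined: substitution saturation")
  list(distance = unname(d), comparableSites = unname(cnt["sites"]))
}

#' Pairwise K2P distance matrix for a BarcodeSet
#'
#' @param x a [BarcodeSet-class] of aligned sequences.
#' @return list of class \code{"k2pMatrix"}: \code{distances} (symmetric,
#'   zero diagonal; NA marks saturated pairs), \code{comparableSites},
#'   \code{saturatedPairs} (two-column id matrix, possibly empty).
#' @export
k2pMatrix <- function(x) {
  m <- barcodeMatrix(x)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  CS <- matrix(0L, n, n, dimnames = dimnames(D))
  sat <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cnt <- pairSiteCounts(m[i, ], m[j, ])
    d <- k2pFromCounts(cnt["sites"], cnt["ts"], cnt["tv"])
    if (is.na(d)) sat <- rbind(sat, c(rownames(m)[i], rownames(m)[j]))
    D[i, j] <- D[j, i] <- unname(d)
    CS[i, j] <- CS[j, i] <- as.integer(cnt["sites"])
  }
  structure(list(distances = D, comparableSites = CS,
                 saturatedPairs = sat, population = populations(x)),
            class = "k2pMatrix")
}

#' @export
print.k2pMatrix <- function(x, ...) {
  cat("K2P distance matrix over", nrow(x$distances), "sequences\n")
  cat(sprintf("  range: %.4g - %.4g\n",
              min(x$distances[upper.tri(x$distances)], na.rm = TRUE),
              max(x$distances[upper.tri(x$distances)], na.rm = TRUE)))
  if (!is.null(x$saturatedPairs))
    cat("  saturated pairs:", nrow(x$saturatedPairs), "\n")
  invisible(x)
}

#' Within/between-population K2P summary and barcode gap
#'
#' Within-population means are taken over all intra-population sequence
#' pairs and between-population means over all cross pairs; standard
#' errors come from a seeded bootstrap over alignment sites.  The barcode
#' gap is the smallest between-population mean minus the largest
#' within-population mean (also expressed in percent).  Populations with a
#' single sequence have no within mean and are reported as NA.
#'
#' @param x a [BarcodeSet-class] of aligned sequences.
#' @param nBoot site-bootstrap replicates for standard errors (default 500).
#' @param seed integer RNG seed.
#' @return list of class \code{"barcodeSummary"}: \code{within} (data.frame
#'   population/mean/se/nPairs), \code{between} (data.frame pair/mean/se),
#'   \code{barcodeGap} and \code{barcodeGapPercent} (global gap), and
#'   \code{populationGap} (per population, smallest between mean involving
#'   it minus its within mean).
#' @export
groupDistanceSummary <- function(x, nBoot = 500L, seed = 1L) {
  m <- barcodeMatrix(x)
  pops <- x@population
  labs <- unique(pops)
  n <- nrow(m)
  L <- ncol(m)
  pairsIdx <- t(combn(n, 2))
  # Per-pair, per-site codes: 0 identical, 1 transition, 2 transversion,
  # NA not comparable.  One pass; reused by every bootstrap replicate.
  codes <- matrix(NA_integer_, nrow(pairsIdx), L)
  purine <- c("A", "G")
  for (p in seq_len(nrow(pairsIdx))) {
    a <- m[pairsIdx[p, 1], ]; b <- m[pairsIdx[p, 2], ]
    ok <- a %in% NUC & b %in% NUC
    code <- integer(L)
    diffs <- ok & a != b
    isTs <- diffs & ((a %in% purine) == (b %in% purine))
    code[isTs] <- 1L
    code[diffs & !isTs] <- 2L
    code[!ok] <- NA_integer_
    codes[p, ] <- code
  }
  pairDistances <- function(siteIdx) {
    cc <- codes[, siteIdx, drop = FALSE]
    sites <- rowSums(!is.na(cc))
    ts <- rowSums(cc == 1L, na.rm = TRUE)
    tv <- rowSums(cc == 2L, na.rm = TRUE)
    vapply(seq_along(sites),
           function(p) k2pFromCounts(sites[p], ts[p], tv[p]), 0)
  }
  d0 <- pairDistances(seq_len(L))
  pa <- pops[pairsIdx[, 1]]; pb <- pops[pairsIdx[, 2]]
  withinIdx <- lapply(labs, function(gl) which(pa == gl & pb == gl))
  names(withinIdx) <- labs
  pairLabs <- combn(labs, 2)
  betweenIdx <- lapply(seq_len(ncol(pairLabs)), function(q) {
    a <- pairLabs[1, q]; b <- pairLabs[2, q]
    which((pa == a & pb == b) | (pa == b & pb == a))
  })
  summarize <- function(d) {
    wi <- vapply(withinIdx, function(ii)
      if (length(ii)) mean(d[ii], na.rm = TRUE) else NA_real_, 0)
    be <- vapply(betweenIdx, function(ii) mean(d[ii], na.rm = TRUE), 0)
    c(wi, be)
  }
  obs <- summarize(d0)
  boot <- withSeed(seed, {
    vapply(seq_len(nBoot), function(r)
      summarize(pairDistances(sample.int(L, L, replace = TRUE))),
      numeric(length(obs)))
  })
  ses <- apply(boot, 1, sd, na.rm = TRUE)
  gW <- length(labs)
  within <- data.frame(population = labs,
                       mean = unname(obs[seq_len(gW)]),
                       se = unname(ses[seq_len(gW)]),
                       nPairs = vapply(withinIdx, length, 0L))
  between <- data.frame(pair = apply(pairLabs, 2, paste, collapse = "-"),
                        popA = pairLabs[1, ], popB = pairLabs[2, ],
                        mean = unname(obs[-seq_len(gW)]),
                        se = unname(ses[-seq_len(gW)]))
  gap <- min(between$mean, na.rm = TRUE) -
    max(c(within$mean, 0), na.rm = TRUE)
  # per-population gap: smallest between mean involving the population
  # minus its own within mean
  popGap <- vapply(labs, function(gl) {
    inv <- between$popA == gl | between$popB == gl
    wi <- within$mean[within$population == gl]
    if (!any(inv) || is.na(wi)) return(NA_real_)
    min(between$mean[inv], na.rm = TRUE) - wi
  }, 0)
  structure(list(within = within, between = between,
                 barcodeGap = gap, barcodeGapPercent = 100 * gap,
                 populationGap = setNames(popGap, labs),
                 nBoot = as.integer(nBoot), seed = as.integer(seed)),
            class = "barcodeSummary")
}

#' @export
print.barcodeSummary <- function(x, ...) {
  cat("K2P distance summary\n  within populations:\n")
  for (i in seq_len(nrow(x$within)))
    cat(sprintf("    %s: %.4f +/- %.4f\n", x$within$population[i],
                x$within$mean[i], x$within$se[i]))
  cat("  between populations:\n")
  for (i in seq_len(nrow(x$between)))
    cat(sprintf("    %s: %.4f +/- %.4f\n", x$between$pair[i],
                x$between$mean[i], x$between$se[i]))
  cat(sprintf("  barcode gap: %.2f%%\n", x$barcodeGapPercent))
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration on the Q criterion.  For an additive input
#' matrix the tree's path-length distances reproduce the input exactly.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the adjacent branch (standard display convention).  When an outgroup id
#' is given the tree is rooted on its branch.
#'
#' @param D symmetric distance matrix with labelled rows (>= 3 taxa), or a
#'   \code{"k2pMatrix"} result.
#' @param outgroup optional taxon id to root on.
#' @return an [ape::phylo] tree (unrooted unless \code{outgroup} given).
#' @examples
#' D <- matrix(c(0, 3, 8, 3, 0, 9, 8, 9, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' njTree(D)
#' @export
njTree <- function(D, outgroup = NULL) {
  if (inherits(D, "k2pMatrix")) {
    if (!is.null(D$saturatedPairs))
      stop("undefined (saturated) distances for pairs: ",
           paste(apply(D$saturatedPairs, 1, paste, collapse = "/"),
                 collapse = ", "))
    D <- D$distances
  }
  D <- as.matrix(D)
  if (anyNA(D)) stop("distance matrix contains undefined entries")
  n <- nrow(D)
  if (n < 3L) stop("at least 3 taxa are required")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # working nodes as newick fragments
  frag <- labels
  active <- seq_len(n)
  Dw <- D
  while (length(active) > 3L) {
    N <- length(active)
    r <- rowSums(Dw)
    Q <- (N - 2) * Dw - outer(r, r, `+`)
    diag(Q) <- Inf
    ij <- which(Q == min(Q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- min(ij); j <- max(ij)
    vi <- 0.5 * Dw[i, j] + (r[i] - r[j]) / (2 * (N - 2))
    vj <- Dw[i, j] - vi
    # negative-length policy: clamp, transfer to the sister branch
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newFrag <- sprintf("(%s:%.17g,%s:%.17g)", frag[i], vi, frag[j], vj)
    dNew <- 0.5 * (Dw[i, ] + Dw[j, ] - Dw[i, j])
    Dw <- rbind(cbind(Dw, dNew), c(dNew, 0))
    keep <- setdiff(seq_len(nrow(Dw)), c(i, j))
    Dw <- Dw[keep, keep, drop = FALSE]
    frag <- c(frag, newFrag)[keep]
    active <- seq_len(nrow(Dw))
  }
  # final three-node star with closed-form branch lengths
  d12 <- Dw[1, 2]; d13 <- Dw[1, 3]; d23 <- Dw[2, 3]
  v1 <- (d12 + d13 - d23) / 2
  v2 <- (d12 + d23 - d13) / 2
  v3 <- (d13 + d23 - d12) / 2
  v <- c(v1, v2, v3)
  for (q in 1:3) if (v[q] < 0) {
    others <- setdiff(1:3, q)
    v[others] <- v[others] + v[q] / 2
    v[q] <- 0
  }
  nwk <- sprintf("(%s:%.17g,%s:%.17g,%s:%.17g);",
                 frag[1], v[1], frag[2], v[2], frag[3], v[3])
  phy <- ape::read.tree(text = nwk)
  if (!is.null(outgroup)) {
    if (!outgroup %in% phy$tip.label)
      stop("outgroup '", outgroup, "' not among taxa")
    phy <- ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
  }
  phy
}

#' Bootstrap support for a neighbor-joining barcode tree
#'
#' Resamples alignment columns with replacement, rebuilds the K2P + NJ
#' tree per replicate, and reports for each internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#' Replicates with saturated (undefined) distances are skipped and
#' counted; more than 5 percent skipped triggers a warning.
#'
#' @param x a [BarcodeSet-class] of aligned sequences (>= 4).
#' @param nReps bootstrap replicates (default 1000).
#' @param seed integer RNG seed.
#' @param outgroup optional taxon id to root the reported tree on.
#' @return list of class \code{"njBootstrap"}: \code{tree} (phylo with
#'   node labels = support percentages), \code{support}, \code{nReps},
#'   \code{skipped}.
#' @export
bootstrapSupport <- function(x, nReps = 1000L, seed = 1L, outgroup = NULL) {
  m <- barcodeMatrix(x)
  if (nrow(m) < 4L) stop("at least 4 sequences are required")
  refD <- k2pCharMatrix(m)
  if (anyNA(refD)) stop("saturated distances in the full alignment")
  ref <- njTree(refD)
  trees <- list()
  skipped <- 0L
  withSeed(seed, {
    for (r in seq_len(nReps)) {
      idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
      Db <- k2pCharMatrix(m[, idx, drop = FALSE])
      if (anyNA(Db)) { skipped <- skipped + 1L; next }
      trees[[length(trees) + 1L]] <- njTree(Db)
    }
  })
  if (skipped > 0.05 * nReps)
    warning(skipped, " of ", nReps,
            " replicates skipped for saturated distances")
  counts <- ape::prop.clades(ref, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / length(trees)
  out <- ref
  out$node.label <- sprintf("%.0f", support)
  if (!is.null(outgroup))
    out <- ape::root(out, outgroup = outgroup, resolve.root = TRUE,
                     edgelabel = TRUE)
  structure(list(tree = out, support = support,
                 nReps = as.integer(nReps), skipped = skipped),
            class = "njBootstrap")
}

# K2P matrix straight from a character matrix (internal; NA = saturated).
k2pCharMatrix <- function(m) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    cnt <- pairSiteCounts(m[i, ], m[j, ])
    D[i, j] <- D[j, i] <- k2pFromCounts(cnt["sites"], cnt["ts"], cnt["tv"])
  }
  D
}

#' @export
print.njBootstrap <- function(x, ...) {
  cat("NJ tree with bootstrap support (", length(x$tree$tip.label),
      " taxa, ", x$nReps, " replicates, ", x$skipped, " skipped)\n", sep = "")
  cat("  newick:", ape::write.tree(x$tree), "\n")
  invisible(x)
}
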