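#' @import methods
#' @importFrom stats anova aov coef cor dist dnorm hclust lm p.adjust pnorm
#'   prcomp rnorm runif sd var wilcox.test as.dist cophenetic cutree predict
#'   quantile rbinom setNames
#' @importFrom utils combn head read.csv write.csv
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Landmark dataset for a set of wings
#'
#' Stores one k-landmark, two-dimensional configuration per specimen together
#' with specimen identity and population membership.  Coordinates are held in
#' millimetres in a \code{k x 2 x n} array whose third dimension is named by
#' specimen id.
#'
#' @slot coords numeric array, \code{k x 2 x n}, landmark coordinates in mm.
#' @slot specimens data.frame with columns \code{id}, \code{population} and
#'   optionally \code{sex}; one row per specimen, in array order.
#'
#' @seealso [readTPS()], [simulateLandmarkDataset()], [gpaAlign()]
#' @export
setClass("WingDataset",
  representation(coords = "array", specimens = "data.frame"))

setValidity("WingDataset", function(object) {
  d <- dim(object@coords)
  msg <- character()
  if (length(d) != 3L || d[2] != 2L)
    msg <- c(msg, "coords must be a k x 2 x n array")
  else {
    if (d[1] < 3L) msg <- c(msg, "at least 3 landmarks are required")
    if (!all(is.finite(object@coords)))
      msg <- c(msg, "all coordinates must be finite")
    if (nrow(object@specimens) != d[3])
      msg <- c(msg, "specimens table must have one row per configuration")
  }
  if (!all(c("id", "population") %in% names(object@specimens)))
    msg <- c(msg, "specimens must have 'id' and 'population' columns")
  else {
    if (anyDuplicated(object@specimens$id))
      msg <- c(msg, "specimen ids must be unique")
    if (any(!nzchar(object@specimens$population)))
      msg <- c(msg, "population labels must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WingDataset
#'
#' @param coords \code{k x 2 x n} array of landmark coordinates (mm), or a
#'   list of \code{k x 2} matrices.
#' @param specimens data.frame with \code{id} and \code{population} columns
#'   (and optionally \code{sex}), one row per configuration.
#' @return A [WingDataset-class] object.
#' @examples
#' tri <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
#' wd <- WingDataset(list(tri, tri + 1),
#'                   data.frame(id = c("a", "b"), population = "p1"))
#' nSpecimens(wd)
#' @export
WingDataset <- function(coords, specimens) {
  if (is.list(coords)) {
    k <- unique(vapply(coords, nrow, 0L))
    if (length(k) != 1L)
      stop("all configurations must share the same landmark count")
    coords <- array(unlist(lapply(coords, as.numeric)), dim = c(k, 2, length(coords)))
  }
  specimens$id <- as.character(specimens$id)
  specimens$population <- as.character(specimens$population)
  dimnames(coords) <- list(NULL, c("x", "y"), specimens$id)
  new("WingDataset", coords = coords, specimens = specimens)
}

#' Outline dataset for a set of wing cells
#'
#' Stores one closed contour per specimen (ordered counter-clockwise, first
#' point at the first anchor landmark) plus the anchor-landmark indices that
#' define the cell.
#'
#' @slot contours list of \code{m_i x 2} coordinate matrices (mm).
#' @slot specimens data.frame with \code{id} and \code{population} columns.
#' @slot anchorLandmarks integer vector of landmark indices delimiting the
#'   cell (e.g. 1:4 for the first outline set, 8:10 for the second).
#' @slot outlineSet character; \code{"outlines1"}, \code{"outlines2"} or
#'   \code{"custom"}.
#' @export
setClass("OutlineDataset",
  representation(contours = "list", specimens = "data.frame",
                 anchorLandmarks = "integer", outlineSet = "character"))

setValidity("OutlineDataset", function(object) {
  msg <- character()
  if (length(object@contours) != nrow(object@specimens))
    msg <- c(msg, "one contour per specimen row is required")
  ok <- vapply(object@contours, function(p)
    is.matrix(p) && ncol(p) == 2L && nrow(p) >= 8L && all(is.finite(p)), TRUE)
  if (!all(ok)) msg <- c(msg, "each contour must be a finite m x 2 matrix, m >= 8")
  if (!object@outlineSet %in% c("outlines1", "outlines2", "custom"))
    msg <- c(msg, "outlineSet must be 'outlines1', 'outlines2' or 'custom'")
  if (anyDuplicated(object@specimens$id))
    msg <- c(msg, "specimen ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an OutlineDataset
#'
#' @param contours list of \code{m x 2} matrices, one closed contour each.
#' @param specimens data.frame with \code{id} and \code{population}.
#' @param anchorLandmarks integer indices of the landmarks anchoring the cell.
#' @param outlineSet one of \code{"outlines1"}, \code{"outlines2"},
#'   \code{"custom"}.
#' @return An [OutlineDataset-class] object.
#' @export
OutlineDataset <- function(contours, specimens,
                           anchorLandmarks = integer(),
                           outlineSet = "custom") {
  specimens$id <- as.character(specimens$id)
  specimens$population <- as.character(specimens$population)
  names(contours) <- specimens$id
  new("OutlineDataset", contours = contours, specimens = specimens,
      anchorLandmarks = as.integer(anchorLandmarks), outlineSet = outlineSet)
}

#' Result of a generalized Procrustes superimposition
#'
#' @slot aligned \code{k x 2 x n} array of superimposed configurations, each
#'   centred at the origin with unit centroid size.
#' @slot consensus \code{k x 2} arithmetic mean of the aligned shapes (its
#'   centroid size is marginally below 1 for noisy data).
#' @slot cs numeric vector of original centroid sizes (mm).
#' @slot specimens specimen table carried over from the input dataset.
#' @slot iterations integer, iterations used.
#' @slot converged logical.
#' @seealso [gpaAlign()], [relativeWarps()]
#' @export
setClass("ProcrustesFit",
  representation(aligned = "array", consensus = "matrix", cs = "numeric",
                 specimens = "data.frame", iterations = "integer",
                 converged = "logical"))

setValidity("ProcrustesFit", function(object) {
  msg <- character()
  n <- dim(object@aligned)[3]
  cs1 <- apply(object@aligned, 3, function(m) sqrt(sum(centerConfig(m)^2)))
  if (any(abs(cs1 - 1) > 1e-8))
    msg <- c(msg, "aligned configurations must have unit centroid size")
  cents <- apply(object@aligned, 3, colMeans)
  if (max(abs(cents)) > 1e-8)
    msg <- c(msg, "aligned configurations must be centred at the origin")
  if (length(object@cs) != n)
    msg <- c(msg, "one centroid size per specimen is required")
  cons <- apply(object@aligned, c(1, 2), mean)
  if (max(abs(cons - object@consensus)) > 1e-8)
    msg <- c(msg, "consensus must be the arithmetic mean of aligned shapes")
  if (length(msg)) msg else TRUE
})

#' Relative-warp (principal component) scores of aligned shapes
#'
#' @slot scores \code{n x p} matrix of principal-axis coordinates.
#' @slot explained numeric vector of per-axis variance fractions.
#' @slot rotation loading matrix mapping centred flat coordinates to scores.
#' @slot center length-2k centring vector (flattened consensus coordinates).
#' @export
setClass("ShapeScores",
  representation(scores = "matrix", explained = "numeric",
                 rotation = "matrix", center = "numeric"))

setValidity("ShapeScores", function(object) {
  msg <- character()
  ev <- object@explained
  if (any(ev < -1e-12)) msg <- c(msg, "explained variance must be non-negative")
  if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-10))
    msg <- c(msg, "explained variance must be non-increasing")
  if (sum(ev) > 1 + 1e-8) msg <- c(msg, "explained variance must sum to <= 1")
  if (length(msg)) msg else TRUE
})

#' Elliptic Fourier coefficients of one closed contour
#'
#' @slot harmonics \code{H x 4} matrix with columns \code{a}, \code{b},
#'   \code{c}, \code{d}.
#' @slot dc numeric length 2: the (A0, C0) offsets of the decomposition.
#' @slot normalized logical; when TRUE the coefficients are invariant to
#'   translation, rotation, scale and starting point, with \code{a1 = 1},
#'   \code{b1 = c1 = 0}.
#' @export
setClass("EFACoefficients",
  representation(harmonics = "matrix", dc = "numeric", normalized = "logical"))

setValidity("EFACoefficients", function(object) {
  msg <- character()
  h <- object@harmonics
  if (!is.numeric(h) || ncol(h) != 4L || nrow(h) < 1L)
    msg <- c(msg, "harmonics must be a numeric H x 4 matrix")
  if (isTRUE(object@normalized) && nrow(h) >= 1L) {
    if (h[1, 1] <= 0) msg <- c(msg, "normalized coefficients require a1 > 0")
    if (max(abs(h[1, 2:3])) > 1e-6)
      msg <- c(msg, "normalized coefficients require b1 = c1 = 0")
  }
  if (length(msg)) msg else TRUE
})

#' A set of population-labelled barcode sequences
#'
#' Wraps a [Biostrings::DNAStringSet] with a population label per sequence.
#'
#' @slot sequences DNAStringSet; names are specimen ids.
#' @slot population character vector parallel to \code{sequences}.
#' @seealso [readBarcodeFasta()], [simulateK2PSequences()], [k2pMatrix()]
#' @export
setClass("BarcodeSet",
  representation(sequences = "DNAStringSet", population = "character"))

setValidity("BarcodeSet", function(object) {
  msg <- character()
  if (length(object@population) != length(object@sequences))
    msg <- c(msg, "one population label per sequence is required")
  if (is.null(names(object@sequences)) || anyDuplicated(names(object@sequences)))
    msg <- c(msg, "sequence ids must be present and unique")
  if (length(msg)) msg else TRUE
})

#' Construct a BarcodeSet
#'
#' @param sequences a named [Biostrings::DNAStringSet] or named character
#'   vector of nucleotide strings.
#' @param population character vector of population labels, one per sequence.
#' @return A [BarcodeSet-class] object.
#' @export
BarcodeSet <- function(sequences, population) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  new("BarcodeSet", sequences = sequences,
      population = as.character(population))
}
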