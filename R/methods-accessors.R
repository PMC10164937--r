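#' Accessors for wingmorph data containers
#'
#' \code{populations} returns the population label per specimen;
#' \code{specimenIds} the specimen identifiers; \code{nSpecimens} the number
#' of specimens; \code{landmarkCount} the landmarks per configuration;
#' \code{specimenTable} the full specimen data.frame; \code{contours} the
#' list of outline coordinate matrices; \code{sequences} the underlying
#' \code{DNAStringSet}.
#'
#' @param x a [WingDataset-class], [OutlineDataset-class],
#'   [ProcrustesFit-class] or [BarcodeSet-class] object.
#' @return See details; vectors, tables or list components of \code{x}.
#' @name accessors
NULL

#' @rdname accessors
setMethod("populations", "WingDataset", function(x) {
  setNames(x@specimens$population, x@specimens$id)
})
#' @rdname accessors
setMethod("populations", "OutlineDataset", function(x) {
  setNames(x@specimens$population, x@specimens$id)
})
#' @rdname accessors
setMethod("populations", "ProcrustesFit", function(x) {
  setNames(x@specimens$population, x@specimens$id)
})
#' @rdname accessors
setMethod("populations", "BarcodeSet", function(x) {
  setNames(x@population, names(x@sequences))
})

#' @rdname accessors
setMethod("specimenIds", "WingDataset", function(x) x@specimens$id)
#' @rdname accessors
setMethod("specimenIds", "OutlineDataset", function(x) x@specimens$id)
#' @rdname accessors
setMethod("specimenIds", "BarcodeSet", function(x) names(x@sequences))

#' @rdname accessors
setMethod("nSpecimens", "WingDataset", function(x) dim(x@coords)[3])
#' @rdname accessors
setMethod("nSpecimens", "OutlineDataset", function(x) length(x@contours))
#' @rdname accessors
setMethod("nSpecimens", "BarcodeSet", function(x) length(x@sequences))

#' @rdname accessors
setMethod("landmarkCount", "WingDataset", function(x) dim(x@coords)[1])

#' @rdname accessors
setMethod("specimenTable", "WingDataset", function(x) x@specimens)
#' @rdname accessors
setMethod("specimenTable", "OutlineDataset", function(x) x@specimens)

#' @rdname accessors
setMethod("contours", "OutlineDataset", function(x) x@contours)

#' @rdname accessors
setMethod("sequences", "BarcodeSet", function(x) x@sequences)

#' Landmark coordinates of a dataset
#'
#' @param x a [WingDataset-class].
#' @return the \code{k x 2 x n} coordinate array (mm).
#' @export
landmarkCoords <- function(x) {
  stopifnot(is(x, "WingDataset"))
  x@coords
}

setMethod("show", "WingDataset", function(object) {
  tab <- table(object@specimens$population)
  cat("WingDataset:", dim(object@coords)[3], "specimens,",
      dim(object@coords)[1], "landmarks\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "OutlineDataset", function(object) {
  tab <- table(object@specimens$population)
  m <- range(vapply(object@contours, nrow, 0L))
  cat("OutlineDataset [", object@outlineSet, "]: ",
      length(object@contours), " contours, ",
      if (m[1] == m[2]) m[1] else paste(m[1], "-", m[2]),
      " points each\n", sep = "")
  cat("  anchor landmarks:", paste(object@anchorLandmarks, collapse = ", "), "\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "ProcrustesFit", function(object) {
  cat("ProcrustesFit:", dim(object@aligned)[3], "specimens,",
      dim(object@aligned)[1], "landmarks\n")
  cat(sprintf("  converged: %s after %d iterations\n",
              object@converged, object@iterations))
  cat(sprintf("  centroid size: %.4g - %.4g mm\n",
              min(object@cs), max(object@cs)))
})

setMethod("show", "ShapeScores", function(object) {
  cat("ShapeScores:", nrow(object@scores), "specimens,",
      ncol(object@scores), "axes\n")
  cat("  explained variance:",
      paste(sprintf("%.1f%%", 100 * head(object@explained, 5)), collapse = ", "),
      if (length(object@explained) > 5) "...", "\n")
})

setMethod("show", "EFACoefficients", function(object) {
  cat("EFACoefficients:", nrow(object@harmonics), "harmonics,",
      if (object@normalized) "normalized" else "raw", "\n")
})

setMethod("show", "BarcodeSet", function(object) {
  tab <- table(object@population)
  w <- unique(Biostrings::width(object@sequences))
  cat("BarcodeSet:", length(object@sequences), "sequences,",
      if (length(w) == 1) paste0("aligned length ", w)
      else paste0("lengths ", min(w), "-", max(w)), "\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
})

#' Scores matrix and explained variance of a ShapeScores object
#'
#' @param x a [ShapeScores-class] object.
#' @return \code{shapeScoreMatrix}: the \code{n x p} score matrix;
#'   \code{explainedVariance}: per-axis variance fractions.
#' @export
shapeScoreMatrix <- function(x) {
  stopifnot(is(x, "ShapeScores"))
  x@scores
}

#' @rdname shapeScoreMatrix
#' @export
explainedVariance <- function(x) {
  stopifnot(is(x, "ShapeScores"))
  x@explained
}

#' Harmonic coefficient matrix of an EFA decomposition
#'
#' @param x an [EFACoefficients-class] object.
#' @return \code{H x 4} matrix with columns a, b, c, d.
#' @export
harmonicMatrix <- function(x) {
  stopifnot(is(x, "EFACoefficients"))
  x@harmonics
}

#' Subset a BarcodeSet
#'
#' @param x a [BarcodeSet-class].
#' @param i index vector (numeric, logical or names).
#' @param j,...,drop ignored.
#' @return a [BarcodeSet-class] containing the selected sequences.
#' @export
setMethod("[", "BarcodeSet", function(x, i, j, ..., drop = TRUE) {
  BarcodeSet(x@sequences[i], x@population[i])
})
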