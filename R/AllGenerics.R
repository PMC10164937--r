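#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname accessors
#' @export
setGeneric("specimenIds", function(x) standardGeneric("specimenIds"))

#' @rdname accessors
#' @export
setGeneric("nSpecimens", function(x) standardGeneric("nSpecimens"))

#' @rdname accessors
#' @export
setGeneric("landmarkCount", function(x) standardGeneric("landmarkCount"))

#' @rdname accessors
#' @export
setGeneric("specimenTable", function(x) standardGeneric("specimenTable"))

#' @rdname accessors
#' @export
setGeneric("contours", function(x) standardGeneric("contours"))

#' @rdname accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Centroid size
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid -- the standard isometric size estimator for landmark data.  For a
#' [WingDataset-class] one value per specimen is returned, in the units of the
#' input coordinates (mm).
#'
#' @param x a \code{k x 2} coordinate matrix or a [WingDataset-class].
#' @return numeric; a single size, or a named vector over specimens.
#' @examples
#' sq <- matrix(c(-1, -1, 1, -1, 1, 1, -1, 1), ncol = 2, byrow = TRUE)
#' centroidSize(sq)  # sqrt(8)
#' @export
setGeneric("centroidSize", function(x) standardGeneric("centroidSize"))

#' @rdname gpaAlign
#' @export
setGeneric("alignedCoords", function(x) standardGeneric("alignedCoords"))

#' @rdname gpaAlign
#' @export
setGeneric("consensusShape", function(x) standardGeneric("consensusShape"))

#' @rdname gpaAlign
#' @export
setGeneric("residualCoords", function(x) standardGeneric("residualCoords"))
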