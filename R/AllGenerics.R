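#' @include AllClasses.R
NULL

#' Grid accessors
#'
#' @param x a \linkS4class{RasterGrid} (or object containing one).
#' @return \code{gridValues}: the value matrix; \code{cellSize}: cell edge
#'   length (m); \code{gridOrigin}: upper-left (x, y); \code{cellCenters}:
#'   an (nrow*ncol) x 2 matrix of cell-centre map coordinates in column-major
#'   cell order.
#' @name grid-accessors
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname grid-accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname grid-accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname grid-accessors
#' @export
setGeneric("cellCenters", function(x) standardGeneric("cellCenters"))

#' @rdname grid-accessors
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname grid-accessors
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)

#' @rdname grid-accessors
#' @export
setMethod("gridOrigin", "RasterGrid", function(x) x@origin)

#' @rdname grid-accessors
#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

#' @rdname grid-accessors
#' @export
setMethod("cellCenters", "RasterGrid", function(x) {
  nr <- nrow(x@values); nc <- ncol(x@values); cs <- x@cellSize
  j <- rep(seq_len(nc), each = nr)
  i <- rep(seq_len(nr), times = nc)
  cbind(x = x@origin[1] + (j - 0.5) * cs,
        y = x@origin[2] - (i - 0.5) * cs)
})

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat(sprintf("%s: %d x %d cells, %g m resolution\n",
              class(object), nrow(v), ncol(v), object@cellSize))
  cat(sprintf("  origin (UL): (%g, %g)  nodata cells: %d\n",
              object@origin[1], object@origin[2], sum(is.na(v))))
  if (length(v))
    cat(sprintf("  values: [%g, %g]\n",
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE))))
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet: %d records (%s)\n", nrow(object@coords),
              paste(sprintf("%s: %d", names(table(object@sourceClass)),
                            as.integer(table(object@sourceClass))),
                    collapse = ", ")))
})

#' @rdname occurrenceSet
#' @param x an \linkS4class{OccurrenceSet}.
#' @export
setMethod("length", "OccurrenceSet", function(x) nrow(x@coords))

#' Occurrence accessors
#' @param x an \linkS4class{OccurrenceSet}.
#' @return \code{occCoords}: n x 2 coordinate matrix; \code{occClass}:
#'   source-class labels.
#' @export
occCoords <- function(x) x@coords

#' @rdname occCoords
#' @export
occClass <- function(x) x@sourceClass

setMethod("show", "SuitabilityEnsemble", function(object) {
  auc <- ensembleAUC(object)
  cat(sprintf(
    "SuitabilityEnsemble: %d replicates over %d predictors; mean test AUC %.3f\n",
    length(object@replicates), length(object@varNames), mean(auc, na.rm = TRUE)))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches (status: %s)\n",
              nrow(object@table), object@status))
  if (nrow(object@table))
    cat(sprintf("  total area %.3f km2\n", sum(object@table$areaKm2)))
})

setMethod("show", "PatchGraph", function(object) {
  cat(sprintf(
    "PatchGraph: %d nodes, p(%g m) = %g, AL = %g\n",
    length(object@id), object@dMed, object@pMed, object@AL))
})

setMethod("show", "ConservationAreas", function(object) {
  tab <- table(object@category)
  cat(sprintf("ConservationAreas: %d polygons (%s)\n",
              length(object@polygons),
              paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                    collapse = ", ")))
})

#' Patch table accessor
#' @param x a \linkS4class{PatchSet}.
#' @return data.frame with one row per patch (id, nCells, areaKm2, strength,
#'   centroidX, centroidY).
#' @export
patchTable <- function(x) x@table

#' Patch label grid accessor
#' @param x a \linkS4class{PatchSet}.
#' @return integer \linkS4class{RasterGrid} of patch ids (0 = background).
#' @export
patchLabels <- function(x) x@labels

#' Per-replicate test AUC of an ensemble
#' @param x a \linkS4class{SuitabilityEnsemble}.
#' @return numeric vector of test AUCs (NA for non-converged replicates).
#' @export
ensembleAUC <- function(x)
  vapply(x@replicates, function(r) r$testAUC, numeric(1))
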