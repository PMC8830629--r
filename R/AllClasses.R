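#' @import methods
NULL

#' RasterGrid: a single-band raster surface
#'
#' The carrier of every spatial surface in the package (predictors, habitat
#' suitability, resistance, kernel and corridor surfaces). Values are stored
#' as a numeric matrix with row 1 at the top of the map; \code{NA} encodes
#' nodata. The grid is georeferenced by a square cell size in meters and the
#' map coordinate of its upper-left corner. The CRS string is metadata only:
#' all computations assume a projected metric reference.
#'
#' The centre of cell (row i, col j) lies at
#' \code{(origin_x + (j - 0.5) * cellSize, origin_y - (i - 0.5) * cellSize)}.
#'
#' @slot values numeric matrix of cell values, \code{NA} = nodata.
#' @slot cellSize positive numeric, cell edge length in meters.
#' @slot origin numeric length-2, map (x, y) of the upper-left grid corner.
#' @slot crs character CRS description (metadata only).
#'
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", cellSize = "numeric",
                 origin = "numeric", crs = "character"),
  prototype(values = matrix(numeric(0), 0, 0), cellSize = 1,
            origin = c(0, 0), crs = NA_character_))

setValidity("RasterGrid", function(object) {
  msg <- character(0)
  if (!is.numeric(object@values) && !is.logical(object@values))
    msg <- c(msg, "values must be a numeric matrix")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be a finite (x, y) pair")
  if (length(msg)) msg else TRUE
})

#' Construct a RasterGrid
#'
#' @param values numeric matrix (row 1 = top of map), \code{NA} = nodata.
#' @param cellSize cell edge length in meters.
#' @param origin map (x, y) of the upper-left corner.
#' @param crs optional CRS string (metadata only).
#' @return A \linkS4class{RasterGrid}.
#' @examples
#' g <- rasterGrid(matrix(1:9, 3, 3), cellSize = 100)
#' dim(g)
#' @export
rasterGrid <- function(values, cellSize, origin = c(0, 0),
                       crs = NA_character_) {
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin), crs = as.character(crs))
}

#' Occurrence point records
#'
#' Presence localities in map coordinates with a source-class label per
#' record (e.g. den, scat, sighting). Classes are carried through but all
#' records are treated identically by the models.
#'
#' @slot coords numeric n x 2 matrix of (x, y) map coordinates.
#' @slot sourceClass character vector of per-record source labels.
#' @exportClass OccurrenceSet
setClass("OccurrenceSet",
  representation(coords = "matrix", sourceClass = "character"))

setValidity("OccurrenceSet", function(object) {
  if (ncol(object@coords) != 2L) return("coords must have two columns")
  if (nrow(object@coords) != length(object@sourceClass))
    return("one sourceClass label per record required")
  TRUE
})

#' Construct an OccurrenceSet
#' @param x,y numeric coordinate vectors (meters, projected CRS).
#' @param sourceClass character labels, recycled to length of \code{x}.
#' @return An \linkS4class{OccurrenceSet}.
#' @export
occurrenceSet <- function(x, y, sourceClass = "presence") {
  coords <- cbind(x = as.numeric(x), y = as.numeric(y))
  new("OccurrenceSet", coords = coords,
      sourceClass = rep_len(as.character(sourceClass), nrow(coords)))
}

#' Synthetic landscape specification
#'
#' Describes a synthetic study landscape: grid geometry, the number of
#' spatially autocorrelated continuous predictors, the Gaussian smoothing
#' scale that sets their autocorrelation range, counts of linear/point/areal
#' anthropogenic features (roads, settlements, dumpsites, croplands) from
#' which distance predictors are derived, the conservation-area network
#' (category mix defaults to the 2 wildlife refuges / 2 protected areas /
#' 5 non-hunting areas of a typical arid-steppe reserve network), prey
#' species count, and the master seed that fixes all outputs bit-for-bit.
#'
#' @exportClass LandscapeSpec
setClass("LandscapeSpec",
  representation(nRows = "integer", nCols = "integer", cellSize = "numeric",
                 nContinuousVars = "integer", autocorrRange = "numeric",
                 nRoads = "integer", nSettlements = "integer",
                 nDumpsites = "integer", nCroplands = "integer",
                 nCAs = "integer", caCategoryMix = "numeric",
                 nPrey = "integer", seed = "integer"))

setValidity("LandscapeSpec", function(object) {
  msg <- character(0)
  if (object@nRows < 16L || object@nCols < 16L)
    msg <- c(msg, "grid must be at least 16 x 16 cells")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be positive")
  if (object@autocorrRange < 0) msg <- c(msg, "autocorrRange must be >= 0")
  if (object@nContinuousVars < 1L)
    msg <- c(msg, "at least one continuous predictor required")
  if (length(msg)) msg else TRUE
})

#' Construct a LandscapeSpec
#'
#' @param nRows,nCols grid dimensions in cells (>= 16).
#' @param cellSize cell size in meters (default 100, the analysis resolution).
#' @param nContinuousVars number of autocorrelated continuous predictors.
#' @param autocorrRange Gaussian smoothing scale in meters controlling the
#'   spatial autocorrelation of the continuous fields; 0 gives iid noise.
#' @param nRoads,nSettlements,nDumpsites,nCroplands feature counts for the
#'   four distance-to-feature predictor classes.
#' @param nCAs number of conservation-area polygons.
#' @param caCategoryMix named numeric mix of CA categories; scaled to nCAs.
#' @param nPrey number of prey species for the prey-availability layer.
#' @param seed integer master seed; fixes every generated output.
#' @return A \linkS4class{LandscapeSpec}.
#' @export
landscapeSpec <- function(nRows = 96L, nCols = 96L, cellSize = 100,
                          nContinuousVars = 3L, autocorrRange = 500,
                          nRoads = 3L, nSettlements = 5L, nDumpsites = 2L,
                          nCroplands = 4L, nCAs = 9L,
                          caCategoryMix = c(wildlife_refuge = 2,
                                            protected_area = 2,
                                            non_hunting_area = 5),
                          nPrey = 3L, seed = 1L) {
  new("LandscapeSpec", nRows = as.integer(nRows), nCols = as.integer(nCols),
      cellSize = as.numeric(cellSize),
      nContinuousVars = as.integer(nContinuousVars),
      autocorrRange = as.numeric(autocorrRange),
      nRoads = as.integer(nRoads), nSettlements = as.integer(nSettlements),
      nDumpsites = as.integer(nDumpsites), nCroplands = as.integer(nCroplands),
      nCAs = as.integer(nCAs), caCategoryMix = caCategoryMix,
      nPrey = as.integer(nPrey), seed = as.integer(seed))
}

#' Known "true" suitability model for synthetic landscapes
#'
#' A logistic suitability function over named stack variables; used to
#' generate occurrences with recoverable structure (ground truth for
#' parameter-recovery tests).
#'
#' @slot coefficients named numeric weights over stack variables.
#' @slot intercept numeric intercept.
#' @exportClass TrueModel
setClass("TrueModel",
  representation(coefficients = "numeric", intercept = "numeric"))

setValidity("TrueModel", function(object) {
  if (is.null(names(object@coefficients)) ||
      any(!nzchar(names(object@coefficients))))
    return("coefficients must be named after stack variables")
  if (all(object@coefficients == 0))
    return("at least one coefficient must be nonzero")
  TRUE
})

#' @rdname TrueModel-class
#' @param coefficients named numeric weights.
#' @param intercept numeric intercept.
#' @export
trueModel <- function(coefficients, intercept = 0) {
  new("TrueModel", coefficients = coefficients,
      intercept = as.numeric(intercept))
}

#' Conservation-area polygon set
#'
#' Non-overlapping convex polygons (closed rings, map coordinates) with one
#' category label each: wildlife_refuge, protected_area or non_hunting_area.
#'
#' @slot polygons list of closed-ring coordinate matrices (n x 2).
#' @slot category character category per polygon.
#' @exportClass ConservationAreas
setClass("ConservationAreas",
  representation(polygons = "list", category = "character"))

setValidity("ConservationAreas", function(object) {
  if (length(object@polygons) != length(object@category))
    return("one category per polygon required")
  ok <- vapply(object@polygons, function(p)
    is.matrix(p) && ncol(p) == 2L && nrow(p) >= 4L, logical(1))
  if (length(ok) && !all(ok))
    return("polygons must be closed-ring n x 2 matrices (n >= 4)")
  TRUE
})

#' Presence-background model configuration
#'
#' Defaults follow the study protocol: 10 bootstrap replicates, 10000
#' background points, an iteration cap of 500, and a 75/25 train/test split
#' of each bootstrap resample.
#'
#' @slot nBackground background sample size per replicate.
#' @slot nReplicates number of bootstrap replicates.
#' @slot maxIterations optimizer iteration cap.
#' @slot trainFraction fraction of each bootstrap resample used to train.
#' @slot regularization ridge penalty (glmnet lambda).
#' @slot seed integer RNG seed for resampling and background draws.
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(nBackground = "integer", nReplicates = "integer",
                 maxIterations = "integer", trainFraction = "numeric",
                 regularization = "numeric", seed = "integer"))

setValidity("ModelConfig", function(object) {
  msg <- character(0)
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    msg <- c(msg, "trainFraction must be in (0, 1)")
  if (object@regularization < 0) msg <- c(msg, "regularization must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ModelConfig-class
#' @param nBackground,nReplicates,maxIterations,trainFraction,regularization,seed
#'   see slot documentation.
#' @export
modelConfig <- function(nBackground = 10000L, nReplicates = 10L,
                        maxIterations = 500L, trainFraction = 0.75,
                        regularization = 0.01, seed = 1L) {
  new("ModelConfig", nBackground = as.integer(nBackground),
      nReplicates = as.integer(nReplicates),
      maxIterations = as.integer(maxIterations),
      trainFraction = as.numeric(trainFraction),
      regularization = as.numeric(regularization), seed = as.integer(seed))
}

#' Fitted presence-background suitability ensemble
#'
#' Bootstrap-replicated ridge-penalized presence-background logistic models
#' over linear + quadratic features of the predictor stack. Per replicate
#' the coefficient vector, the train/test presence indices, the test AUC and
#' a convergence flag are retained.
#'
#' @slot replicates list of per-replicate fits.
#' @slot varNames character, predictor names the ensemble was fitted on.
#' @slot config the \linkS4class{ModelConfig} used.
#' @exportClass SuitabilityEnsemble
setClass("SuitabilityEnsemble",
  representation(replicates = "list", varNames = "character",
                 config = "ModelConfig"))

setValidity("SuitabilityEnsemble", function(object) {
  if (length(object@replicates) != object@config@nReplicates)
    return("replicate count must match config")
  TRUE
})

#' Binarization threshold rule
#'
#' Either the 10th-percentile training-presence rule or the mean presence
#' suitability rule, with the resolved threshold value. Cells with
#' suitability >= value are classed suitable.
#'
#' @slot method "p10_training_presence" or "mean_presence_suitability".
#' @slot value resolved threshold in [0, 1].
#' @exportClass BinaryThresholdRule
setClass("BinaryThresholdRule",
  representation(method = "character", value = "numeric"))

setValidity("BinaryThresholdRule", function(object) {
  if (!object@method %in% c("p10_training_presence",
                            "mean_presence_suitability"))
    return("unknown threshold method")
  if (object@value < 0 || object@value > 1)
    return("threshold value must lie in [0, 1]")
  TRUE
})

#' Resistance surface
#'
#' A \linkS4class{RasterGrid} of per-cell movement resistance in [1, 10],
#' with provenance describing the suitability-to-resistance transform.
#'
#' @slot provenance list recording the source and transform parameters.
#' @exportClass ResistanceSurface
setClass("ResistanceSurface", contains = "RasterGrid",
  representation(provenance = "list"))

#' Resistant-kernel surface
#'
#' Summed per-source dispersal kernels: each source contributes
#' \code{max(0, 1 - cost/D)} at every cell, where cost is the accumulated
#' least-cost distance from the source and D the dispersal threshold in cost
#' units (resistance-weighted meters).
#'
#' @slot threshold dispersal threshold D in cost units.
#' @slot sources numeric matrix of source (x, y) coordinates.
#' @exportClass KernelSurface
setClass("KernelSurface", contains = "RasterGrid",
  representation(threshold = "numeric", sources = "matrix"))

#' Labelled habitat patches
#'
#' 8-connected components of a binary habitat surface. The label grid holds
#' integer patch ids (0 = background); the table one row per patch with cell
#' count, area (km^2), strength (summed kernel value, when delineated from a
#' kernel surface) and centroid.
#'
#' @slot labels integer \linkS4class{RasterGrid} of patch ids.
#' @slot table data.frame of per-patch records.
#' @slot status "ok", "empty" (no positive cells) or "degenerate"
#'   (constant field, strict percentile cut removes everything).
#' @exportClass PatchSet
setClass("PatchSet",
  representation(labels = "RasterGrid", table = "data.frame",
                 status = "character"))

#' Patch graph for probability-of-connectivity analysis
#'
#' Nodes are patches (or conservation areas) with positive attribute a_i
#' (area or strength); pairwise Euclidean edge-to-edge distances d_ij feed a
#' negative-exponential dispersal probability p_ij = exp(-k d_ij) calibrated
#' so that p(dMed) = pMed. AL is the total landscape attribute (e.g. area)
#' entering the PC denominator.
#'
#' @slot id integer node ids.
#' @slot attr numeric positive node attributes.
#' @slot dist numeric symmetric distance matrix (meters).
#' @slot pMed,dMed dispersal-probability calibration: p(dMed) = pMed.
#' @slot AL landscape total attribute.
#' @exportClass PatchGraph
setClass("PatchGraph",
  representation(id = "integer", attr = "numeric", dist = "matrix",
                 pMed = "numeric", dMed = "numeric", AL = "numeric"))

setValidity("PatchGraph", function(object) {
  msg <- character(0)
  n <- length(object@id)
  if (length(object@attr) != n) msg <- c(msg, "one attribute per node")
  if (any(object@attr <= 0)) msg <- c(msg, "node attributes must be positive")
  if (!all(dim(object@dist) == c(n, n)))
    msg <- c(msg, "dist must be n x n")
  if (n && isTRUE(any(abs(object@dist - t(object@dist)) > 1e-8,
                      na.rm = TRUE)))  # Inf - Inf is NaN, still symmetric
    msg <- c(msg, "dist must be symmetric")
  if (object@pMed <= 0 || object@pMed >= 1)
    msg <- c(msg, "pMed must lie in (0, 1)")
  if (object@dMed <= 0) msg <- c(msg, "dMed must be positive")
  if (object@AL <= 0) msg <- c(msg, "AL must be positive")
  if (length(msg)) msg else TRUE
})

#' Full-pipeline configuration
#'
#' Defaults reproduce the study protocol: focal extents
#' {100, 500, 1000, 2000, 4000} m, dispersal thresholds
#' {50000, ..., 250000} cost units, 70th-percentile cores, and the model
#' defaults of \code{\link{modelConfig}}.
#'
#' @slot spec synthetic \linkS4class{LandscapeSpec} driving input generation.
#' @slot truth \linkS4class{TrueModel} generating occurrences.
#' @slot nOccurrences number of simulated presence records.
#' @slot extents focal radii (m) for the multi-extent analysis.
#' @slot dispersalThresholds kernel thresholds (cost units).
#' @slot kernelPercentile percentile defining core habitat.
#' @slot bufferWidth least-cost-path buffer (m).
#' @slot model \linkS4class{ModelConfig}.
#' @slot pMed,dMed dispersal-probability calibration for dPC.
#' @slot seed master seed.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(spec = "LandscapeSpec", truth = "TrueModel",
                 nOccurrences = "integer", extents = "numeric",
                 dispersalThresholds = "numeric",
                 kernelPercentile = "numeric", bufferWidth = "numeric",
                 model = "ModelConfig", pMed = "numeric", dMed = "numeric",
                 seed = "integer"))
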