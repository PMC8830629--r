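#' @include AllClasses.R utils.R raster-core.R
NULL

#' Transform habitat suitability into movement resistance
#'
#' Applies the negative-exponential transform \code{R_raw = 1000^(-HS)} and
#' linearly rescales the transform's analytic codomain
#' [1000^-1, 1000^0] = [0.001, 1] to [1, 10], so that resistance is exactly
#' 1 where suitability is 1 and exactly 10 where suitability is 0,
#' independently of the particular map. One cost unit then equals one
#' resistance-weighted meter of traversal.
#'
#' @param hs suitability \linkS4class{RasterGrid} with values in [0, 1].
#' @return A \linkS4class{ResistanceSurface} (values in [1, 10]).
#' @examples
#' hs <- rasterGrid(matrix(c(0, 0.5, 1), 1, 3), cellSize = 100)
#' gridValues(suitabilityToResistance(hs))  # 10, 1.276, 1
#' @export
suitabilityToResistance <- function(hs) {
  v <- hs@values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  rRaw <- 1000^(-v)
  lo <- 1000^-1; hi <- 1000^0
  r <- 1 + 9 * (rRaw - lo) / (hi - lo)
  new("ResistanceSurface",
      rasterGrid(r, hs@cellSize, hs@origin, hs@crs),
      provenance = list(transform = "1000^(-HS), rescaled to [1,10]",
                        base = 1000, range = c(1, 10)))
}

# 8-neighbour cost lattice as an igraph: vertices are all cells
# (column-major index), edges only between non-nodata neighbours, edge cost
# = mean resistance of the two cells times the centre-to-centre distance
# (cellSize orthogonally, cellSize * sqrt(2) diagonally).
latticeGraph <- function(resistance) {
  v <- resistance@values
  nr <- nrow(v); nc <- ncol(v); cs <- resistance@cellSize
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list(); weights <- list(); e <- 0L
  shifts <- list(c(0L, 1L, 1), c(1L, 0L, 1), c(1L, 1L, sqrt(2)),
                 c(1L, -1L, sqrt(2)))
  for (s in shifts) {
    di <- s[1]; dj <- s[2]; dl <- s[3]
    ri <- seq_len(nr - di)
    cj <- if (dj >= 0) seq_len(nc - dj) else seq.int(1 - dj, nc)
    a <- as.vector(idx[ri, cj, drop = FALSE])
    b <- as.vector(idx[ri + di, cj + dj, drop = FALSE])
    ok <- !is.na(v[a]) & !is.na(v[b])
    if (!any(ok)) next
    e <- e + 1L
    edges[[e]] <- rbind(a[ok], b[ok])
    weights[[e]] <- (v[a][ok] + v[b][ok]) / 2 * cs * dl
  }
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  if (e > 0L) {
    g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
    igraph::E(g)$weight <- unlist(weights)
  }
  g
}

# Resolve sources given as OccurrenceSet / coordinate matrix / cell indices
# to cell indices; error on nodata or out-of-grid sources.
resolveSources <- function(resistance, sources) {
  cells <- if (is(sources, "OccurrenceSet"))
    coordsToCells(resistance, occCoords(sources))
  else if (is.matrix(sources) && ncol(sources) == 2L)
    coordsToCells(resistance, sources)
  else as.integer(sources)
  if (any(is.na(cells)) || any(cells < 1L) ||
      any(cells > length(resistance@values)))
    stop("source location outside the grid")
  if (any(is.na(resistance@values[cells])))
    stop("source located on a nodata cell")
  cells
}

#' Accumulated cost distance from source cells
#'
#' Dijkstra's algorithm on the 8-neighbour lattice: the minimal accumulated
#' cost (in cost units = resistance-weighted meters) from each source to
#' every cell. Cells beyond \code{maxCost}, and cells unreachable from a
#' source, carry \code{Inf}.
#'
#' @param resistance a \linkS4class{ResistanceSurface} (or any
#'   \linkS4class{RasterGrid} of per-cell resistance).
#' @param sources an \linkS4class{OccurrenceSet}, an n x 2 coordinate
#'   matrix, or a vector of cell indices.
#' @param maxCost cost cutoff (default \code{Inf}).
#' @return For a single source, a \linkS4class{RasterGrid} of accumulated
#'   cost; for several, a (sources x cells) matrix (cells column-major).
#' @export
costDistance <- function(resistance, sources, maxCost = Inf) {
  cells <- resolveSources(resistance, sources)
  g <- latticeGraph(resistance)
  d <- igraph::distances(g, v = cells, mode = "out",
                         algorithm = "dijkstra")
  d[d > maxCost] <- Inf
  d[, is.na(as.vector(resistance@values))] <- NA_real_
  if (length(cells) == 1L)
    return(rasterGrid(matrix(d[1L, ], nrow(resistance@values),
                             ncol(resistance@values)),
                      resistance@cellSize, resistance@origin,
                      resistance@crs))
  d
}

#' Resistant-kernel connectivity surface
#'
#' Around each source point the dispersal kernel
#' \code{K_s(x) = max(0, 1 - c_s(x)/D)} decays linearly from 1 at the
#' source to 0 at accumulated cost \code{D} (the dispersal threshold in
#' cost units); the surface is the sum over sources — an incidence
#' function of expected movement rate through every cell.
#'
#' @param resistance resistance surface.
#' @param sources sources (see \code{\link{costDistance}}).
#' @param D dispersal threshold in cost units (> 0), e.g. 50000 cost units
#'   for a 50 km reach through optimal habitat.
#' @param decay "linear" (default) or "gaussian"
#'   (\code{exp(-(c/D)^2 * log(20))}, clipped to 0 at \code{c >= D}).
#' @return A \linkS4class{KernelSurface}.
#' @export
resistantKernel <- function(resistance, sources, D,
                            decay = c("linear", "gaussian")) {
  decay <- match.arg(decay)
  if (D <= 0) stop("dispersal threshold D must be positive")
  cells <- resolveSources(resistance, sources)
  d <- igraph::distances(latticeGraph(resistance), v = cells, mode = "out",
                         algorithm = "dijkstra")
  K <- if (decay == "linear") {
    kk <- 1 - d / D
    kk[kk < 0] <- 0
    kk
  } else ifelse(d < D, exp(-(d / D)^2 * log(20)), 0)
  if (!is.matrix(K)) K <- matrix(K, nrow = length(cells))
  k <- colSums(K)
  k[is.na(as.vector(resistance@values))] <- NA_real_
  srcXY <- cellCenters(resistance)[cells, , drop = FALSE]
  new("KernelSurface",
      rasterGrid(matrix(k, nrow(resistance@values),
                        ncol(resistance@values)),
                 resistance@cellSize, resistance@origin, resistance@crs),
      threshold = as.numeric(D), sources = srcXY)
}

#' Maximum geodesic reach of a dispersal threshold
#'
#' Under the cost-unit convention (1 cost unit = 1 resistance-weighted
#' meter), a threshold of D cost units lets an individual travel
#' \code{D / R} meters through habitat of uniform resistance R; e.g.
#' 50000 cost units correspond to 50 km through optimal habitat (R = 1).
#'
#' @param D dispersal threshold in cost units.
#' @param resistance uniform resistance value (default 1, optimal habitat).
#' @return reach in meters.
#' @export
maxReach <- function(D, resistance = 1) D / resistance

#' Least-cost path between two points
#'
#' The minimal accumulated-cost 8-connected route between two locations
#' under the mean-resistance edge-cost rule. Cost ties are resolved
#' deterministically (a single path is returned for fixed inputs).
#'
#' @param resistance resistance surface.
#' @param a,b (x, y) coordinates or cell indices; must differ.
#' @return list with \code{cells} (ordered cell indices), \code{coords}
#'   (ordered cell-centre coordinates) and \code{cost} (total cost units).
#' @export
leastCostPath <- function(resistance, a, b) {
  ca <- resolveSources(resistance, if (length(a) == 2L && !is.matrix(a))
    matrix(a, 1) else a)
  cb <- resolveSources(resistance, if (length(b) == 2L && !is.matrix(b))
    matrix(b, 1) else b)
  if (ca == cb) stop("endpoints coincide")
  g <- latticeGraph(resistance)
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = ca, to = cb, mode = "out",
                           output = "vpath"))
  cells <- as.integer(sp$vpath[[1]])
  if (length(cells) == 0L)
    stop("no path exists between the endpoints (nodata barrier)")
  cost <- as.numeric(igraph::distances(g, v = ca, to = cb))
  list(cells = cells,
       coords = cellCenters(resistance)[cells, , drop = FALSE],
       cost = cost)
}

#' Factorial least-cost-path corridor surface
#'
#' Computes the least-cost path for every unordered pair of source points
#' (no dispersal threshold), buffers each path by \code{bufferWidth}
#' meters, and sums the buffered paths: the per-cell count of pairs whose
#' corridor passes through the cell (corridor strength).
#'
#' @param resistance resistance surface.
#' @param sources >= 2 sources (see \code{\link{costDistance}}).
#' @param bufferWidth buffer radius in meters around each path (default
#'   200 m, i.e. two cells at the 100 m analysis resolution).
#' @return A \linkS4class{RasterGrid} of corridor strength counts.
#' @export
factorialLcp <- function(resistance, sources, bufferWidth = 200) {
  cells <- unique(resolveSources(resistance, sources))
  if (length(cells) < 2L) stop("need at least two distinct sources")
  v <- resistance@values
  nr <- nrow(v); nc <- ncol(v); cs <- resistance@cellSize
  g <- latticeGraph(resistance)
  k <- floor(bufferWidth / cs + 1e-9)
  off <- expand.grid(di = -k:k, dj = -k:k)
  off <- off[(off$di^2 + off$dj^2) * cs^2 <= bufferWidth^2 + 1e-6, ]
  strength <- matrix(0, nr, nc)
  n <- length(cells)
  for (i in seq_len(n - 1L)) {
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = cells[i],
                             to = cells[(i + 1L):n], mode = "out",
                             output = "vpath"))
    for (p in sp$vpath) {
      pc <- as.integer(p)
      if (length(pc) == 0L) next
      pi <- (pc - 1L) %% nr + 1L
      pj <- (pc - 1L) %/% nr + 1L
      bi <- rep(pi, each = nrow(off)) + off$di
      bj <- rep(pj, each = nrow(off)) + off$dj
      ok <- bi >= 1L & bi <= nr & bj >= 1L & bj <= nc
      hit <- unique((bj[ok] - 1L) * nr + bi[ok])
      strength[hit] <- strength[hit] + 1
    }
  }
  strength[is.na(v)] <- NA_real_
  rasterGrid(strength, cs, resistance@origin, resistance@crs)
}
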