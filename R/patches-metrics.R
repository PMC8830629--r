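#' @include AllClasses.R utils.R raster-core.R
NULL

# 8-connected component labelling of a logical matrix via igraph
# components; labels are contiguous from 1 in order of first (column-major)
# cell appearance.
labelComponents <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(cells)) return(lab)
  pos <- integer(nr * nc)
  pos[cells] <- seq_along(cells)
  idx <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list(); e <- 0L
  for (s in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    di <- s[1]; dj <- s[2]
    ri <- seq_len(nr - di)
    cj <- if (dj >= 0) seq_len(nc - dj) else seq.int(1 - dj, nc)
    a <- as.vector(idx[ri, cj, drop = FALSE])
    b <- as.vector(idx[ri + di, cj + dj, drop = FALSE])
    ok <- mask[a] & mask[b]
    if (any(ok)) { e <- e + 1L; edges[[e]] <- rbind(pos[a[ok]], pos[b[ok]]) }
  }
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (e > 0L) g <- igraph::add_edges(g, as.vector(do.call(cbind, edges)))
  comp <- igraph::components(g)$membership
  # renumber so labels appear in order of first cell
  first <- tapply(seq_along(cells), comp, min)
  remap <- integer(length(first))
  remap[order(first)] <- seq_along(first)
  lab[cells] <- remap[comp]
  lab
}

#' Delineate core habitat patches from a kernel surface
#'
#' The core threshold is the stated percentile (default 70, linear
#' interpolation) of the kernel values over the positive-kernel support
#' (cells with K > 0; taking the percentile over all cells would let the
#' zero background swamp the distribution). Core cells are those with
#' K strictly above the threshold; 8-connected components become patches
#' with area (km^2), strength (summed kernel value) and centroid. A kernel
#' with no positive cells yields an empty PatchSet with status "empty"; a
#' constant positive kernel yields status "degenerate" (the strict cut
#' removes everything).
#'
#' @param kernel a \linkS4class{KernelSurface} (or kernel-valued grid).
#' @param percentile core percentile (default 70).
#' @param support "positive" (default) or "all" cells for the percentile.
#' @return A \linkS4class{PatchSet}.
#' @export
delineateCores <- function(kernel, percentile = 70,
                           support = c("positive", "all")) {
  support <- match.arg(support)
  v <- kernel@values
  emptyTable <- data.frame(id = integer(0), nCells = integer(0),
                           areaKm2 = numeric(0), strength = numeric(0),
                           centroidX = numeric(0), centroidY = numeric(0))
  emptySet <- function(status)
    new("PatchSet",
        labels = rasterGrid(matrix(0, nrow(v), ncol(v)), kernel@cellSize,
                            kernel@origin, kernel@crs),
        table = emptyTable, status = status)
  pool <- if (support == "positive") v[!is.na(v) & v > 0] else v[!is.na(v)]
  if (!length(pool)) return(emptySet("empty"))
  thr <- stats::quantile(pool, percentile / 100, type = 7, names = FALSE)
  mask <- !is.na(v) & v > thr
  if (!any(mask)) return(emptySet("degenerate"))
  lab <- labelComponents(mask)
  ids <- seq_len(max(lab))
  ctr <- cellCenters(kernel)
  cs <- kernel@cellSize
  tab <- do.call(rbind, lapply(ids, function(id) {
    cells <- which(lab == id)
    data.frame(id = id, nCells = length(cells),
               areaKm2 = length(cells) * cs^2 / 1e6,
               strength = sum(v[cells]),
               centroidX = mean(ctr[cells, 1]),
               centroidY = mean(ctr[cells, 2]))
  }))
  new("PatchSet",
      labels = rasterGrid(lab + 0, cs, kernel@origin, kernel@crs),
      table = tab, status = "ok")
}

binaryMask <- function(binary) {
  v <- binary@values
  if (any(!is.na(v) & !(v %in% c(0, 1))))
    stop("grid is not binary (values other than 0/1 present)")
  !is.na(v) & v == 1
}

#' Percentage of landscape in habitat (PLAND)
#'
#' @param binary binary habitat \linkS4class{RasterGrid} (1 = habitat).
#' @return percent of non-nodata cells that are habitat.
#' @export
pland <- function(binary) {
  mask <- binaryMask(binary)
  100 * sum(mask) / sum(!is.na(binary@values))
}

#' Number of habitat patches (NP)
#'
#' Count of 8-connected habitat components.
#' @param binary binary habitat grid.
#' @return integer patch count.
#' @export
numberOfPatches <- function(binary) {
  lab <- labelComponents(binaryMask(binary))
  max(lab)
}

#' Largest patch index (LPI)
#'
#' Size of the largest 8-connected habitat patch as a percentage of the
#' landscape (non-nodata cells). Always <= PLAND.
#' @param binary binary habitat grid.
#' @return percent.
#' @export
lpi <- function(binary) {
  lab <- labelComponents(binaryMask(binary))
  if (max(lab) == 0L) return(0)
  100 * max(tabulate(lab[lab > 0L])) / sum(!is.na(binary@values))
}

#' Correlation length (area-weighted mean radius of gyration)
#'
#' Per patch, the radius of gyration is the mean distance of its cell
#' centres to the patch centroid; the correlation length is the
#' area-weighted mean over patches — the expected distance an individual
#' placed at random in a random habitat patch can move before hitting the
#' patch boundary.
#'
#' @param binary binary habitat grid.
#' @return correlation length in meters (0 with status attribute when no
#'   habitat is present).
#' @export
correlationLength <- function(binary) {
  mask <- binaryMask(binary)
  lab <- labelComponents(mask)
  if (max(lab) == 0L) {
    out <- 0
    attr(out, "status") <- "no habitat"
    return(out)
  }
  ctr <- cellCenters(binary)
  gy <- vapply(seq_len(max(lab)), function(id) {
    cells <- which(lab == id)
    cx <- mean(ctr[cells, 1]); cy <- mean(ctr[cells, 2])
    mean(sqrt((ctr[cells, 1] - cx)^2 + (ctr[cells, 2] - cy)^2))
  }, numeric(1))
  a <- tabulate(lab[lab > 0L])
  sum(gy * a) / sum(a)
}
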