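#' @include AllClasses.R utils.R patches-metrics.R
NULL

# Ray-casting point-in-polygon for a closed ring; boundary handling is
# irrelevant here because polygon edges snap to cell boundaries while test
# points are cell centres.
pointsInRing <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Minimum pairwise Euclidean distance between two point sets, chunked.
minCrossDist <- function(A, B) {
  best <- Inf
  step <- 2000L
  for (s in seq(1L, nrow(A), by = step)) {
    idx <- s:min(s + step - 1L, nrow(A))
    d2 <- outer(A[idx, 1], B[, 1], "-")^2 + outer(A[idx, 2], B[, 2], "-")^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

#' Build a patch graph for connectivity prioritization
#'
#' Nodes are the patches of a \linkS4class{PatchSet} with attribute a_i =
#' area (km^2) or strength (summed kernel value). Pairwise distances are
#' edge-to-edge: the minimal Euclidean distance between cell centres of the
#' two patches. Direct dispersal probabilities follow the negative
#' exponential \code{p_ij = exp(-k d_ij)} with \code{k = -ln(pMed)/dMed},
#' so that \code{p(dMed) = pMed}.
#'
#' @param patches a \linkS4class{PatchSet} with >= 1 patch.
#' @param attribute "area" or "strength".
#' @param pMed probability at the calibration distance (default 0.5).
#' @param dMed calibration distance in meters (e.g. the median dispersal
#'   distance of the species).
#' @param AL landscape total attribute; defaults to the total non-nodata
#'   landscape area in km^2 for "area", and the summed patch strength for
#'   "strength" (dPC is ratio-based, so only relative scale matters).
#' @return A \linkS4class{PatchGraph}.
#' @export
buildPatchGraph <- function(patches, attribute = c("area", "strength"),
                            pMed = 0.5, dMed, AL = NULL) {
  attribute <- match.arg(attribute)
  tab <- patches@table
  if (!nrow(tab)) stop("patch set is empty")
  a <- if (attribute == "area") tab$areaKm2 else tab$strength
  if (any(a <= 0)) stop("non-positive patch attribute")
  lab <- patches@labels@values
  ctr <- cellCenters(patches@labels)
  pts <- lapply(tab$id, function(id) ctr[which(lab == id), , drop = FALSE])
  n <- nrow(tab)
  d <- matrix(0, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- minCrossDist(pts[[i]], pts[[j]])
  if (is.null(AL))
    AL <- if (attribute == "area")
      sum(!is.na(lab)) * patches@labels@cellSize^2 / 1e6
    else sum(tab$strength)
  new("PatchGraph", id = as.integer(tab$id), attr = a, dist = d,
      pMed = as.numeric(pMed), dMed = as.numeric(dMed),
      AL = as.numeric(AL))
}

#' Construct a patch graph directly from node attributes and distances
#'
#' Convenience constructor used when nodes are not raster patches (e.g.
#' abstract graphs in simulation studies).
#'
#' @param attr positive node attributes.
#' @param dist symmetric distance matrix (meters).
#' @param pMed,dMed dispersal calibration, \code{p(dMed) = pMed}.
#' @param AL landscape total attribute.
#' @param id optional node ids.
#' @return A \linkS4class{PatchGraph}.
#' @export
patchGraph <- function(attr, dist, pMed = 0.5, dMed, AL,
                       id = seq_along(attr)) {
  new("PatchGraph", id = as.integer(id), attr = as.numeric(attr),
      dist = dist, pMed = as.numeric(pMed), dMed = as.numeric(dMed),
      AL = as.numeric(AL))
}

# Maximum-probability path matrix p*_ij: the max over paths of the product
# of step probabilities, computed as shortest paths over edge weights
# -ln(p_ij); diagonal is 1. Infinite distances (p = 0) contribute no edge.
maxProductProbability <- function(graph, keep = seq_along(graph@attr)) {
  k <- -log(graph@pMed) / graph@dMed
  d <- graph@dist[keep, keep, drop = FALSE]
  n <- nrow(d)
  if (n == 1L) return(matrix(1, 1, 1))
  w <- k * d
  # infinite distance means p = 0: no edge at all (0 in the adjacency);
  # finite zero distance still needs an edge, hence the tiny floor
  A <- ifelse(is.finite(w), pmax(w, 1e-300), 0)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  D <- igraph::distances(g, algorithm = "dijkstra")
  P <- exp(-D)
  diag(P) <- 1
  P
}

pcFromGraph <- function(graph, keep = seq_along(graph@attr)) {
  a <- graph@attr[keep]
  P <- maxProductProbability(graph, keep)
  sum(outer(a, a) * P) / graph@AL^2
}

#' Probability of connectivity (PC)
#'
#' \code{PC = sum_ij a_i a_j p*_ij / AL^2} over ordered node pairs
#' (including i = j with p*_ii = 1), where p*_ij is the maximum-probability
#' path between i and j. PC is the probability that two points placed at
#' random in the landscape both fall in habitat and are connected.
#'
#' @param graph a \linkS4class{PatchGraph}.
#' @return PC in (0, 1] (1 when a single patch covers the landscape).
#' @export
pcIndex <- function(graph) {
  validObject(graph)
  pcFromGraph(graph)
}

#' Per-node importance dPC
#'
#' \code{dPC_k = 100 (PC - PC_without_k) / PC}: the percent loss of the
#' probability of connectivity when node k is removed (its cells and every
#' path routing through it).
#'
#' @param graph a \linkS4class{PatchGraph}.
#' @param node optional node id; default computes all nodes.
#' @return named numeric vector of dPC percentages.
#' @export
dpc <- function(graph, node = NULL) {
  validObject(graph)
  pc <- pcFromGraph(graph)
  nodes <- if (is.null(node)) graph@id else node
  out <- vapply(nodes, function(k) {
    keep <- which(graph@id != k)
    pck <- if (length(keep)) pcFromGraph(graph, keep) else 0
    100 * (pc - pck) / pc
  }, numeric(1))
  stats::setNames(out, nodes)
}

#' dPC decomposition into intra, flux and connector fractions
#'
#' \code{dPCintra_k = 100 a_k^2 / (PC AL^2)} (the patch's own internal
#' connectivity), \code{dPCflux_k = 100 * 2 sum_{j != k} a_k a_j p*_kj /
#' (PC AL^2)} (dispersal flux between k and the rest), and
#' \code{dPCconnector_k = dPC_k - intra_k - flux_k} (the loss in other
#' pairs' best paths when k is removed — k's stepping-stone role). The
#' three fractions sum to dPC by construction.
#'
#' @param graph a \linkS4class{PatchGraph}.
#' @return data.frame with columns id, dPC, dPCintra, dPCflux,
#'   dPCconnector.
#' @export
dpcFractions <- function(graph) {
  validObject(graph)
  pc <- pcFromGraph(graph)
  P <- maxProductProbability(graph)
  a <- graph@attr
  dpcAll <- dpc(graph)
  intra <- 100 * a^2 / (pc * graph@AL^2)
  flux <- vapply(seq_along(a), function(k)
    100 * 2 * sum(a[k] * a[-k] * P[k, -k]) / (pc * graph@AL^2), numeric(1))
  data.frame(id = graph@id, dPC = as.numeric(dpcAll), dPCintra = intra,
             dPCflux = flux, dPCconnector = as.numeric(dpcAll) - intra - flux)
}

#' Rank patches by dPC
#'
#' Descending dPC; ties broken by the larger attribute, then the lower id.
#'
#' @param graph a \linkS4class{PatchGraph}.
#' @return data.frame with columns rank, id, attr, dPC.
#' @export
rankPatches <- function(graph) {
  d <- dpc(graph)
  ord <- order(-d, -graph@attr, graph@id)
  data.frame(rank = seq_along(ord), id = graph@id[ord],
             attr = graph@attr[ord], dPC = as.numeric(d[ord]))
}

#' Conservation-area coverage of target habitat (gap analysis)
#'
#' The covered percentage is the share of target cells (core-patch cells or
#' binary habitat cells) whose centres fall inside conservation-area
#' polygons, reported per category, per polygon, and in total. Empty
#' targets yield 0 percent with a status flag.
#'
#' @param targets a \linkS4class{PatchSet} or binary
#'   \linkS4class{RasterGrid}.
#' @param cas a \linkS4class{ConservationAreas} object.
#' @return list with \code{total} (percent), \code{byCategory}
#'   (data.frame category/percent), \code{byCA} (data.frame id, category,
#'   percent) and \code{status}.
#' @export
gapCoverage <- function(targets, cas) {
  grid <- if (is(targets, "PatchSet")) targets@labels else targets
  mask <- if (is(targets, "PatchSet")) grid@values > 0 & !is.na(grid@values)
  else binaryMask(targets)
  nTarget <- sum(mask)
  cats <- c("wildlife_refuge", "protected_area", "non_hunting_area")
  catTab <- data.frame(category = cats, percent = 0)
  if (nTarget == 0L)
    return(list(total = 0, byCategory = catTab,
                byCA = data.frame(id = integer(0), category = character(0),
                                  percent = numeric(0)),
                status = "no target cells"))
  ctr <- cellCenters(grid)[which(mask), , drop = FALSE]
  inAny <- rep(FALSE, nrow(ctr))
  perCA <- numeric(length(cas@polygons))
  inCat <- stats::setNames(rep(list(rep(FALSE, nrow(ctr))), length(cats)),
                           cats)
  for (i in seq_along(cas@polygons)) {
    inside <- pointsInRing(ctr[, 1], ctr[, 2], cas@polygons[[i]])
    perCA[i] <- 100 * sum(inside) / nTarget
    inAny <- inAny | inside
    cat <- cas@category[i]
    if (cat %in% cats) inCat[[cat]] <- inCat[[cat]] | inside
  }
  catTab$percent <- vapply(cats, function(cat)
    100 * sum(inCat[[cat]]) / nTarget, numeric(1))
  list(total = 100 * sum(inAny) / nTarget, byCategory = catTab,
       byCA = data.frame(id = seq_along(perCA), category = cas@category,
                         percent = perCA),
       status = "ok")
}

#' Prioritize conservation areas as habitat patches
#'
#' Each conservation area is treated as a patch whose attribute is the
#' extent (km^2) of suitable habitat inside it; areas with no suitable
#' habitat are excluded with a warning (a zero attribute is not a valid
#' graph node). Distances are edge-to-edge between the suitable cells of
#' each area, and the dPC decomposition is computed per area.
#'
#' @param cas a \linkS4class{ConservationAreas} object.
#' @param suitable binary suitable-habitat \linkS4class{RasterGrid}.
#' @param pMed,dMed dispersal calibration (see
#'   \code{\link{buildPatchGraph}}).
#' @return data.frame: id, category, areaKm2 (suitable extent), dPC and
#'   fractions; attribute \code{excluded} lists dropped area ids.
#' @export
caPrioritization <- function(cas, suitable, pMed = 0.5, dMed) {
  if (!length(cas@polygons)) stop("at least one conservation area required")
  mask <- binaryMask(suitable)
  ctrAll <- cellCenters(suitable)
  suitIdx <- which(mask)
  ctr <- ctrAll[suitIdx, , drop = FALSE]
  cs <- suitable@cellSize
  pts <- list(); attr <- numeric(0); keep <- integer(0)
  for (i in seq_along(cas@polygons)) {
    inside <- pointsInRing(ctr[, 1], ctr[, 2], cas@polygons[[i]])
    if (!any(inside)) next
    keep <- c(keep, i)
    pts[[length(pts) + 1L]] <- ctr[inside, , drop = FALSE]
    attr <- c(attr, sum(inside) * cs^2 / 1e6)
  }
  excluded <- setdiff(seq_along(cas@polygons), keep)
  if (length(excluded))
    warning("conservation area(s) with no suitable habitat excluded: ",
            paste(excluded, collapse = ", "))
  if (!length(keep))
    stop("no conservation area contains suitable habitat")
  n <- length(keep)
  d <- matrix(0, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- minCrossDist(pts[[i]], pts[[j]])
  AL <- sum(!is.na(suitable@values)) * cs^2 / 1e6
  g <- patchGraph(attr, d, pMed = pMed, dMed = dMed, AL = AL, id = keep)
  out <- dpcFractions(g)
  out <- cbind(out[, "id", drop = FALSE],
               category = cas@category[keep], areaKm2 = attr,
               out[, c("dPC", "dPCintra", "dPCflux", "dPCconnector")])
  attr(out, "excluded") <- excluded
  out
}
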