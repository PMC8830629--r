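#' @include AllClasses.R utils.R
NULL

#' Read / write ESRI ASCII grids
#'
#' Plain-text single-band raster I/O in the ESRI ASCII grid dialect
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value header followed by
#' row-major values, top row first). Values round-trip exactly: they are
#' written with full double precision. Only square cells are supported;
#' a file declaring dx != dy (via \code{dx}/\code{dy} keywords) is rejected.
#'
#' @param path file path.
#' @return \code{readAsciiGrid}: a \linkS4class{RasterGrid};
#'   \code{writeAsciiGrid}: the path, invisibly.
#' @examples
#' g <- rasterGrid(matrix(runif(9), 3, 3), cellSize = 100)
#' p <- tempfile(fileext = ".asc")
#' writeAsciiGrid(g, p)
#' identical(gridValues(readAsciiGrid(p)), gridValues(g))
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path, n = 7L)
  hdr <- list(); nHdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2L && is.na(suppressWarnings(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2]); nHdr <- nHdr + 1L
    } else break
  }
  if (any(c("dx", "dy") %in% names(hdr)))
    stop("non-square cells (dx/dy header) are not supported; ",
         "resample to square cells first")
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header fields ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(path, what = numeric(), skip = nHdr, quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d", nr * nc, length(vals)))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0
  rasterGrid(m, cellSize = hdr$cellsize,
             origin = c(xll, yll + nr * hdr$cellsize))
}

#' @rdname readAsciiGrid
#' @param grid a \linkS4class{RasterGrid}.
#' @export
writeAsciiGrid <- function(grid, path) {
  v <- grid@values
  nr <- nrow(v); nc <- ncol(v); cs <- grid@cellSize
  nodata <- -9999
  if (any(!is.na(v) & v == nodata)) nodata <- -3.4e38
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
               sprintf("xllcorner %.10g", grid@origin[1]),
               sprintf("yllcorner %.10g", grid@origin[2] - nr * cs),
               sprintf("cellsize %.10g", cs),
               sprintf("NODATA_value %.10g", nodata)), con)
  out <- v
  out[is.na(out)] <- nodata
  writeLines(apply(out, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Circular moving-window (focal) mean
#'
#' Replaces each cell by the mean of all cells whose centres lie within
#' \code{radius} meters of the focal cell centre (centre-distance membership,
#' the focal cell always included). Nodata cells are ignored in the mean and
#' the window shrinks at the landscape edge, so no padding bias is
#' introduced. Nodata cells stay nodata. This is the multi-extent smoothing
#' step: re-expressing each predictor as its neighbourhood mean at a chosen
#' analysis extent.
#'
#' @param grid a \linkS4class{RasterGrid}.
#' @param radius window radius in meters; a radius smaller than half a cell
#'   leaves the grid unchanged (with a warning).
#' @return A \linkS4class{RasterGrid} of focal means.
#' @export
focalMeanCircular <- function(grid, radius) {
  if (radius < 0) stop("radius must be >= 0")
  cs <- grid@cellSize
  if (radius < cs / 2) {
    warning("radius smaller than half a cell; returning the grid unchanged")
    return(grid)
  }
  v <- grid@values
  nr <- nrow(v); nc <- ncol(v)
  k <- floor(radius / cs + 1e-9)
  off <- expand.grid(di = -k:k, dj = -k:k)
  keep <- (off$di^2 + off$dj^2) * cs^2 <= radius^2 + 1e-6
  off <- off[keep, ]
  kern <- matrix(0, 2 * k + 1, 2 * k + 1)
  kern[cbind(off$di + k + 1, off$dj + k + 1)] <- 1
  mask <- !is.na(v)
  v0 <- ifelse(mask, v, 0)
  sums <- zeroPadConvolve(v0, kern)
  counts <- zeroPadConvolve(mask * 1, kern)
  out <- ifelse(counts > 0.5, sums / pmax(counts, 0.5), NA_real_)
  out[!mask] <- NA_real_
  rasterGrid(out, cs, grid@origin, grid@crs)
}

# Zero-padded linear convolution with a centered (2k+1)^2 kernel via FFT.
zeroPadConvolve <- function(m, kern) {
  nr <- nrow(m); nc <- ncol(m)
  kk <- (nrow(kern) - 1L) / 2L
  pr <- nr + 2L * kk; pc <- nc + 2L * kk
  A <- matrix(0, pr, pc); A[seq_len(nr), seq_len(nc)] <- m
  K <- matrix(0, pr, pc)
  K[seq_len(nrow(kern)), seq_len(ncol(kern))] <- kern
  res <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) /
    (pr * pc)
  # the valid window, aligned so the kernel centre sits on each cell
  res[kk + seq_len(nr), kk + seq_len(nc)]
}

#' Greedy Pearson collinearity screening
#'
#' Computes the pairwise Pearson correlation matrix over cells where all
#' members of a pair are non-nodata, then greedily resolves collinearity:
#' while any pair exceeds \code{|r| > threshold}, the worst offending pair
#' is found and the member with the larger mean absolute correlation to all
#' other retained variables is dropped. Zero-variance layers cannot be
#' screened; they are flagged and retained with a warning.
#'
#' @param stack named list of \linkS4class{RasterGrid} predictors.
#' @param threshold absolute correlation cut (default 0.8).
#' @return list with \code{retained} (names), \code{dropped} (names),
#'   \code{flagged} (zero-variance names) and \code{correlation} (matrix).
#' @export
pearsonScreen <- function(stack, threshold = 0.8) {
  X <- stackMatrix(stack)
  nm <- colnames(X)
  if (ncol(X) < 2L) stop("need at least two variables to screen")
  sds <- apply(X, 2L, stats::sd, na.rm = TRUE)
  flagged <- nm[!is.finite(sds) | sds == 0]
  if (length(flagged))
    warning("zero-variance variable(s) retained unscreened: ",
            paste(flagged, collapse = ", "))
  R <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
  active <- setdiff(nm, flagged)
  dropped <- character(0)
  repeat {
    if (length(active) < 2L) break
    Ra <- abs(R[active, active, drop = FALSE])
    diag(Ra) <- 0
    if (max(Ra, na.rm = TRUE) <= threshold) break
    worst <- which(Ra == max(Ra, na.rm = TRUE), arr.ind = TRUE)[1L, ]
    cand <- active[worst]
    meanAbs <- vapply(cand, function(v)
      mean(Ra[v, setdiff(active, v)], na.rm = TRUE), numeric(1))
    drop <- cand[which.max(meanAbs)]
    dropped <- c(dropped, drop)
    active <- setdiff(active, drop)
  }
  list(retained = c(active, flagged)[order(match(c(active, flagged), nm))],
       dropped = dropped, flagged = flagged, correlation = R)
}

#' Moran's I from a value vector and a weight matrix
#'
#' The classic global Moran statistic
#' \code{I = (n/S0) * sum_ij w_ij z_i z_j / sum_i z_i^2} with \code{z}
#' mean-centred values and \code{S0 = sum(w)}, plus expectation
#' \code{E[I] = -1/(n-1)}, standard deviation under the normality
#' assumption, and the resulting z-score. A constant value vector has no
#' defined I; the result carries \code{status = "undefined"}.
#'
#' @param values numeric vector of unit values (e.g. point counts per cell).
#' @param weights n x n non-negative weight matrix, zero diagonal.
#' @return list with \code{I}, \code{expected}, \code{sd}, \code{zScore},
#'   \code{status}.
#' @export
moranStatistic <- function(values, weights) {
  n <- length(values)
  if (n < 2L) stop("need at least two units")
  if (!all(dim(weights) == c(n, n))) stop("weight matrix must be n x n")
  z <- values - mean(values)
  s2 <- sum(z^2)
  if (s2 == 0)
    return(list(I = NA_real_, expected = -1 / (n - 1), sd = NA_real_,
                zScore = NA_real_, status = "undefined"))
  W <- weights
  diag(W) <- 0
  S0 <- sum(W)
  I <- (n / S0) * sum(W * outer(z, z)) / s2
  EI <- -1 / (n - 1)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  varI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  sdI <- sqrt(max(varI, 0))
  list(I = I, expected = EI, sd = sdI, zScore = (I - EI) / sdI,
       status = "ok")
}

#' Global Moran's I of an occurrence point pattern
#'
#' Points are binned to counts on an aggregation grid laid over the
#' landscape; the Moran statistic is evaluated on the per-cell counts with
#' inverse-distance weights \code{w_ij = 1/d_ij} between aggregation-cell
#' centres. The weighting scheme and count value field are this package's
#' documented convention for screening occurrence data for spatial
#' autocorrelation; |z| < 1.96 indicates no significant autocorrelation at
#' the 5 percent level.
#'
#' @param occurrences an \linkS4class{OccurrenceSet}.
#' @param grid a \linkS4class{RasterGrid} supplying the landscape geometry.
#' @param aggregationCell aggregation cell size in meters (default 10x the
#'   grid cell).
#' @return list as \code{\link{moranStatistic}}, plus \code{counts} and
#'   \code{n} (number of aggregation cells).
#' @export
moransI <- function(occurrences, grid, aggregationCell = 10 * cellSize(grid)) {
  xy <- occCoords(occurrences)
  nr <- nrow(grid@values); nc <- ncol(grid@values); cs <- grid@cellSize
  nAr <- max(1L, ceiling(nr * cs / aggregationCell))
  nAc <- max(1L, ceiling(nc * cs / aggregationCell))
  ai <- pmin(pmax(floor((grid@origin[2] - xy[, 2]) / aggregationCell) + 1, 1), nAr)
  aj <- pmin(pmax(floor((xy[, 1] - grid@origin[1]) / aggregationCell) + 1, 1), nAc)
  counts <- matrix(0, nAr, nAc)
  for (k in seq_along(ai))
    counts[ai[k], aj[k]] <- counts[ai[k], aj[k]] + 1
  if (sum(counts > 0) < 2L)
    stop("need at least two occupied aggregation cells")
  cx <- grid@origin[1] + (rep(seq_len(nAc), each = nAr) - 0.5) * aggregationCell
  cy <- grid@origin[2] - (rep(seq_len(nAr), times = nAc) - 0.5) * aggregationCell
  d <- as.matrix(stats::dist(cbind(cx, cy)))
  W <- ifelse(d > 0, 1 / d, 0)
  res <- moranStatistic(as.vector(counts), W)
  res$counts <- counts
  res$n <- length(counts)
  res
}

#' Euclidean distance to the nearest feature cell
#'
#' For a binary feature raster (1 = feature), returns per-cell centre-to-
#' nearest-feature-cell-centre Euclidean distance in meters (exact distance
#' transform). Nodata cells in the input stay nodata; feature cells get 0.
#'
#' @param features a \linkS4class{RasterGrid} with values in {0, 1}.
#' @return A \linkS4class{RasterGrid} of distances (m).
#' @export
distanceToFeatures <- function(features) {
  v <- features@values
  feat <- !is.na(v) & v != 0
  if (!any(feat)) stop("no feature cells in input")
  m <- matrix(1, nrow(v), ncol(v))
  m[feat] <- 0
  d <- EBImage::distmap(m, metric = "euclidean")
  out <- as.matrix(d) * features@cellSize
  out[is.na(v)] <- NA_real_
  rasterGrid(out, features@cellSize, features@origin, features@crs)
}
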