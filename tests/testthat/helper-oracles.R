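# Independent brute-force oracles used to validate the package's
# implementations on small fixtures. Each is written from the definition,
# not by calling the code path it checks.

# Wrap a bare resistance matrix as a ResistanceSurface.
resSurf <- function(m, cellSize = 100)
  new("ResistanceSurface", rasterGrid(m, cellSize), provenance = list())

# All-pairs accumulated cost on the 8-neighbour lattice by Floyd-Warshall
# (matrix-relaxation form). Edge cost = mean resistance * distance.
oracleCostMatrix <- function(resMat, cellSize = 100) {
  nr <- nrow(resMat); nc <- ncol(resMat)
  n <- nr * nc
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (is.na(resMat[i, j])) next
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (is.na(resMat[ii, jj])) next
      len <- cellSize * sqrt(di^2 + dj^2)
      a <- (j - 1) * nr + i; b <- (jj - 1) * nr + ii
      D[a, b] <- (resMat[i, j] + resMat[ii, jj]) / 2 * len
    }
  }
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

# Correlation length from the definition: per-patch mean distance of cell
# centres to the patch centroid, area-weighted. Patches found by repeated
# flood fill (8-connected).
oracleCorrelationLength <- function(binMat, cellSize = 100) {
  nr <- nrow(binMat); nc <- ncol(binMat)
  seen <- matrix(FALSE, nr, nc)
  gyr <- numeric(0); areas <- numeric(0)
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!isTRUE(binMat[i0, j0] == 1) || seen[i0, j0]) next
    queue <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    cells <- matrix(numeric(0), 0, 2)
    while (length(queue)) {
      c0 <- queue[[1]]; queue <- queue[-1]
      cells <- rbind(cells, c0)
      for (di in -1:1) for (dj in -1:1) {
        ii <- c0[1] + di; jj <- c0[2] + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
        if (isTRUE(binMat[ii, jj] == 1) && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, list(c(ii, jj)))
        }
      }
    }
    x <- (cells[, 2] - 0.5) * cellSize
    y <- -(cells[, 1] - 0.5) * cellSize
    gyr <- c(gyr, mean(sqrt((x - mean(x))^2 + (y - mean(y))^2)))
    areas <- c(areas, nrow(cells))
  }
  if (!length(areas)) return(0)
  sum(gyr * areas) / sum(areas)
}

# Moran's I by explicit double loop.
oracleMoranI <- function(z, W) {
  n <- length(z)
  zc <- z - mean(z)
  num <- 0; S0 <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- num + W[i, j] * zc[i] * zc[j]
    S0 <- S0 + W[i, j]
  }
  (n / S0) * num / sum(zc^2)
}

# AUC as the explicit all-pairs win fraction (ties count one half).
oracleAUC <- function(pres, bg) {
  wins <- 0
  for (p in pres) for (b in bg)
    wins <- wins + if (p > b) 1 else if (p == b) 0.5 else 0
  wins / (length(pres) * length(bg))
}

# Maximum-probability path matrix by exhaustive enumeration of all simple
# paths (feasible for n <= 7).
oraclePStar <- function(dist, k) {
  n <- nrow(dist)
  p <- exp(-k * dist)
  best <- diag(n)
  explore <- function(path, prob, target) {
    last <- path[length(path)]
    if (last == target) {
      best[path[1], target] <<- max(best[path[1], target], prob)
      return(invisible())
    }
    for (nxt in setdiff(seq_len(n), path)) {
      step <- p[last, nxt]
      if (step > 0) explore(c(path, nxt), prob * step, target)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    explore(i, 1, j)
  }
  best
}

oraclePC <- function(attr, dist, k, AL) {
  P <- oraclePStar(dist, k)
  sum(outer(attr, attr) * P) / AL^2
}

# Random abstract patch graph for decomposition / oracle tests.
randomPatchGraph <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(runif(2 * n, 0, 20000), n, 2)
  d <- as.matrix(dist(pts))
  patchGraph(attr = runif(n, 0.5, 10), dist = d, pMed = 0.5,
             dMed = runif(1, 2000, 10000), AL = 100)
}

# Small standard fixtures shared across tests.
smallStack <- function(seed = 1, nRows = 48, nCols = 48) {
  generatePredictorStack(landscapeSpec(nRows = nRows, nCols = nCols,
                                       seed = seed))
}

strongTruth <- function() trueModel(c(var1 = 2.5, var2 = -2),
                                    intercept = -4)
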