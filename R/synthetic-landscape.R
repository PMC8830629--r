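#' @include AllClasses.R utils.R raster-core.R
NULL

# Spatially autocorrelated standard-normal field: white noise convolved
# with a Gaussian kernel on the torus (circular convolution keeps the field
# stationary), then standardized to mean 0, sd 1. range = 0 -> iid noise.
gaussianRandomField <- function(nr, nc, rangeCells) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (rangeCells > 0) {
    di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
    dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
    d2 <- outer(di^2, dj^2, "+")
    kern <- exp(-d2 / (2 * rangeCells^2))
    kern <- kern / sum(kern)
    noise <- Re(stats::fft(stats::fft(noise) * stats::fft(kern),
                           inverse = TRUE)) / (nr * nc)
  }
  (noise - mean(noise)) / stats::sd(noise)
}

# Rasterize a straight segment between two cells (Bresenham-like walk).
lineCells <- function(nr, nc, from, to) {
  nSteps <- max(abs(to - from)) + 1L
  i <- round(seq(from[1], to[1], length.out = nSteps))
  j <- round(seq(from[2], to[2], length.out = nSteps))
  unique(cbind(pmin(pmax(i, 1L), nr), pmin(pmax(j, 1L), nc)))
}

#' Generate a synthetic predictor stack
#'
#' Builds the predictor set the analysis assumes: \code{nContinuousVars}
#' spatially autocorrelated continuous fields (standardized white noise
#' smoothed at \code{autocorrRange}), plus one Euclidean distance layer per
#' anthropogenic feature class — roads drawn as random polylines,
#' settlements and dumpsites as point features, croplands as rectangular
#' blocks — each rasterized and passed through the exact distance
#' transform. All layers share geometry; the whole stack is a deterministic
#' function of \code{spec@seed}.
#'
#' @param spec a \linkS4class{LandscapeSpec}.
#' @return named list of \linkS4class{RasterGrid} layers
#'   (\code{var1..varK}, then \code{dist_roads}, \code{dist_settlements},
#'   \code{dist_dumpsites}, \code{dist_croplands} as present).
#' @export
generatePredictorStack <- function(spec) {
  validObject(spec)
  nr <- spec@nRows; nc <- spec@nCols; cs <- spec@cellSize
  withSeed(childSeed(spec@seed, "predictors"), {
    stack <- list()
    for (k in seq_len(spec@nContinuousVars))
      stack[[paste0("var", k)]] <- rasterGrid(
        gaussianRandomField(nr, nc, spec@autocorrRange / cs), cs)
    featureMasks <- list()
    if (spec@nRoads > 0) {
      m <- matrix(0, nr, nc)
      for (r in seq_len(spec@nRoads)) {
        from <- c(sample(nr, 1L), 1L)
        to <- c(sample(nr, 1L), nc)
        m[lineCells(nr, nc, from, to)] <- 1
      }
      featureMasks$dist_roads <- m
    }
    if (spec@nSettlements > 0) {
      m <- matrix(0, nr, nc)
      m[cbind(sample(nr, spec@nSettlements, replace = TRUE),
              sample(nc, spec@nSettlements, replace = TRUE))] <- 1
      featureMasks$dist_settlements <- m
    }
    if (spec@nDumpsites > 0) {
      m <- matrix(0, nr, nc)
      m[cbind(sample(nr, spec@nDumpsites, replace = TRUE),
              sample(nc, spec@nDumpsites, replace = TRUE))] <- 1
      featureMasks$dist_dumpsites <- m
    }
    if (spec@nCroplands > 0) {
      m <- matrix(0, nr, nc)
      for (b in seq_len(spec@nCroplands)) {
        h <- sample(3:max(3L, nr %/% 10), 1L)
        w <- sample(3:max(3L, nc %/% 10), 1L)
        i0 <- sample(nr - h + 1L, 1L); j0 <- sample(nc - w + 1L, 1L)
        m[i0:(i0 + h - 1L), j0:(j0 + w - 1L)] <- 1
      }
      featureMasks$dist_croplands <- m
    }
    for (nm in names(featureMasks))
      stack[[nm]] <- distanceToFeatures(rasterGrid(featureMasks[[nm]], cs))
    stack
  })
}

#' Simulate occurrence points from a known suitability truth
#'
#' Cells are sampled without replacement with probability proportional to
#' \code{plogis(intercept + sum(coef * var))} over the stack variables named
#' in the truth; each sampled cell contributes one point at its centre.
#' Without-replacement cell sampling avoids duplicate coordinates that would
#' distort Moran's I. Source-class labels are drawn in the 55:88:45
#' den/scat/sighting ratio of a typical multi-source carnivore dataset; all
#' classes are treated identically downstream.
#'
#' @param truth a \linkS4class{TrueModel}.
#' @param stack predictor stack (list of \linkS4class{RasterGrid}).
#' @param nPoints number of occurrence records (>= 20).
#' @param seed integer seed.
#' @return An \linkS4class{OccurrenceSet}.
#' @export
simulateOccurrences <- function(truth, stack, nPoints, seed = 1L) {
  checkStack(stack)
  if (nPoints < 20) stop("nPoints must be >= 20")
  miss <- setdiff(names(truth@coefficients), names(stack))
  if (length(miss))
    stop("truth references variables absent from the stack: ",
         paste(miss, collapse = ", "))
  X <- stackMatrix(stack)
  eta <- truth@intercept
  for (nm in names(truth@coefficients))
    eta <- eta + truth@coefficients[[nm]] * X[, nm]
  p <- stats::plogis(eta)
  valid <- which(!is.na(p))
  if (nPoints > length(valid))
    stop("nPoints exceeds the number of valid cells")
  g <- stack[[1]]
  withSeed(seed, {
    cells <- sample(valid, nPoints, replace = FALSE, prob = p[valid])
    cls <- sample(c("den", "scat", "sighting"), nPoints, replace = TRUE,
                  prob = c(55, 88, 45) / 188)
    ctr <- cellCenters(g)[cells, , drop = FALSE]
    occurrenceSet(ctr[, 1], ctr[, 2], cls)
  })
}

#' Generate a synthetic conservation-area network
#'
#' Places \code{spec@nCAs} non-overlapping axis-aligned rectangular polygons
#' inside the landscape and assigns category labels according to
#' \code{spec@caCategoryMix} (default 2 wildlife refuges, 2 protected areas,
#' 5 non-hunting areas). Polygon corners snap to cell boundaries so no cell
#' centre ever falls on a polygon edge. Placement retries are bounded; an
#' overfull landscape is an error.
#'
#' @param spec a \linkS4class{LandscapeSpec}.
#' @return A \linkS4class{ConservationAreas} object (empty if
#'   \code{spec@nCAs == 0}).
#' @export
generateConservationAreas <- function(spec) {
  validObject(spec)
  if (spec@nCAs < 1L)
    return(new("ConservationAreas", polygons = list(),
               category = character(0)))
  nr <- spec@nRows; nc <- spec@nCols; cs <- spec@cellSize
  mix <- spec@caCategoryMix
  cats <- rep(names(mix), times = pmax(round(mix / sum(mix) * spec@nCAs), 0))
  cats <- rep_len(c(cats, rep(names(mix), spec@nCAs)), spec@nCAs)
  withSeed(childSeed(spec@seed, "cas"), {
    boxes <- matrix(numeric(0), 0, 4)  # i0, i1, j0, j1 in cell units
    tries <- 0L
    while (nrow(boxes) < spec@nCAs) {
      tries <- tries + 1L
      if (tries > 200L * spec@nCAs)
        stop("could not place non-overlapping conservation areas; ",
             "reduce nCAs or enlarge the landscape")
      h <- sample(max(2L, nr %/% 12):max(3L, nr %/% 5), 1L)
      w <- sample(max(2L, nc %/% 12):max(3L, nc %/% 5), 1L)
      i0 <- sample(0:(nr - h), 1L); j0 <- sample(0:(nc - w), 1L)
      cand <- c(i0, i0 + h, j0, j0 + w)
      overlaps <- nrow(boxes) > 0 &&
        any(cand[1] < boxes[, 2] & cand[2] > boxes[, 1] &
            cand[3] < boxes[, 4] & cand[4] > boxes[, 3])
      if (!overlaps) boxes <- rbind(boxes, cand)
    }
    polys <- lapply(seq_len(nrow(boxes)), function(b) {
      i0 <- boxes[b, 1]; i1 <- boxes[b, 2]
      j0 <- boxes[b, 3]; j1 <- boxes[b, 4]
      x0 <- j0 * cs; x1 <- j1 * cs
      yTop <- -i0 * cs; yBot <- -i1 * cs  # origin (0, 0) at upper-left
      cbind(c(x0, x1, x1, x0, x0), c(yTop, yTop, yBot, yBot, yTop))
    })
    new("ConservationAreas", polygons = polys, category = cats)
  })
}

#' Generate prey suitability and density surfaces
#'
#' For each of \code{spec@nPrey} prey species (default three, emulating a
#' wild goat / mouflon / goitered gazelle assemblage): a habitat
#' suitability surface in [0, 1] (logistic transform of an autocorrelated
#' field) and a zonal density surface that is constant within each of four
#' rectangular abundance zones (abundance divided by zone area, mirroring
#' census-style density assignment).
#'
#' @param spec a \linkS4class{LandscapeSpec}.
#' @return list of per-species lists with elements \code{suitability} and
#'   \code{density} (\linkS4class{RasterGrid}).
#' @export
generatePreyZones <- function(spec) {
  validObject(spec)
  if (spec@nPrey < 1L) stop("at least one prey species required")
  nr <- spec@nRows; nc <- spec@nCols; cs <- spec@cellSize
  withSeed(childSeed(spec@seed, "prey"), {
    lapply(seq_len(spec@nPrey), function(s) {
      suit <- stats::plogis(gaussianRandomField(nr, nc,
                                                spec@autocorrRange / cs))
      iSplit <- sample(seq(nr %/% 4, 3 * nr %/% 4), 1L)
      jSplit <- sample(seq(nc %/% 4, 3 * nc %/% 4), 1L)
      dens <- matrix(0, nr, nc)
      zones <- list(cbind(1, iSplit, 1, jSplit),
                    cbind(1, iSplit, jSplit + 1, nc),
                    cbind(iSplit + 1, nr, 1, jSplit),
                    cbind(iSplit + 1, nr, jSplit + 1, nc))
      for (z in zones) {
        areaKm2 <- (z[2] - z[1] + 1) * (z[4] - z[3] + 1) * cs^2 / 1e6
        abundance <- stats::runif(1, 0, 50 * areaKm2)
        dens[z[1]:z[2], z[3]:z[4]] <- abundance / areaKm2
      }
      list(suitability = rasterGrid(suit, cs),
           density = rasterGrid(dens, cs))
    })
  })
}

#' Write / read occurrence CSV
#'
#' Columns x, y, class.
#' @param occurrences an \linkS4class{OccurrenceSet}.
#' @param path file path.
#' @export
writeOccurrencesCsv <- function(occurrences, path) {
  df <- data.frame(x = occCoords(occurrences)[, 1],
                   y = occCoords(occurrences)[, 2],
                   class = occClass(occurrences))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOccurrencesCsv
#' @export
readOccurrencesCsv <- function(path) {
  df <- utils::read.csv(path)
  occurrenceSet(df$x, df$y,
                if ("class" %in% names(df)) df$class else "presence")
}

#' Write / read conservation areas as GeoJSON
#'
#' A FeatureCollection of Polygon features with a \code{category} property.
#' @param cas a \linkS4class{ConservationAreas} object.
#' @param path file path.
#' @export
writeGeoJSON <- function(cas, path) {
  features <- lapply(seq_along(cas@polygons), function(i) {
    ring <- cas@polygons[[i]]
    list(type = "Feature",
         properties = list(id = i, category = cas@category[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(r) as.numeric(ring[r, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeGeoJSON
#' @export
readGeoJSON <- function(path) {
  fc <- jsonlite::read_json(path)
  polys <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(p) as.numeric(unlist(p))))
  })
  cats <- vapply(fc$features, function(f)
    as.character(f$properties$category), character(1))
  new("ConservationAreas", polygons = polys, category = cats)
}
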