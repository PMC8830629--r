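test_that("patch graphs use edge-to-edge distances and calibrated decay", {
  # two single-cell patches two cells apart plus an adjacent pair
  m <- matrix(0, 5, 7)
  m[3, 2] <- 5; m[3, 3] <- 4   # patch 1: two touching cells
  m[3, 6] <- 3                 # patch 2
  m[1, 1] <- 0.001             # sacrificial minimum eaten by the strict cut
  ks <- new("KernelSurface", rasterGrid(m, 100), threshold = 1,
            sources = matrix(0, 1, 2))
  ps <- delineateCores(ks, 0, support = "positive")
  # percentile 0 keeps everything above the minimum; two patches expected
  expect_equal(nrow(patchTable(ps)), 2)
  g <- buildPatchGraph(ps, "strength", pMed = 0.5, dMed = 1000)
  expect_equal(g@dist[1, 2], 300)  # nearest distinct centres
  k <- -log(0.5) / 1000
  expect_equal(exp(-k * 1000), 0.5, tolerance = 1e-12)  # p(dMed) = pMed
  expect_equal(exp(-k * 0), 1)
  # the 100th percentile with a strict cut leaves nothing to build on
  m2 <- matrix(0, 3, 4)
  m2[2, 2] <- 1; m2[2, 3] <- 2
  ks2 <- new("KernelSurface", rasterGrid(m2, 100), threshold = 1,
             sources = matrix(0, 1, 2))
  expect_error(buildPatchGraph(delineateCores(ks2, 100), "area",
                               dMed = 1000), "empty")
})

test_that("PC spans its analytic extremes", {
  # a single patch covering the whole landscape
  g1 <- patchGraph(attr = 10, dist = matrix(0, 1, 1), pMed = 0.5,
                   dMed = 1000, AL = 10)
  expect_equal(pcIndex(g1), 1)
  # two isolated equal patches (infinite separation)
  g2 <- patchGraph(attr = c(2, 2), dist = matrix(c(0, Inf, Inf, 0), 2),
                   pMed = 0.5, dMed = 1000, AL = 10)
  expect_equal(pcIndex(g2), 2 * 4 / 100)
})

test_that("p* routes through a stepping stone when the product is larger", {
  # chain 1 - 2 - 3: direct 1-3 distance is far larger than the two hops
  d <- matrix(c(0, 1000, 5000,
                1000, 0, 1000,
                5000, 1000, 0), 3, 3, byrow = TRUE)
  g <- patchGraph(attr = c(1, 1, 1), dist = d, pMed = 0.5, dMed = 1000,
                  AL = 10)
  P <- connscape:::maxProductProbability(g)
  expect_equal(P[1, 3], 0.5 * 0.5, tolerance = 1e-12)  # two-hop product
  expect_gt(P[1, 3], exp(log(0.5) * 5))                # beats direct
})

test_that("PC and dPC match the exhaustive path-enumeration oracle", {
  for (seed in 1:5) {
    n <- 3 + (seed %% 5)
    g <- randomPatchGraph(n, seed)
    k <- -log(g@pMed) / g@dMed
    expect_equal(pcIndex(g), oraclePC(g@attr, g@dist, k, g@AL),
                 tolerance = 1e-9)
    d <- dpc(g)
    for (j in seq_len(n)) {
      pcFull <- oraclePC(g@attr, g@dist, k, g@AL)
      pcDrop <- oraclePC(g@attr[-j], g@dist[-j, -j, drop = FALSE], k,
                         g@AL)
      expect_equal(as.numeric(d[j]), 100 * (pcFull - pcDrop) / pcFull,
                   tolerance = 1e-9)
    }
  }
})

test_that("removing a node never increases PC and dPC is non-negative", {
  for (seed in 6:10) {
    g <- randomPatchGraph(6, seed)
    expect_true(all(dpc(g) >= -1e-12))
  }
})

test_that("dPC has its hand-computed two-patch value", {
  # two equal patches with p12 = 0.5: PC = (1+1+0.5+0.5) a^2/AL^2;
  # removing either leaves a^2/AL^2, so dPC = 100 * 2/3
  g <- patchGraph(attr = c(1, 1), dist = matrix(c(0, 1000, 1000, 0), 2),
                  pMed = 0.5, dMed = 1000, AL = 10)
  expect_equal(as.numeric(dpc(g)), rep(200 / 3, 2), tolerance = 1e-9)
  # sole patch: total loss
  g1 <- patchGraph(attr = 5, dist = matrix(0, 1, 1), pMed = 0.5,
                   dMed = 1000, AL = 10)
  expect_equal(as.numeric(dpc(g1)), 100)
})

test_that("the dPC fractions sum to dPC on random graphs", {
  for (seed in 11:40) {
    g <- randomPatchGraph(2 + (seed %% 9), seed)
    f <- dpcFractions(g)
    expect_equal(f$dPCintra + f$dPCflux + f$dPCconnector, f$dPC,
                 tolerance = 1e-9)
  }
})

test_that("fraction structure reflects node roles", {
  # isolated patch: no edges -> dPC is pure intra
  g <- patchGraph(attr = c(3, 2), dist = matrix(c(0, Inf, Inf, 0), 2),
                  pMed = 0.5, dMed = 1000, AL = 10)
  f <- dpcFractions(g)
  expect_equal(f$dPCflux, c(0, 0))
  expect_equal(f$dPCconnector, c(0, 0), tolerance = 1e-12)
  expect_equal(f$dPC, f$dPCintra, tolerance = 1e-12)
  # vanishing stepping stone bridging two big patches: pure connector
  d <- matrix(c(0, 1000, 1e7,
                1000, 0, 1000,
                1e7, 1000, 0), 3, 3, byrow = TRUE)
  g2 <- patchGraph(attr = c(5, 1e-6, 5), dist = d, pMed = 0.5,
                   dMed = 1000, AL = 20)
  f2 <- dpcFractions(g2)
  expect_lt(f2$dPCintra[2], 1e-8)
  expect_lt(f2$dPCflux[2], 1e-3)
  expect_gt(f2$dPCconnector[2], 1)
})

test_that("rankings are deterministic and scale-invariant", {
  g <- randomPatchGraph(6, 99)
  r <- rankPatches(g)
  expect_equal(r$rank, 1:6)
  expect_true(all(diff(r$dPC) <= 1e-12))
  # joint scaling of attributes and AL leaves dPC unchanged
  g2 <- patchGraph(attr = g@attr * 7, dist = g@dist, pMed = g@pMed,
                   dMed = g@dMed, AL = g@AL * 7)
  expect_equal(dpc(g2), dpc(g), tolerance = 1e-9)
  expect_identical(rankPatches(g2)$id, r$id)
  # symmetric twins tie exactly
  gs <- patchGraph(attr = c(2, 2), dist = matrix(c(0, 500, 500, 0), 2),
                   pMed = 0.5, dMed = 1000, AL = 10)
  d <- dpc(gs)
  expect_equal(d[[1]], d[[2]], tolerance = 1e-12)
})

test_that("gap coverage counts cell centres inside polygons", {
  m <- matrix(0, 10, 10)
  m[3:6, 3:6] <- 1  # 16 target cells
  b <- rasterGrid(m, 100)
  # polygon covering exactly the left half of the target block
  half <- cbind(c(200, 400, 400, 200, 200), c(-200, -200, -600, -600, -200))
  cas <- new("ConservationAreas", polygons = list(half),
             category = "protected_area")
  cov <- gapCoverage(b, cas)
  expect_equal(cov$total, 50)
  expect_equal(cov$byCategory$percent[
    cov$byCategory$category == "protected_area"], 50)
  # full cover
  full <- cbind(c(0, 1000, 1000, 0, 0), c(0, 0, -1000, -1000, 0))
  covF <- gapCoverage(b, new("ConservationAreas", polygons = list(full),
                             category = "wildlife_refuge"))
  expect_equal(covF$total, 100)
  # disjoint polygon
  off <- cbind(c(700, 900, 900, 700, 700), c(-700, -700, -900, -900, -700))
  cov0 <- gapCoverage(b, new("ConservationAreas", polygons = list(off),
                             category = "non_hunting_area"))
  expect_equal(cov0$total, 0)
  # empty target
  covE <- gapCoverage(rasterGrid(matrix(0, 4, 4), 100),
                      new("ConservationAreas", polygons = list(full),
                          category = "wildlife_refuge"))
  expect_equal(covE$total, 0)
  expect_identical(covE$status, "no target cells")
})

test_that("CA prioritization treats areas as patches of suitable habitat", {
  m <- matrix(0, 12, 12)
  m[2:4, 2:4] <- 1
  m[2:4, 9:11] <- 1
  suitable <- rasterGrid(m, 100)
  twin1 <- cbind(c(100, 400, 400, 100, 100), c(-100, -100, -400, -400, -100))
  twin2 <- cbind(c(800, 1100, 1100, 800, 800),
                 c(-100, -100, -400, -400, -100))
  empty <- cbind(c(600, 700, 700, 600, 600), c(-800, -800, -900, -900, -800))
  cas <- new("ConservationAreas", polygons = list(twin1, twin2, empty),
             category = c("wildlife_refuge", "protected_area",
                          "non_hunting_area"))
  expect_warning(out <- caPrioritization(cas, suitable, dMed = 1000),
                 "excluded")
  expect_equal(attr(out, "excluded"), 3L)
  expect_equal(nrow(out), 2)
  expect_equal(out$dPC[1], out$dPC[2], tolerance = 1e-9)  # symmetric twins
  expect_equal(out$areaKm2, rep(9 * 0.01, 2), tolerance = 1e-12)
  # a single CA is the whole network
  one <- suppressWarnings(caPrioritization(
    new("ConservationAreas", polygons = list(twin1),
        category = "wildlife_refuge"), suitable, dMed = 1000))
  expect_equal(one$dPC, 100)
})

test_that("non-dominant patch dPC grows with dispersal distance", {
  # fixed layout: one big patch and satellites; desk-scale dMed ladder
  set.seed(70)
  pts <- rbind(c(0, 0), c(6000, 0), c(0, 7000), c(8000, 8000))
  d <- as.matrix(dist(pts))
  attr <- c(10, 2, 2, 2)
  dMeds <- c(5000, 10000, 15000, 20000, 25000)
  meanMinor <- vapply(dMeds, function(dm) {
    g <- patchGraph(attr, d, pMed = 0.5, dMed = dm, AL = 50)
    mean(dpc(g)[-1])
  }, numeric(1))
  expect_true(all(diff(meanMinor) >= -1e-9))
})
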