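test_that("AUC matches hand-enumerated and brute-force values", {
  expect_equal(aucScore(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(aucScore(c(0.3, 0.6, 0.9), c(0.3, 0.6, 0.9)), 0.5)
  expect_equal(aucScore(c(0.7, 0.4), c(0.5, 0.3)), 0.75)
  set.seed(1)
  for (rep in 1:5) {
    pres <- round(runif(sample(5:50, 1)), 2)
    bg <- round(runif(sample(5:150, 1)), 2)
    expect_equal(aucScore(pres, bg), oracleAUC(pres, bg),
                 tolerance = 1e-12)
  }
  expect_error(aucScore(numeric(0), 1), "non-empty")
})

test_that("AUC agrees with pROC on a random scoring", {
  skip_if_not_installed("pROC")
  set.seed(2)
  pres <- runif(40); bg <- runif(60)
  roc <- pROC::roc(response = c(rep(1, 40), rep(0, 60)),
                   predictor = c(pres, bg), quiet = TRUE,
                   direction = "<")
  expect_equal(aucScore(pres, bg), as.numeric(pROC::auc(roc)),
               tolerance = 1e-9)
})

test_that("ensemble recovers the sign of a strong single-variable truth", {
  st <- smallStack(seed = 21)
  occ <- simulateOccurrences(trueModel(c(var1 = 3), intercept = -4),
                             st, 150, seed = 22)
  ens <- fitEnsemble(occ, st, modelConfig(nBackground = 1000L,
                                          nReplicates = 10L, seed = 23))
  signs <- vapply(ens@replicates, function(r) r$coef[["var1"]] > 0,
                  logical(1))
  expect_gte(sum(signs), 9)
  expect_s4_class(ens, "SuitabilityEnsemble")
  expect_length(ens@replicates, 10)
})

test_that("extreme regularization shrinks predictions to a constant", {
  st <- smallStack(seed = 24)
  occ <- simulateOccurrences(strongTruth(), st, 60, seed = 25)
  ens <- fitEnsemble(occ, st, modelConfig(nBackground = 500L,
                                          nReplicates = 3L,
                                          regularization = 1e6,
                                          seed = 26))
  hs <- gridValues(predictSuitability(ens, st))
  expect_lt(max(hs) - min(hs), 1e-3)
  coefs <- unlist(lapply(ens@replicates, function(r) r$coef))
  expect_lt(max(abs(coefs)), 1e-3)
})

test_that("predictions are bounded and mirror a single replicate", {
  st <- smallStack(seed = 27)
  occ <- simulateOccurrences(strongTruth(), st, 60, seed = 28)
  ens1 <- fitEnsemble(occ, st, modelConfig(nBackground = 500L,
                                           nReplicates = 1L, seed = 29))
  hs <- predictSuitability(ens1, st)
  v <- gridValues(hs)
  expect_true(all(v >= 0 & v <= 1))
  r <- ens1@replicates[[1]]
  X <- sapply(st, function(g) as.vector(gridValues(g)))
  colnames(X) <- names(st)
  st2 <- attr(ens1@replicates, "featureStats")
  Xs <- sweep(sweep(X, 2, st2$center, "-"), 2, pmax(st2$scale, 1e-12), "/")
  manual <- plogis(r$intercept +
                     cbind(Xs, Xs^2) %*% r$coef)
  expect_equal(as.vector(v), as.vector(manual), tolerance = 1e-12)
})

test_that("zeroed coefficients predict a flat logistic surface", {
  st <- smallStack(seed = 30)
  occ <- simulateOccurrences(strongTruth(), st, 60, seed = 31)
  ens <- fitEnsemble(occ, st, modelConfig(nBackground = 200L,
                                          nReplicates = 1L, seed = 32))
  ens@replicates[[1]]$coef[] <- 0
  ens@replicates[[1]]$intercept <- 0.4
  hs <- gridValues(predictSuitability(ens, st))
  expect_equal(unique(round(as.vector(hs), 12)), round(plogis(0.4), 12))
})

test_that("prediction on a stack missing model variables names them", {
  st <- smallStack(seed = 33)
  occ <- simulateOccurrences(strongTruth(), st, 60, seed = 34)
  ens <- fitEnsemble(occ, st, modelConfig(nBackground = 200L,
                                          nReplicates = 1L, seed = 35))
  expect_error(predictSuitability(ens, st[-1]), "var1")
})

test_that("p10 threshold follows the linear-interpolation percentile", {
  hs <- rasterGrid(matrix(seq(0.1, 1, by = 0.1), 1, 10), 100)
  ctr <- cellCenters(hs)
  occ <- occurrenceSet(ctr[, 1], ctr[, 2])
  ens <- new("SuitabilityEnsemble",
             replicates = list(list(coef = c(x = 1), intercept = 0,
                                    trainIdx = 1:10, testIdx = integer(0),
                                    converged = TRUE, testAUC = NA_real_)),
             varNames = "x",
             config = modelConfig(nReplicates = 1L))
  rule <- resolveThreshold(ens, occ, hs, "p10_training_presence")
  expect_equal(rule@value, 0.19, tolerance = 1e-12)
  # mean rule over a two-point subset
  occ2 <- occurrenceSet(ctr[c(2, 4), 1], ctr[c(2, 4), 2])
  rule2 <- resolveThreshold(ens, occ2, hs, "mean_presence_suitability")
  expect_equal(rule2@value, 0.3, tolerance = 1e-12)
})

test_that("thresholding is inclusive, monotone, and total at zero", {
  set.seed(36)
  hs <- rasterGrid(matrix(runif(64), 8, 8), 100)
  all1 <- applyThreshold(hs, 0)
  expect_true(all(gridValues(all1) == 1))
  exact <- applyThreshold(hs, gridValues(hs)[3, 3])
  expect_equal(gridValues(exact)[3, 3], 1)  # >= is inclusive
  prev <- NULL
  for (t in seq(0, 1, by = 0.1)) {
    b <- sum(gridValues(applyThreshold(hs, t)))
    if (!is.null(prev)) expect_lte(b, prev)
    prev <- b
  }
})

test_that("permutation importance isolates the sole informative variable", {
  st <- smallStack(seed = 37)
  occ <- simulateOccurrences(trueModel(c(var1 = 3), intercept = -4),
                             st, 150, seed = 38)
  ens <- fitEnsemble(occ, st, modelConfig(nBackground = 1000L,
                                          nReplicates = 5L, seed = 39))
  vi <- variableImportance(ens, occ, st, nPermutations = 3, seed = 40)
  expect_equal(sum(vi), 100, tolerance = 1e-6)
  expect_equal(names(which.max(vi)), "var1")
  expect_gt(vi[["var1"]], 60)
})

test_that("response curves track coefficient sign and sweep length", {
  st <- smallStack(seed = 41)
  occ <- simulateOccurrences(trueModel(c(var1 = 3), intercept = -4),
                             st, 150, seed = 42)
  ens <- fitEnsemble(occ, st, modelConfig(nBackground = 1000L,
                                          nReplicates = 3L, seed = 43))
  rc <- responseCurve(ens, st, "var1", nPoints = 50)
  expect_equal(nrow(rc), 50)
  # broadly increasing over the swept range for a strong positive truth
  expect_gt(cor(rc$value, rc$suitability, method = "spearman"), 0.8)
  rc2 <- responseCurve(ens, st, "var1", nPoints = 2)
  expect_equal(nrow(rc2), 2)
  expect_equal(rc2$value,
               range(gridValues(st$var1)), tolerance = 1e-9)
})

test_that("ensembles require enough presences and in-bounds points", {
  st <- smallStack(seed = 44)
  occSmall <- simulateOccurrences(strongTruth(), st, 20, seed = 45)
  occBad <- occurrenceSet(c(1e6, 2e6), c(0, 0))
  expect_error(fitEnsemble(occBad, st), "at least 20")
  occOut <- occurrenceSet(rep(1e6, 25), rep(1e6, 25))
  expect_error(fitEnsemble(occOut, st), "outside")
  expect_s4_class(fitEnsemble(occSmall, st,
                              modelConfig(nBackground = 200L,
                                          nReplicates = 2L, seed = 46)),
                  "SuitabilityEnsemble")
})
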