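#' @include AllClasses.R utils.R raster-core.R
NULL

# Linear + quadratic feature expansion of a raw predictor matrix.
# Raw variables are centred/scaled with the supplied statistics so the
# ridge penalty treats features comparably across replicates.
expandFeatures <- function(X, center, scale) {
  Xs <- sweep(sweep(X, 2L, center, "-"), 2L, pmax(scale, 1e-12), "/")
  F <- cbind(Xs, Xs^2)
  colnames(F) <- c(colnames(X), paste0(colnames(X), "^2"))
  F
}

stackStats <- function(X) {
  list(center = apply(X, 2L, mean, na.rm = TRUE),
       scale = apply(X, 2L, stats::sd, na.rm = TRUE))
}

#' Fit a presence-background suitability ensemble
#'
#' The suitability model is a ridge-penalized presence-background logistic
#' regression over linear + quadratic features of the screened predictor
#' stack — the same model family as maximum-entropy presence-background
#' estimation restricted to linear/quadratic feature classes. Per
#' replicate: the presence set is bootstrap-resampled, split into
#' train/test by \code{trainFraction}, a fresh uniform background sample of
#' \code{nBackground} cells (presences not excluded) is drawn, and the
#' penalized model is fitted with an iteration cap. Test AUC contrasts the
#' held-out presence scores with the background scores. Replicates that
#' fail to converge are flagged; the ensemble is valid while at least half
#' converge.
#'
#' @param occurrences an \linkS4class{OccurrenceSet} (>= 20 presences).
#' @param stack screened predictor stack.
#' @param config a \linkS4class{ModelConfig}.
#' @return A \linkS4class{SuitabilityEnsemble}.
#' @export
fitEnsemble <- function(occurrences, stack, config = modelConfig()) {
  checkStack(stack)
  validObject(config)
  n <- length(occurrences)
  if (n < 20L) stop("need at least 20 presence records")
  X <- stackMatrix(stack)
  colnames(X) <- names(stack)
  valid <- which(stats::complete.cases(X))
  presCells <- coordsToCells(stack[[1]], occCoords(occurrences))
  if (any(is.na(presCells)) || any(is.na(X[presCells, ])))
    stop("occurrence points fall outside the valid stack region")
  st <- stackStats(X[valid, , drop = FALSE])
  lam <- config@regularization
  reps <- withSeed(config@seed, lapply(seq_len(config@nReplicates),
                                       function(r) {
    boot <- sample(n, n, replace = TRUE)
    nTrain <- max(1L, floor(config@trainFraction * n))
    trainIdx <- boot[seq_len(nTrain)]
    testIdx <- boot[setdiff(seq_len(n), seq_len(nTrain))]
    bg <- sample(valid, config@nBackground, replace = TRUE)
    Ftrain <- expandFeatures(X[c(presCells[trainIdx], bg), , drop = FALSE],
                             st$center, st$scale)
    y <- c(rep(1, length(trainIdx)), rep(0, length(bg)))
    converged <- TRUE
    fit <- withCallingHandlers(
      tryCatch(glmnet::glmnet(Ftrain, y, family = "binomial", alpha = 0,
                              lambda = lam * c(100, 10, 1),
                              maxit = config@maxIterations,
                              standardize = FALSE),
               error = function(e) NULL),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      })
    if (is.null(fit))
      return(list(coef = NULL, intercept = NA_real_, trainIdx = trainIdx,
                  testIdx = testIdx, bg = bg, converged = FALSE,
                  testAUC = NA_real_))
    beta <- as.numeric(stats::coef(fit, s = lam))
    names(beta) <- c("(Intercept)", colnames(Ftrain))
    scoreCells <- function(cells) {
      Fm <- expandFeatures(X[cells, , drop = FALSE], st$center, st$scale)
      as.numeric(stats::plogis(beta[1] + Fm %*% beta[-1]))
    }
    testAUC <- if (length(testIdx))
      aucScore(scoreCells(presCells[testIdx]), scoreCells(bg))
    else NA_real_
    list(coef = beta[-1], intercept = beta[[1]], trainIdx = trainIdx,
         testIdx = testIdx, bg = bg, converged = converged,
         testAUC = testAUC)
  }))
  nConv <- sum(vapply(reps, function(r) isTRUE(r$converged), logical(1)))
  if (nConv < config@nReplicates / 2)
    stop(sprintf("only %d of %d replicates converged; ensemble invalid",
                 nConv, config@nReplicates))
  ens <- new("SuitabilityEnsemble", replicates = reps,
             varNames = names(stack), config = config)
  attr(ens@replicates, "featureStats") <- st
  ens
}

replicateScores <- function(ensemble, X, cells = NULL) {
  st <- attr(ensemble@replicates, "featureStats")
  if (!is.null(cells)) X <- X[cells, , drop = FALSE]
  Fm <- expandFeatures(X, st$center, st$scale)
  S <- sapply(ensemble@replicates, function(r) {
    if (is.null(r$coef)) return(rep(NA_real_, nrow(Fm)))
    as.numeric(stats::plogis(r$intercept + Fm %*% r$coef))
  })
  if (!is.matrix(S)) S <- matrix(S, nrow = nrow(Fm))
  S
}

#' Predict the habitat-suitability surface
#'
#' Per-cell mean of the replicate logistic predictions (non-converged
#' replicates excluded); nodata cells propagate.
#'
#' @param ensemble a \linkS4class{SuitabilityEnsemble}.
#' @param stack predictor stack with the variables the ensemble was fitted
#'   on (extra layers are ignored).
#' @return A \linkS4class{RasterGrid} with values in [0, 1].
#' @export
predictSuitability <- function(ensemble, stack) {
  checkStack(stack)
  miss <- setdiff(ensemble@varNames, names(stack))
  if (length(miss))
    stop("stack is missing model variables: ", paste(miss, collapse = ", "))
  stack <- stack[ensemble@varNames]
  X <- stackMatrix(stack)
  colnames(X) <- names(stack)
  ok <- stats::complete.cases(X)
  S <- replicateScores(ensemble, X[ok, , drop = FALSE])
  hs <- rep(NA_real_, nrow(X))
  hs[ok] <- rowMeans(S, na.rm = TRUE)
  g <- stack[[1]]
  rasterGrid(matrix(hs, nrow(g@values), ncol(g@values)),
             g@cellSize, g@origin, g@crs)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random presence score exceeds a random background
#' score, ties counting one half — the rank-sum formulation of the AUC.
#'
#' @param presenceScores,backgroundScores non-empty numeric vectors.
#' @return AUC in [0, 1].
#' @examples
#' aucScore(c(0.9, 0.8), c(0.1, 0.2))  # 1
#' @export
aucScore <- function(presenceScores, backgroundScores) {
  n1 <- length(presenceScores); n2 <- length(backgroundScores)
  if (n1 == 0L || n2 == 0L) stop("both score lists must be non-empty")
  r <- rank(c(presenceScores, backgroundScores), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Resolve a binarization threshold
#'
#' \code{p10_training_presence}: the 10th percentile (linear-interpolation
#' convention) of the suitability at each replicate's training presences,
#' averaged over converged replicates — so 90 percent of training presences
#' score as suitable. \code{mean_presence_suitability}: the mean
#' suitability at all occurrence points.
#'
#' @param ensemble a fitted \linkS4class{SuitabilityEnsemble}.
#' @param occurrences the \linkS4class{OccurrenceSet} used in fitting.
#' @param hs predicted suitability \linkS4class{RasterGrid}.
#' @param method threshold rule.
#' @return A \linkS4class{BinaryThresholdRule}.
#' @export
resolveThreshold <- function(ensemble, occurrences, hs,
                             method = c("p10_training_presence",
                                        "mean_presence_suitability")) {
  method <- match.arg(method)
  cells <- coordsToCells(hs, occCoords(occurrences))
  hsAt <- as.vector(hs@values)[cells]
  if (method == "mean_presence_suitability") {
    value <- mean(hsAt, na.rm = TRUE)
  } else {
    if (length(occurrences) < 10L)
      stop("p10 rule needs at least 10 presences")
    p10s <- vapply(ensemble@replicates, function(r) {
      if (is.null(r$coef)) return(NA_real_)
      stats::quantile(hsAt[r$trainIdx], 0.10, type = 7, na.rm = TRUE)
    }, numeric(1))
    value <- mean(p10s, na.rm = TRUE)
  }
  new("BinaryThresholdRule", method = method, value = value)
}

#' Apply a binarization threshold
#'
#' Cells with suitability >= the resolved threshold become 1 (suitable),
#' the rest 0; nodata propagates. Raising the threshold never adds
#' suitable cells.
#'
#' @param hs suitability \linkS4class{RasterGrid}.
#' @param rule a \linkS4class{BinaryThresholdRule} (or bare numeric).
#' @return A binary \linkS4class{RasterGrid}.
#' @export
applyThreshold <- function(hs, rule) {
  value <- if (is(rule, "BinaryThresholdRule")) rule@value else as.numeric(rule)
  v <- ifelse(is.na(hs@values), NA_real_, as.numeric(hs@values >= value))
  rasterGrid(v, hs@cellSize, hs@origin, hs@crs)
}

#' Permutation variable importance
#'
#' Per variable: the mean drop in evaluation AUC when that variable's
#' values (and its derived quadratic feature) are permuted across the
#' evaluation points (all presences plus a background sample), averaged
#' over converged replicates and permutations, negative drops clamped to
#' zero, rescaled to sum to 100. This replaces path-dependent
#' "percent contribution" reporting with a model-agnostic permutation
#' measure.
#'
#' @param ensemble a fitted \linkS4class{SuitabilityEnsemble}.
#' @param occurrences the fitting \linkS4class{OccurrenceSet}.
#' @param stack the predictor stack.
#' @param nPermutations permutations per variable (default 5).
#' @param nBackground evaluation background sample size (default 1000).
#' @param seed RNG seed.
#' @return named numeric percent contributions summing to 100.
#' @export
variableImportance <- function(ensemble, occurrences, stack,
                               nPermutations = 5L, nBackground = 1000L,
                               seed = 1L) {
  checkStack(stack)
  stack <- stack[ensemble@varNames]
  X <- stackMatrix(stack)
  colnames(X) <- names(stack)
  valid <- which(stats::complete.cases(X))
  presCells <- coordsToCells(stack[[1]], occCoords(occurrences))
  withSeed(seed, {
    bg <- sample(valid, nBackground, replace = TRUE)
    evalCells <- c(presCells, bg)
    isPres <- c(rep(TRUE, length(presCells)), rep(FALSE, length(bg)))
    Xe <- X[evalCells, , drop = FALSE]
    base <- replicateScores(ensemble, Xe)
    baseAUC <- apply(base, 2L, function(s)
      if (all(is.na(s))) NA_real_ else aucScore(s[isPres], s[!isPres]))
    drops <- vapply(ensemble@varNames, function(v) {
      mean(vapply(seq_len(nPermutations), function(p) {
        Xp <- Xe
        Xp[, v] <- Xp[sample(nrow(Xp)), v]
        S <- replicateScores(ensemble, Xp)
        permAUC <- apply(S, 2L, function(s)
          if (all(is.na(s))) NA_real_ else aucScore(s[isPres], s[!isPres]))
        mean(baseAUC - permAUC, na.rm = TRUE)
      }, numeric(1)))
    }, numeric(1))
    drops <- pmax(drops, 0)
    if (sum(drops) == 0) return(stats::setNames(rep(0, length(drops)),
                                                ensemble@varNames))
    100 * drops / sum(drops)
  })
}

#' Response curve of one predictor
#'
#' Sweeps the target variable across its observed range while holding all
#' other variables at their landscape means; predictions are averaged over
#' converged replicates.
#'
#' @param ensemble a fitted \linkS4class{SuitabilityEnsemble}.
#' @param stack the predictor stack.
#' @param variable variable name.
#' @param nPoints number of sweep points (default 100).
#' @return data.frame with columns \code{value} and \code{suitability}.
#' @export
responseCurve <- function(ensemble, stack, variable, nPoints = 100L) {
  checkStack(stack)
  if (!variable %in% ensemble@varNames)
    stop(sprintf("variable '%s' is not in the model", variable))
  stack <- stack[ensemble@varNames]
  X <- stackMatrix(stack)
  colnames(X) <- names(stack)
  mu <- apply(X, 2L, mean, na.rm = TRUE)
  rng <- range(X[, variable], na.rm = TRUE)
  sweep <- seq(rng[1], rng[2], length.out = nPoints)
  Xs <- matrix(rep(mu, each = nPoints), nPoints,
               dimnames = list(NULL, names(mu)))
  Xs[, variable] <- sweep
  S <- replicateScores(ensemble, Xs)
  data.frame(value = sweep, suitability = rowMeans(S, na.rm = TRUE))
}

#' Prey availability surface
#'
#' Cellwise sum over prey species of suitability times density.
#'
#' @param prey list of per-species lists with \code{suitability} and
#'   \code{density} grids (as from \code{\link{generatePreyZones}}).
#' @return A \linkS4class{RasterGrid}.
#' @export
preyAvailability <- function(prey) {
  if (!length(prey)) stop("at least one prey species required")
  g <- prey[[1]]$suitability
  acc <- matrix(0, nrow(g@values), ncol(g@values))
  for (sp in prey) {
    stopIfGeometryMismatch(g, sp$suitability, "prey layers")
    stopIfGeometryMismatch(g, sp$density, "prey layers")
    acc <- acc + sp$suitability@values * sp$density@values
  }
  rasterGrid(acc, g@cellSize, g@origin, g@crs)
}
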