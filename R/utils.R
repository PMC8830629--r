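# Internal helpers: seeded RNG scoping, geometry checks, stack handling.

# Evaluate expr with a private RNG stream seeded by `seed`; the caller's
# .Random.seed is untouched. All package randomness flows through this.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct child seed from a master seed and a stage label.
# Deterministic, label-sensitive, and kept within 32-bit integer range.
childSeed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 31 + k) %% 2147480009
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147480009)
}

#' Do two grids share geometry?
#'
#' Grids share geometry when dimensions, cell size and origin agree exactly
#' (within 1e-9 m). All multi-layer operations require this.
#'
#' @param a,b \linkS4class{RasterGrid} objects.
#' @return TRUE or FALSE.
#' @export
sameGeometry <- function(a, b) {
  all(dim(a@values) == dim(b@values)) &&
    abs(a@cellSize - b@cellSize) < 1e-9 &&
    all(abs(a@origin - b@origin) < 1e-9)
}

stopIfGeometryMismatch <- function(a, b, what = "grids") {
  if (!sameGeometry(a, b))
    stop(sprintf(
      "geometry mismatch between %s: %d x %d @ %g m origin (%g, %g) vs %d x %d @ %g m origin (%g, %g)",
      what, nrow(a@values), ncol(a@values), a@cellSize,
      a@origin[1], a@origin[2], nrow(b@values), ncol(b@values), b@cellSize,
      b@origin[1], b@origin[2]))
  invisible(TRUE)
}

# Validate a predictor stack: named list of RasterGrid sharing geometry.
checkStack <- function(stack) {
  if (!length(stack)) stop("empty predictor stack")
  if (is.null(names(stack)) || any(!nzchar(names(stack))))
    stop("stack layers must be named")
  if (!all(vapply(stack, is, logical(1), "RasterGrid")))
    stop("stack layers must be RasterGrid objects")
  for (i in seq_along(stack)[-1])
    stopIfGeometryMismatch(stack[[1]], stack[[i]],
                           sprintf("layers '%s' and '%s'",
                                   names(stack)[1], names(stack)[i]))
  invisible(TRUE)
}

# Stack values as an (ncells x nvars) matrix, column-major cell order.
stackMatrix <- function(stack) {
  checkStack(stack)
  do.call(cbind, lapply(stack, function(g) as.vector(g@values)))
}

# Map coordinates -> cell index (column-major), NA outside the grid.
coordsToCells <- function(grid, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  cs <- grid@cellSize
  j <- floor((xy[, 1] - grid@origin[1]) / cs) + 1
  i <- floor((grid@origin[2] - xy[, 2]) / cs) + 1
  nr <- nrow(grid@values); nc <- ncol(grid@values)
  ok <- i >= 1 & i <= nr & j >= 1 & j <= nc & is.finite(i) & is.finite(j)
  idx <- ifelse(ok, (j - 1) * nr + i, NA_real_)
  as.integer(idx)
}

# Polynomial rolling checksum of a raw vector (mod a prime below 2^31),
# hex string; used for run-manifest checksums.
contentChecksum <- function(raw) {
  p <- 2147480009
  b <- as.integer(raw)
  h <- 0
  # process in blocks with a precomputed power ladder to keep the R loop short
  blk <- 512L
  pow <- numeric(blk)
  pow[1] <- 1
  for (i in seq_len(blk - 1L)) pow[i + 1L] <- (pow[i] * 257) %% p
  powBlk <- (pow[blk] * 257) %% p
  mulmod <- function(a, bb) {
    hi <- floor(a / 65536); lo <- a %% 65536
    (((hi * bb) %% p) * 65536 + lo * bb) %% p
  }
  for (s in seq(1L, length(b), by = blk)) {
    chunk <- b[s:min(s + blk - 1L, length(b))]
    n <- length(chunk)
    h <- mulmod(h, if (n == blk) powBlk else (pow[n] * 257) %% p)
    h <- (h + sum(chunk * pow[n:1]) %% p) %% p
  }
  sprintf("%08x", h)
}

fileChecksum <- function(path)
  contentChecksum(readBin(path, "raw", n = file.info(path)$size))
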