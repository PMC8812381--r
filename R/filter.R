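#' High-pass filter by discrete-cosine projection
#'
#' Removes the per-column mean and every discrete-cosine basis component
#' with period longer than `cutoffS` (the drift band). Spectrally equivalent
#' to the conventional 100-s high-pass for this purpose, but deterministic
#' and exactly idempotent. Output columns are mean-zero.
#'
#' @param series scan x voxel (or scan x regressor) numeric matrix or vector.
#' @param cutoffS cutoff period, seconds; must exceed `2 * trS`.
#' @param trS repetition time, seconds.
#' @return filtered matrix of the same shape.
#' @export
highpass <- function(series, cutoffS = 100, trS = 2.0) {
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 3L) stop("series must have at least 3 scans")
  if (cutoffS <= 2 * trS) stop("cutoffS must exceed twice the repetition time")
  xc <- sweep(x, 2, colMeans(x))
  K <- floor(2 * n * trS / cutoffS)
  if (K >= 1L) {
    s <- seq_len(n) - 0.5
    B <- vapply(seq_len(K), function(k) cos(pi * s * k / n), numeric(n))
    # DCT-II columns are orthogonal with squared norm n/2
    xc <- xc - B %*% (crossprod(B, xc) * (2 / n))
  }
  out <- xc
  dimnames(out) <- dimnames(x)
  if (is.null(dim(series))) drop(out) else out
}

# Row-normalised 1-D Gaussian convolution operator (k x k). Truncated at
# 3 sigma; row renormalisation preserves constants exactly at boundaries.
.gaussOperator <- function(nAxis, sigmaVox) {
  if (sigmaVox <= 0) return(diag(nAxis))
  r <- max(1L, ceiling(3 * sigmaVox))
  w <- stats::dnorm(-r:r, sd = sigmaVox)
  S <- matrix(0, nAxis, nAxis)
  for (i in seq_len(nAxis)) {
    j <- pmax(1L, pmin(nAxis, i + (-r:r)))
    for (t in seq_along(j)) S[i, j[t]] <- S[i, j[t]] + w[t]
  }
  sweep(S, 1, rowSums(S), "/")
}

#' Spatial Gaussian smoothing on the voxel grid
#'
#' Separable 3-D Gaussian smoothing of each scan, with
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))` per axis (in millimetres,
#' converted to voxels by `voxelSizeMm`). The kernel is renormalised at grid
#' boundaries, so constant images are unchanged and the mask mean is
#' preserved for interior voxels.
#'
#' @param series scan x voxel matrix (voxels in column-major grid order).
#' @param gridDim length-3 integer grid dimensions (product = voxel count).
#' @param fwhmMm kernel full width at half maximum, millimetres.
#' @param voxelSizeMm isotropic voxel edge, millimetres.
#' @return smoothed matrix of the same shape.
#' @export
smoothSpatial <- function(series, gridDim, fwhmMm = 5, voxelSizeMm = 3) {
  if (fwhmMm < 0) stop("fwhmMm must be non-negative")
  if (voxelSizeMm <= 0) stop("voxelSizeMm must be positive")
  x <- as.matrix(series)
  gridDim <- as.integer(gridDim)
  if (length(gridDim) != 3L || prod(gridDim) != ncol(x))
    stop("gridDim must be 3 dimensions whose product equals the voxel count")
  if (fwhmMm == 0) return(x)
  sigma <- fwhmMm / (2 * sqrt(2 * log(2))) / voxelSizeMm
  ops <- lapply(gridDim, .gaussOperator, sigmaVox = sigma)
  nScans <- nrow(x)
  # apply along each axis by reshaping to (axis, rest) and multiplying
  arr <- array(t(x), dim = c(gridDim, nScans))
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:4, ax))
    a <- aperm(arr, perm)
    d <- dim(a)
    a <- ops[[ax]] %*% matrix(a, nrow = d[1])
    arr <- aperm(array(a, d), order(perm))
  }
  out <- t(matrix(arr, nrow = prod(gridDim)))
  dimnames(out) <- dimnames(x)
  out
}
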