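#' Sample the double-gamma haemodynamic response function
#'
#' The kernel is the difference of two gamma-density components: a positive
#' lobe with its mode at `peakDelayS` and an undershoot with its mode at
#' `undershootDelayS`, each normalised to unit component peak, the second
#' scaled by `undershootRatio`. The full kernel is rescaled so its maximum
#' is exactly 1.
#'
#' @param timeGrid non-negative, increasing vector of sample times (seconds).
#' @param params an [HrfParams-class]; see [hrfParams()].
#' @return numeric vector of kernel values at `timeGrid`.
#' @examples
#' h <- doubleGammaHrf(seq(0, 32, by = 0.1), hrfParams())
#' @export
doubleGammaHrf <- function(timeGrid, params = hrfParams()) {
  validObject(params)
  if (length(timeGrid) == 0L) stop("empty time grid")
  if (any(timeGrid < 0) || is.unsorted(timeGrid, strictly = TRUE))
    stop("time grid must be non-negative and strictly increasing")
  gammaLobe <- function(t, delay, disp) {
    shape <- delay / disp + 1 # mode of the gamma density sits at `delay`
    dgamma(t, shape = shape, scale = disp) /
      dgamma(delay, shape = shape, scale = disp)
  }
  k <- gammaLobe(timeGrid, params@peakDelayS, params@peakDispersionS) -
    params@undershootRatio *
      gammaLobe(timeGrid, params@undershootDelayS, params@undershootDispersionS)
  mx <- max(k)
  if (mx <= 0) stop("kernel has no positive lobe on this grid")
  k / mx
}

# Trial regressors on the scan grid: boxcar (onset, duration) convolved with
# the HRF on a fine grid (TR/oversampling) and decimated to scan times
# 0, TR, 2*TR, ... Shared by the forward simulator and the design builder --
# it IS the same linear forward model on both sides.
convolveTrialRegressors <- function(onsets, durations, nScans, trS, params) {
  dt <- trS / params@oversampling
  nFine <- ceiling(nScans * trS / dt) + 1L
  kern <- doubleGammaHrf(seq(0, params@kernelLengthS, by = dt), params)
  scanIdx <- pmin(nFine, round((seq_len(nScans) - 1) * trS / dt) + 1L)
  out <- matrix(0, nScans, length(onsets))
  for (j in seq_along(onsets)) {
    box <- numeric(nFine)
    i0 <- floor(onsets[j] / dt) + 1L
    i1 <- min(nFine, ceiling((onsets[j] + durations[j]) / dt))
    if (i0 > nFine) stop(sprintf("event %d starts beyond the run", j))
    box[i0:i1] <- 1
    cv <- convolve(box, rev(kern), type = "open")[seq_len(nFine)] * dt
    out[, j] <- cv[scanIdx]
  }
  out
}
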