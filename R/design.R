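#' Build the single-trial design matrix
#'
#' One regressor per trial — the trial's boxcar (onset, duration) convolved
#' with the double-gamma HRF at `oversampling` sub-TR resolution, then
#' decimated to the scan grid — followed by seven unconvolved nuisance
#' columns (six motion series and the global signal). This is the
#' least-squares-all parameterisation: all trials enter one model.
#'
#' @param events event table for the run.
#' @param confounds scan x 7 matrix (columns `motion_1..6`, `global_signal`).
#' @param nScans number of scans in the run.
#' @param trS repetition time, seconds.
#' @param hrf an [HrfParams-class].
#' @return a [DesignMatrix-class] with `nTrials + 7` columns.
#' @export
buildDesignMatrix <- function(events, confounds, nScans, trS,
                              hrf = hrfParams()) {
  validateEvents(events)
  runEnd <- nScans * trS
  late <- which(events$onset + events$duration > runEnd)
  if (length(late))
    stop(sprintf("event(s) end beyond the run: trial_id %s",
                 paste(events$trial_id[late], collapse = ", ")))
  confounds <- as.matrix(confounds)
  need <- c(paste0("motion_", 1:6), "global_signal")
  miss <- setdiff(need, colnames(confounds))
  if (length(miss))
    stop(paste("missing confound column(s):", paste(miss, collapse = ", ")))
  if (nrow(confounds) != nScans)
    stop("confounds must have one row per scan")

  reg <- convolveTrialRegressors(events$onset, events$duration,
                                 nScans, trS, hrf)
  colnames(reg) <- paste0("trial_", events$trial_id)
  X <- cbind(reg, confounds[, need])
  new("DesignMatrix",
      design = X,
      roles = c(rep("trial", nrow(events)), rep("motion", 6), "global_signal"),
      trialIds = c(as.integer(events$trial_id), rep(NA_integer_, 7)))
}
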