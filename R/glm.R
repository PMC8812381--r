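#' Fit the least-squares-all single-trial GLM
#'
#' Ordinary least squares per voxel with one regressor per trial plus the
#' seven nuisance columns and an internally added intercept. Per-trial
#' t-statistics (`beta / SE`, residual degrees of freedom) are mapped to
#' z-statistics through the t cumulative probability and the standard-normal
#' quantile, clamped at `zClamp` to keep saturated values finite for the
#' classifier.
#'
#' @param run a [BoldRun-class].
#' @param design a [DesignMatrix-class]; must be of full column rank and
#'   leave positive residual degrees of freedom.
#' @param data optional scan x voxel matrix overriding the run's raw signal
#'   (e.g. after filtering/smoothing).
#' @param zClamp absolute bound on the returned z-statistics.
#' @return a [TrialPatternDataset-class] (one column per trial).
#' @export
fitLsaGlm <- function(run, design, data = NULL, zClamp = 8.2) {
  Y <- if (is.null(data)) boldSignal(run) else as.matrix(data)
  X <- cbind(design@design, intercept = 1)
  n <- nrow(Y)
  p <- ncol(X)
  if (nrow(X) != n) stop("design and data disagree on scan count")
  if (n <= p) stop("more regressors (plus intercept) than scans")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(paste("design matrix is rank deficient; collinear column(s):",
               paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtxInvDiag <- diag(chol2inv(qr.R(qrX)))[order(qrX$pivot)]
  tMat <- beta / sqrt(outer(xtxInvDiag, sigma2))
  trialRows <- which(design@roles == "trial")
  tTrial <- tMat[trialRows, , drop = FALSE]
  z <- sign(tTrial) * qnorm(pt(abs(tTrial), df, lower.tail = FALSE,
                               log.p = TRUE),
                            lower.tail = FALSE, log.p = TRUE)
  z[tTrial == 0] <- 0
  z <- pmin(pmax(z, -zClamp), zClamp)

  events <- runEvents(run)
  ord <- match(design@trialIds[trialRows], events$trial_id)
  cd <- DataFrame(
    label = events$trial_type[ord],
    run_id = events$run_id[ord],
    trial_id = events$trial_id[ord],
    outcome = events$outcome[ord]
  )
  rownames(cd) <- paste0("trial", events$trial_id[ord])
  z <- t(z)
  dimnames(z) <- NULL
  se <- SummarizedExperiment(
    assays = list(z = z),
    rowData = rowData(run), colData = cd,
    metadata = list(gridDim = metadata(run)$gridDim, df = df,
                    beta = t(beta[trialRows, , drop = FALSE]))
  )
  new("TrialPatternDataset", se)
}

#' First-level processing of one run
#'
#' The standard chain: high-pass filter the data (100-s discrete-cosine
#' cutoff), spatially smooth (5-mm FWHM), recompute the global-signal
#' regressor as the mask mean of the filtered series, build the single-trial
#' design, apply the same high-pass to the trial and motion regressors
#' (so filtering cannot bias the trial estimates), and fit the GLM.
#'
#' @param run a [BoldRun-class].
#' @param hrf an [HrfParams-class].
#' @param cutoffS high-pass cutoff period, seconds.
#' @param fwhmMm smoothing FWHM, millimetres (0 disables smoothing).
#' @param voxelSizeMm isotropic voxel size, millimetres.
#' @param filterDesign apply the high-pass to trial/motion regressors too.
#' @return a [TrialPatternDataset-class].
#' @export
processRun <- function(run, hrf = hrfParams(), cutoffS = 100, fwhmMm = 5,
                       voxelSizeMm = 3, filterDesign = TRUE) {
  trS <- boldTr(run)
  Y <- boldSignal(run)
  Y <- highpass(Y, cutoffS = cutoffS, trS = trS)
  if (fwhmMm > 0)
    Y <- smoothSpatial(Y, boldGridDim(run), fwhmMm = fwhmMm,
                       voxelSizeMm = voxelSizeMm)
  conf <- nuisance(run)
  conf[, "global_signal"] <- rowMeans(Y)
  design <- buildDesignMatrix(runEvents(run), conf, nScans = nrow(Y),
                              trS = trS, hrf = hrf)
  if (filterDesign) {
    filt <- design@roles %in% c("trial", "motion")
    X <- design@design
    X[, filt] <- highpass(X[, filt, drop = FALSE], cutoffS = cutoffS, trS = trS)
    design@design <- X
  }
  fitLsaGlm(run, design, data = Y)
}

#' Trial patterns for a whole simulated subject
#'
#' Runs [processRun()] on every training run and on the transfer run and
#' concatenates trials within task.
#'
#' @param study a [SubjectStudy-class].
#' @param hrf,cutoffS,fwhmMm,voxelSizeMm,filterDesign passed to [processRun()].
#' @return list with elements `training` and `transfer`, each a
#'   [TrialPatternDataset-class].
#' @export
trialPatterns <- function(study, hrf = hrfParams(), cutoffS = 100,
                          fwhmMm = 5, voxelSizeMm = 3, filterDesign = TRUE) {
  stopifnot(is(study, "SubjectStudy"))
  tr <- lapply(study@trainingRuns, processRun, hrf = hrf, cutoffS = cutoffS,
               fwhmMm = fwhmMm, voxelSizeMm = voxelSizeMm,
               filterDesign = filterDesign)
  training <- do.call(SummarizedExperiment::cbind, unname(tr))
  training <- new("TrialPatternDataset", training)
  transfer <- processRun(study@transferRun, hrf = hrf, cutoffS = cutoffS,
                         fwhmMm = fwhmMm, voxelSizeMm = voxelSizeMm,
                         filterDesign = filterDesign)
  list(training = training, transfer = transfer)
}
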