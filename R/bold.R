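#' Render a BOLD run from an event schedule
#'
#' Forward model of the acquisition: each trial contributes
#' `signalAmplitude` times its voxel pattern, modulated over time by its
#' boxcar convolved with the double-gamma HRF; a low-frequency drift (cosine
#' mixture with periods above `driftCutoffS`, independent voxel loadings) and
#' stationary AR(1) Gaussian noise are added. Six motion-like random-walk
#' nuisance series and the global signal (mask mean of the rendered data)
#' are emitted alongside in `colData`.
#'
#' @param events event table for one run (onsets relative to run start).
#' @param trialPatterns nTrials x nVoxels matrix: the voxel pattern driving
#'   each trial (condition prototype for training trials, latent-strategy
#'   prototype for transfer trials).
#' @param config a [GeneratorConfig-class].
#' @param hrf an [HrfParams-class].
#' @param nScans number of scans; defaults to covering the last event plus
#'   the HRF kernel length.
#' @param seed optional integer for a local RNG stream.
#' @return a [BoldRun-class].
#' @export
renderBold <- function(events, trialPatterns, config = generatorConfig(),
                       hrf = hrfParams(), nScans = NULL, seed = NULL) {
  validObject(config)
  validateEvents(events)
  if (config@trS <= 0) stop("TR must be positive")
  nTrials <- nrow(events)
  V <- ncol(trialPatterns)
  if (nrow(trialPatterns) != nTrials)
    stop("trialPatterns must have one row per event")
  if (is.null(nScans))
    nScans <- ceiling((max(events$onset + events$duration) + hrf@kernelLengthS) /
                        config@trS)
  runEnd <- nScans * config@trS
  late <- which(events$onset + events$duration > runEnd)
  if (length(late))
    stop(sprintf("event(s) extend beyond the run: trial_id %s",
                 paste(events$trial_id[late], collapse = ", ")))

  withSeed(seed, {
    reg <- convolveTrialRegressors(events$onset, events$duration,
                                   nScans, config@trS, hrf)
    signal <- config@signalAmplitude * (reg %*% trialPatterns)
    signal <- signal + .sampleDrift(nScans, V, config) +
      .sampleAr1Noise(nScans, V, config)
    motion <- .sampleMotion(nScans)
    .newBoldRun(signal, config, events, motion)
  })
}

# cosine drift: every component has period > driftCutoffS (the band the
# 100-s high-pass is meant to remove), with independent N(0, driftAmplitude)
# voxel loadings per component.
.sampleDrift <- function(nScans, nVoxels, config, driftCutoffS = 100) {
  if (config@driftAmplitude == 0) return(matrix(0, nScans, nVoxels))
  K <- floor(2 * nScans * config@trS / driftCutoffS)
  if (K < 1L) return(matrix(0, nScans, nVoxels))
  s <- seq_len(nScans) - 0.5
  B <- vapply(seq_len(K), function(k) cos(pi * s * k / nScans),
              numeric(nScans))
  L <- matrix(rnorm(K * nVoxels, sd = config@driftAmplitude), K, nVoxels)
  B %*% L
}

# stationary AR(1) noise with marginal SD noiseSd; 50-scan burn-in.
.sampleAr1Noise <- function(nScans, nVoxels, config) {
  if (config@noiseSd == 0) return(matrix(0, nScans, nVoxels))
  phi <- config@ar1Coef
  if (phi == 0) return(matrix(rnorm(nScans * nVoxels, sd = config@noiseSd),
                              nScans, nVoxels))
  burn <- 50L
  innov <- matrix(rnorm((nScans + burn) * nVoxels,
                        sd = config@noiseSd * sqrt(1 - phi^2)),
                  nScans + burn, nVoxels)
  x <- stats::filter(innov, phi, method = "recursive")
  matrix(as.numeric(x[(burn + 1):(burn + nScans), ]), nScans, nVoxels)
}

# six smooth random-walk motion-like series (only their role as nuisance
# regressors matters, not biomechanical realism).
.sampleMotion <- function(nScans) {
  m <- vapply(1:6, function(i) cumsum(rnorm(nScans, sd = 0.02)),
              numeric(nScans))
  colnames(m) <- paste0("motion_", 1:6)
  m
}

.newBoldRun <- function(signal, config, events, motion) {
  nScans <- nrow(signal)
  V <- ncol(signal)
  gd <- gridDims(V)
  coords <- arrayInd(seq_len(V), gd)
  cd <- DataFrame(as.data.frame(motion),
                  global_signal = rowMeans(signal))
  rownames(cd) <- paste0("scan", seq_len(nScans))
  rd <- DataFrame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  rownames(rd) <- paste0("v", seq_len(V))
  se <- SummarizedExperiment(
    assays = list(bold = t(signal)),
    rowData = rd, colData = cd,
    metadata = list(trS = config@trS, gridDim = gd, events = events)
  )
  new("BoldRun", se)
}

#' Simulate one complete subject
#'
#' Draws (under a per-subject child seed derived from the root seed, so
#' adding subjects never perturbs existing ones) the condition prototypes,
#' the training and transfer event schedules, the latent transfer truth,
#' and renders every BOLD run.
#'
#' @param config a [GeneratorConfig-class].
#' @param subject subject index (1-based).
#' @param hrf an [HrfParams-class].
#' @return a [SubjectStudy-class].
#' @examples
#' study <- simulateSubject(generatorConfig(nVoxels = 48, seed = 3))
#' study
#' @export
simulateSubject <- function(config = generatorConfig(), subject = 1L,
                            hrf = hrfParams()) {
  validObject(config)
  sseed <- subjectSeed(config@seed, subject)
  withSeed(sseed, {
    protos <- sampleConditionPatterns(config)
    trainEv <- sampleEventSchedule("training", config)
    truth <- assignTransferTruth(config)
    transferEv <- sampleEventSchedule("transfer", config)
    transferEv$outcome <- truth$outcome

    trainingRuns <- lapply(split(trainEv, trainEv$run_id), function(ev) {
      renderBold(ev, protos[ev$trial_type, , drop = FALSE], config, hrf)
    })
    names(trainingRuns) <- paste0("run", seq_along(trainingRuns))
    transferRun <- renderBold(transferEv,
                              protos[truth$strategy, , drop = FALSE],
                              config, hrf)
    new("SubjectStudy",
        trainingRuns = trainingRuns, transferRun = transferRun,
        prototypes = protos, truth = truth, config = config,
        subject = as.integer(subject))
  })
}

#' Simulate a multi-subject study
#'
#' @param config a [GeneratorConfig-class]; `nSubjects` subjects are drawn.
#' @param hrf an [HrfParams-class].
#' @return list of [SubjectStudy-class] objects.
#' @export
simulateStudy <- function(config = generatorConfig(), hrf = hrfParams()) {
  lapply(seq_len(config@nSubjects), function(s)
    simulateSubject(config, subject = s, hrf = hrf))
}
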