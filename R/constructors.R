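#' Create a generator configuration
#'
#' Defaults reproduce the emulated acquisition: TR 2.0 s; clips of 1.2-1.5 s;
#' inter-trial intervals jittered on a 0.1-s grid between 2 and 8 s (mean
#' 5 s); breaks of 3-8 s (mean 5.5 s) after every mini-block of 3 clips; a
#' 5-s instruction cue opening each run; four training runs blocked by
#' instruction in AABB (or BBAA) order; and a single 60-trial penalty-reading
#' transfer run.
#'
#' @param nSubjects number of subjects.
#' @param nVoxels voxels on the rectangular grid (default 500: desk-scale
#'   with the same mathematics as whole-brain).
#' @param nTrainingRuns training runs; must be even so classes balance.
#' @param trialsPerMiniblock clips per mini-block.
#' @param miniblocksPerRun mini-blocks per run.
#' @param nTransferTrials penalty-reading trials.
#' @param trS repetition time, seconds.
#' @param clipDurationRangeS clip duration interval, seconds.
#' @param itiRangeS inter-trial interval bounds, seconds (0.1-s grid).
#' @param breakRangeS mini-block break bounds, seconds (0.1-s grid).
#' @param cueDurationS instruction cue duration, seconds.
#' @param instructionOrder `"AABB"` or `"BBAA"`.
#' @param design `"blocked"` (default) or `"interleaved"`.
#' @param signalAmplitude condition-pattern effect size (GLM beta units).
#' @param patternOverlap correlation of the two condition prototypes.
#' @param noiseSd marginal SD of the AR(1) voxel noise.
#' @param ar1Coef lag-1 autocorrelation of the voxel noise.
#' @param driftAmplitude per-component scale of the low-frequency drift.
#' @param pCorrect probability a transfer trial is correctly anticipated.
#' @param pImgGivenCorrect P(imagery strategy | correct trial).
#' @param pImgGivenIncorrect P(imagery strategy | incorrect trial).
#' @param seed integer root seed.
#' @return a validated [GeneratorConfig-class].
#' @examples
#' cfg <- generatorConfig(nSubjects = 1, nVoxels = 50, seed = 7)
#' cfg
#' @export
generatorConfig <- function(nSubjects = 1L,
                            nVoxels = 500L,
                            nTrainingRuns = 4L,
                            trialsPerMiniblock = 3L,
                            miniblocksPerRun = 4L,
                            nTransferTrials = 60L,
                            trS = 2.0,
                            clipDurationRangeS = c(1.2, 1.5),
                            itiRangeS = c(2, 8),
                            breakRangeS = c(3, 8),
                            cueDurationS = 5,
                            instructionOrder = c("AABB", "BBAA"),
                            design = c("blocked", "interleaved"),
                            signalAmplitude = 1,
                            patternOverlap = 0.3,
                            noiseSd = 1,
                            ar1Coef = 0.3,
                            driftAmplitude = 1,
                            pCorrect = 0.5,
                            pImgGivenCorrect = 0.622,
                            pImgGivenIncorrect = 0.5,
                            seed = 1L) {
  new("GeneratorConfig",
    nSubjects = as.integer(nSubjects),
    nVoxels = as.integer(nVoxels),
    nTrainingRuns = as.integer(nTrainingRuns),
    trialsPerMiniblock = as.integer(trialsPerMiniblock),
    miniblocksPerRun = as.integer(miniblocksPerRun),
    nTransferTrials = as.integer(nTransferTrials),
    trS = trS,
    clipDurationRangeS = as.numeric(clipDurationRangeS),
    itiRangeS = as.numeric(itiRangeS),
    breakRangeS = as.numeric(breakRangeS),
    cueDurationS = cueDurationS,
    instructionOrder = match.arg(instructionOrder),
    design = match.arg(design),
    signalAmplitude = signalAmplitude,
    patternOverlap = patternOverlap,
    noiseSd = noiseSd,
    ar1Coef = ar1Coef,
    driftAmplitude = driftAmplitude,
    pCorrect = pCorrect,
    pImgGivenCorrect = pImgGivenCorrect,
    pImgGivenIncorrect = pImgGivenIncorrect,
    seed = as.integer(seed)
  )
}

#' Create double-gamma HRF parameters
#'
#' The canonical parameterisation: positive lobe peaking 6 s after onset,
#' undershoot at 16 s, unit dispersions, undershoot one sixth of the peak.
#' Each component is a gamma density with shape `delay/dispersion + 1`, so
#' its mode sits exactly at the stated delay.
#'
#' @param peakDelayS peak time, seconds.
#' @param undershootDelayS undershoot time, seconds.
#' @param peakDispersionS peak dispersion, seconds.
#' @param undershootDispersionS undershoot dispersion, seconds.
#' @param undershootRatio undershoot/peak amplitude ratio.
#' @param kernelLengthS sampled kernel length, seconds.
#' @param oversampling design-matrix oversampling (subdivisions per TR).
#' @return a validated [HrfParams-class].
#' @export
hrfParams <- function(peakDelayS = 6, undershootDelayS = 16,
                      peakDispersionS = 1, undershootDispersionS = 1,
                      undershootRatio = 1 / 6, kernelLengthS = 32,
                      oversampling = 20L) {
  new("HrfParams",
    peakDelayS = peakDelayS, undershootDelayS = undershootDelayS,
    peakDispersionS = peakDispersionS,
    undershootDispersionS = undershootDispersionS,
    undershootRatio = undershootRatio, kernelLengthS = kernelLengthS,
    oversampling = as.integer(oversampling)
  )
}

#' Create a pipeline configuration
#'
#' @param generator a [GeneratorConfig-class].
#' @param hrf an [HrfParams-class].
#' @param cutoffS high-pass cutoff period, seconds.
#' @param fwhmMm smoothing kernel FWHM, millimetres.
#' @param voxelSizeMm isotropic voxel size, millimetres.
#' @param kFolds cross-validation folds.
#' @param nPermDecoding within-task label permutations.
#' @param nPermTransfer cross-classification label permutations.
#' @param tThresh group t-map threshold.
#' @param minClusterVoxels minimum cluster extent (strictly exceeded).
#' @param connectivity 6 or 26.
#' @param alpha per-subject significance level.
#' @param seed analysis root seed.
#' @return a validated [PipelineConfig-class].
#' @export
pipelineConfig <- function(generator = generatorConfig(),
                           hrf = hrfParams(),
                           cutoffS = 100, fwhmMm = 5, voxelSizeMm = 3,
                           kFolds = 10L, nPermDecoding = 1000L,
                           nPermTransfer = 1000L, tThresh = 1.7,
                           minClusterVoxels = 200L, connectivity = 26L,
                           alpha = 0.05, seed = 1L) {
  new("PipelineConfig",
    generator = generator, hrf = hrf, cutoffS = cutoffS, fwhmMm = fwhmMm,
    voxelSizeMm = voxelSizeMm, kFolds = as.integer(kFolds),
    nPermDecoding = as.integer(nPermDecoding),
    nPermTransfer = as.integer(nPermTransfer), tThresh = tThresh,
    minClusterVoxels = as.integer(minClusterVoxels),
    connectivity = as.integer(connectivity), alpha = alpha,
    seed = as.integer(seed)
  )
}
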