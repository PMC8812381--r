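#' @import methods
#' @importFrom stats rnorm runif rbinom dgamma pt qnorm sd var convolve
#'   cor t.test p.adjust
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

#' Configuration of the synthetic study generator
#'
#' Holds every parameter of the forward model: the event schedule of the
#' two-condition training task (attention, ATT, vs kinesthetic imagery, IMG)
#' and of the 4-alternative penalty-reading transfer task; the multivariate
#' signal (condition prototype patterns); and the noise model (low-frequency
#' drift plus AR(1) Gaussian noise). Construct with [generatorConfig()].
#'
#' @slot nSubjects number of simulated subjects.
#' @slot nVoxels number of voxels on the rectangular grid.
#' @slot nTrainingRuns number of training-task runs (instruction blocks).
#' @slot trialsPerMiniblock video clips per mini-block (clips are separated
#'   by jittered ITIs; mini-blocks by jittered breaks).
#' @slot miniblocksPerRun mini-blocks in each run.
#' @slot nTransferTrials penalty-reading trials in the single transfer run.
#' @slot trS repetition time of the simulated acquisition, seconds.
#' @slot clipDurationRangeS min/max video clip duration, seconds.
#' @slot itiRangeS min/max inter-trial interval, seconds, on a 0.1-s grid.
#' @slot breakRangeS min/max mini-block break, seconds, on a 0.1-s grid.
#' @slot cueDurationS duration of the instruction cue opening each run.
#' @slot instructionOrder `"AABB"` or `"BBAA"`: which instruction occupies
#'   the first half of the training runs.
#' @slot design `"blocked"` (one instruction per run, the acquisition the
#'   package emulates) or `"interleaved"` (instructions randomised within
#'   run, used by the confound experiment as the leakage-free control).
#' @slot signalAmplitude GLM effect size of the condition pattern.
#' @slot patternOverlap Pearson correlation between the two condition
#'   prototype patterns, in \[-1, 1\].
#' @slot noiseSd marginal standard deviation of the AR(1) voxel noise.
#' @slot ar1Coef lag-1 autoregressive coefficient of the voxel noise.
#' @slot driftAmplitude scale of the low-frequency cosine drift loadings.
#' @slot pCorrect probability a transfer trial is correctly anticipated.
#' @slot pImgGivenCorrect probability a correct transfer trial is driven by
#'   the imagery pattern (the latent quantity the cross-classification
#'   statistic estimates).
#' @slot pImgGivenIncorrect same, for incorrectly anticipated trials.
#' @slot seed integer root seed; per-subject streams are derived from it.
#' @export
setClass("GeneratorConfig",
  representation(
    nSubjects = "integer",
    nVoxels = "integer",
    nTrainingRuns = "integer",
    trialsPerMiniblock = "integer",
    miniblocksPerRun = "integer",
    nTransferTrials = "integer",
    trS = "numeric",
    clipDurationRangeS = "numeric",
    itiRangeS = "numeric",
    breakRangeS = "numeric",
    cueDurationS = "numeric",
    instructionOrder = "character",
    design = "character",
    signalAmplitude = "numeric",
    patternOverlap = "numeric",
    noiseSd = "numeric",
    ar1Coef = "numeric",
    driftAmplitude = "numeric",
    pCorrect = "numeric",
    pImgGivenCorrect = "numeric",
    pImgGivenIncorrect = "numeric",
    seed = "integer"
  )
)

.checkRange <- function(x, what) {
  if (length(x) != 2L || any(!is.finite(x)))
    return(sprintf("%s must be two finite numbers", what))
  if (x[1] > x[2])
    return(sprintf("%s: lower bound %g exceeds upper bound %g", what, x[1], x[2]))
  NULL
}

setValidity("GeneratorConfig", function(object) {
  msg <- character()
  counts <- c(
    nSubjects = object@nSubjects, nVoxels = object@nVoxels,
    nTrainingRuns = object@nTrainingRuns,
    trialsPerMiniblock = object@trialsPerMiniblock,
    miniblocksPerRun = object@miniblocksPerRun,
    nTransferTrials = object@nTransferTrials
  )
  bad <- names(counts)[is.na(counts) | counts < 1L]
  if (length(bad)) msg <- c(msg, paste("positive count required for:",
                                       paste(bad, collapse = ", ")))
  if (!is.na(object@nVoxels) && object@nVoxels < 2L)
    msg <- c(msg, "nVoxels must be at least 2")
  if (object@trS <= 0) msg <- c(msg, "trS must be positive")
  for (w in c("clipDurationRangeS", "itiRangeS", "breakRangeS")) {
    e <- .checkRange(slot(object, w), w)
    if (!is.null(e)) msg <- c(msg, e)
  }
  if (object@nTrainingRuns %% 2L != 0L)
    msg <- c(msg, "nTrainingRuns must be even so class frequencies balance")
  if (!object@instructionOrder %in% c("AABB", "BBAA"))
    msg <- c(msg, "instructionOrder must be 'AABB' or 'BBAA'")
  if (!object@design %in% c("blocked", "interleaved"))
    msg <- c(msg, "design must be 'blocked' or 'interleaved'")
  probs <- c(pCorrect = object@pCorrect,
             pImgGivenCorrect = object@pImgGivenCorrect,
             pImgGivenIncorrect = object@pImgGivenIncorrect)
  badp <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
  if (length(badp)) msg <- c(msg, paste("probabilities must lie in [0, 1]:",
                                        paste(badp, collapse = ", ")))
  if (!is.finite(object@patternOverlap) ||
      abs(object@patternOverlap) > 1)
    msg <- c(msg, "patternOverlap must lie in [-1, 1]")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@ar1Coef < 0 || object@ar1Coef >= 1)
    msg <- c(msg, "ar1Coef must lie in [0, 1)")
  if (object@driftAmplitude < 0) msg <- c(msg, "driftAmplitude must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Double-gamma haemodynamic response parameters
#'
#' Canonical two-component haemodynamic response: a gamma-shaped positive
#' lobe peaking at `peakDelayS` minus a scaled gamma-shaped undershoot
#' peaking at `undershootDelayS`. Construct with [hrfParams()].
#'
#' @slot peakDelayS time of the positive peak, seconds.
#' @slot undershootDelayS time of the undershoot trough, seconds.
#' @slot peakDispersionS width parameter of the positive lobe.
#' @slot undershootDispersionS width parameter of the undershoot.
#' @slot undershootRatio undershoot amplitude relative to the peak.
#' @slot kernelLengthS length of the sampled kernel, seconds.
#' @slot oversampling design-matrix oversampling factor (subdivisions per TR).
#' @export
setClass("HrfParams",
  representation(
    peakDelayS = "numeric",
    undershootDelayS = "numeric",
    peakDispersionS = "numeric",
    undershootDispersionS = "numeric",
    undershootRatio = "numeric",
    kernelLengthS = "numeric",
    oversampling = "integer"
  )
)

setValidity("HrfParams", function(object) {
  msg <- character()
  pos <- c(peakDelayS = object@peakDelayS,
           undershootDelayS = object@undershootDelayS,
           peakDispersionS = object@peakDispersionS,
           undershootDispersionS = object@undershootDispersionS,
           undershootRatio = object@undershootRatio,
           kernelLengthS = object@kernelLengthS)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste("must be positive:", paste(bad, collapse = ", ")))
  if (is.na(object@oversampling) || object@oversampling < 1L)
    msg <- c(msg, "oversampling must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' A simulated or loaded BOLD run
#'
#' Extends [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' with one assay, `"bold"` (voxel x scan). Scan-level nuisance series (six
#' motion-like regressors and the global signal) live in `colData`; voxel
#' grid coordinates in `rowData`; the repetition time, grid dimensions and
#' the event table of the run in `metadata`.
#'
#' @export
setClass("BoldRun", contains = "SummarizedExperiment")

setValidity("BoldRun", function(object) {
  msg <- character()
  if (!"bold" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'bold' is required")
  md <- metadata(object)
  if (is.null(md$trS) || !is.finite(md$trS) || md$trS <= 0)
    msg <- c(msg, "metadata trS must be a positive repetition time")
  if (is.null(md$gridDim) || length(md$gridDim) != 3L ||
      prod(md$gridDim) != nrow(object))
    msg <- c(msg, "metadata gridDim must be 3 dimensions whose product is the voxel count")
  need <- c(paste0("motion_", 1:6), "global_signal")
  if (!all(need %in% colnames(colData(object))))
    msg <- c(msg, paste("colData must contain nuisance columns:",
                        paste(setdiff(need, colnames(colData(object))), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Trial-wise activation patterns
#'
#' Extends [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment]
#' with one assay, `"z"` (voxel x trial), holding single-trial z-statistic
#' patterns. `colData` carries per-trial `label` (ATT/IMG or penalty),
#' `run_id`, `trial_id` and, for transfer trials, `outcome`
#' (correct/incorrect anticipation). `metadata` keeps the voxel grid.
#'
#' @export
setClass("TrialPatternDataset", contains = "SummarizedExperiment")

setValidity("TrialPatternDataset", function(object) {
  msg <- character()
  if (!"z" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'z' is required")
  else if (!all(is.finite(assay(object, "z"))))
    msg <- c(msg, "z values must all be finite")
  need <- c("label", "run_id", "trial_id")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste("colData must contain:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A design matrix for the single-trial (least-squares-all) GLM
#'
#' One haemodynamically convolved regressor per trial plus seven unconvolved
#' nuisance columns (six motion, one global signal). Built by
#' [buildDesignMatrix()].
#'
#' @slot design scan x regressor numeric matrix.
#' @slot roles character role per column: `"trial"`, `"motion"` or
#'   `"global_signal"`.
#' @slot trialIds integer trial id per column (NA for nuisance columns).
#' @export
setClass("DesignMatrix",
  representation(design = "matrix", roles = "character", trialIds = "integer")
)

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (ncol(object@design) != length(object@roles) ||
      ncol(object@design) != length(object@trialIds))
    msg <- c(msg, "roles and trialIds must have one entry per column")
  tc <- object@roles == "trial"
  if (any(tc)) {
    zero <- which(tc)[colSums(abs(object@design[, tc, drop = FALSE])) == 0]
    if (length(zero))
      msg <- c(msg, paste("all-zero trial columns:", paste(zero, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' A trained two-class linear decision rule
#'
#' Weight vector, intercept and the stored class-label order of a linear
#' support-vector classifier. The decision rule is
#' `score = weights . x + intercept`; `score >= 0` predicts `labels[1]`
#' (ties at the boundary deterministically take the first stored label).
#'
#' @slot weights numeric weight vector, one entry per voxel.
#' @slot intercept numeric intercept.
#' @slot labels length-2 character vector; `labels[1]` is the positive side.
#' @export
setClass("LinearModel",
  representation(weights = "numeric", intercept = "numeric", labels = "character")
)

setValidity("LinearModel", function(object) {
  msg <- character()
  if (!all(is.finite(object@weights)) || !is.finite(object@intercept))
    msg <- c(msg, "weights and intercept must be finite")
  if (length(object@labels) != 2L || anyDuplicated(object@labels))
    msg <- c(msg, "labels must be two distinct class names")
  if (length(msg)) msg else TRUE
})

#' Within-task decoding result for one subject
#'
#' @slot foldAccuracies accuracy on each held-out fold.
#' @slot meanAccuracy arithmetic mean of the fold accuracies.
#' @slot nullAccuracies permutation-null mean accuracies (one per shuffle).
#' @slot pValue add-one permutation p-value.
#' @slot weights fold-averaged classifier weight vector.
#' @slot intercept fold-averaged intercept.
#' @slot labels stored class-label order of the fold models.
#' @export
setClass("DecodingResult",
  representation(
    foldAccuracies = "numeric", meanAccuracy = "numeric",
    nullAccuracies = "numeric", pValue = "numeric",
    weights = "numeric", intercept = "numeric", labels = "character"
  )
)

setValidity("DecodingResult", function(object) {
  msg <- character()
  if (any(object@foldAccuracies < 0 | object@foldAccuracies > 1))
    msg <- c(msg, "fold accuracies must lie in [0, 1]")
  if (abs(object@meanAccuracy - mean(object@foldAccuracies)) > 1e-12)
    msg <- c(msg, "meanAccuracy must equal the mean of foldAccuracies")
  if (length(object@pValue) &&
      (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Group-level statistics of classifier weight maps
#'
#' @slot tValues per-voxel one-sample t of subject fold-averaged weights
#'   against zero (infinite sentinel where the across-subject variance is 0).
#' @slot df degrees of freedom (subjects - 1).
#' @slot zeroVariance logical flag per voxel marking the sentinel values.
#' @slot gridDim voxel grid dimensions.
#' @export
setClass("GroupWeightStats",
  representation(tValues = "numeric", df = "integer",
                 zeroVariance = "logical", gridDim = "integer")
)

#' Per-subject cross-classification result
#'
#' @slot predictions predicted label (ATT/IMG) per transfer trial.
#' @slot outcomes outcome (correct/incorrect) per transfer trial.
#' @slot imgProportion fraction of correctly anticipated trials predicted IMG.
#' @slot nullProportions permutation-null IMG proportions.
#' @slot pValue one-sided (greater-than-chance) add-one permutation p-value.
#' @export
setClass("TransferResult",
  representation(predictions = "character", outcomes = "character",
                 imgProportion = "numeric", nullProportions = "numeric",
                 pValue = "numeric")
)

#' Group-level cross-classification result
#'
#' @slot subjectProportions per-subject IMG proportions on correct trials.
#' @slot subjectPValues per-subject permutation p-values (may be empty).
#' @slot groupMean mean proportion across subjects.
#' @slot groupSd standard deviation across subjects.
#' @slot groupT one-sample t statistic against chance (0.5).
#' @slot groupDf degrees of freedom (subjects - 1).
#' @slot groupP two-sided p-value.
#' @slot nSignificant subjects individually above chance at `alpha`.
#' @slot alpha per-subject significance level.
#' @export
setClass("CrossClassResult",
  representation(
    subjectProportions = "numeric", subjectPValues = "numeric",
    groupMean = "numeric", groupSd = "numeric", groupT = "numeric",
    groupDf = "integer", groupP = "numeric",
    nSignificant = "integer", alpha = "numeric"
  )
)

#' Result of the blocked-design inflation experiment
#'
#' @slot arms data.frame with one row per design arm x metric: mean and
#'   Monte-Carlo standard error of the null cross-validated accuracy and of
#'   the null cross-classification proportion.
#' @slot perReplicate data.frame of per-replicate metrics.
#' @slot nReplicates number of simulated null subjects per arm.
#' @slot configs the generator configurations of the arms.
#' @export
setClass("ConfoundReport",
  representation(arms = "data.frame", perReplicate = "data.frame",
                 nReplicates = "integer", configs = "list")
)

#' A complete simulated subject
#'
#' @slot trainingRuns list of [BoldRun-class] objects, one per training run.
#' @slot transferRun the penalty-reading [BoldRun-class].
#' @slot prototypes 2 x voxel matrix of condition prototype patterns
#'   (rows "ATT", "IMG").
#' @slot truth per-transfer-trial data.frame of latent strategy and outcome.
#' @slot config the [GeneratorConfig-class] used.
#' @slot subject subject index.
#' @export
setClass("SubjectStudy",
  representation(trainingRuns = "list", transferRun = "BoldRun",
                 prototypes = "matrix", truth = "data.frame",
                 config = "GeneratorConfig", subject = "integer")
)

#' Full pipeline configuration
#'
#' Analysis constants default to the values used throughout the package:
#' 10-fold cross-validation, 1,000 permutation iterations, a 100-s high-pass
#' cutoff, 5-mm FWHM smoothing, and cluster thresholding at t > 1.7 with a
#' 200-voxel minimum extent. Construct with [pipelineConfig()].
#'
#' @slot generator a [GeneratorConfig-class].
#' @slot hrf an [HrfParams-class].
#' @slot cutoffS high-pass cutoff period, seconds.
#' @slot fwhmMm spatial smoothing kernel FWHM, millimetres.
#' @slot voxelSizeMm isotropic voxel size, millimetres.
#' @slot kFolds cross-validation folds.
#' @slot nPermDecoding label permutations for within-task inference.
#' @slot nPermTransfer label permutations for cross-classification inference.
#' @slot tThresh group t-map threshold.
#' @slot minClusterVoxels minimum cluster extent (strictly exceeded).
#' @slot connectivity 6 or 26 neighbour connectivity for clustering.
#' @slot alpha per-subject significance level.
#' @slot seed analysis-stage root seed.
#' @export
setClass("PipelineConfig",
  representation(
    generator = "GeneratorConfig", hrf = "HrfParams",
    cutoffS = "numeric", fwhmMm = "numeric", voxelSizeMm = "numeric",
    kFolds = "integer", nPermDecoding = "integer", nPermTransfer = "integer",
    tThresh = "numeric", minClusterVoxels = "integer",
    connectivity = "integer", alpha = "numeric", seed = "integer"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  if (is.na(object@kFolds) || object@kFolds < 2L)
    msg <- c(msg, "kFolds must be at least 2")
  if (object@nPermDecoding < 1L || object@nPermTransfer < 1L)
    msg <- c(msg, "permutation counts must be positive")
  if (object@cutoffS <= 2 * object@generator@trS)
    msg <- c(msg, "cutoffS must exceed twice the repetition time")
  if (object@fwhmMm < 0) msg <- c(msg, "fwhmMm must be non-negative")
  if (object@tThresh < 0) msg <- c(msg, "tThresh must be non-negative")
  if (!object@connectivity %in% c(6L, 26L))
    msg <- c(msg, "connectivity must be 6 or 26")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
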