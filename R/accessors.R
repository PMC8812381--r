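#' @name accessors
#' @title Accessors for crossdecode objects
#' @description Slot access for the package's S4 classes goes through these
#'   generics; downstream code never reaches into slots directly.
#' @param object,x an object of the documented class.
#' @param ... unused.
NULL

#' @rdname accessors
#' @export
setGeneric("zMatrix", function(x) standardGeneric("zMatrix"))

#' @describeIn accessors trial x voxel matrix of single-trial z-statistics.
#' @export
setMethod("zMatrix", "TrialPatternDataset", function(x) t(assay(x, "z")))

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @describeIn accessors per-trial annotation (label, run, outcome) as a
#'   data.frame in trial order.
#' @export
setMethod("trialInfo", "TrialPatternDataset",
          function(x) as.data.frame(colData(x)))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @describeIn accessors per-trial condition labels.
#' @export
setMethod("trialLabels", "TrialPatternDataset",
          function(x) as.character(colData(x)$label))

#' @rdname accessors
#' @export
setGeneric("trialOutcomes", function(x) standardGeneric("trialOutcomes"))

#' @describeIn accessors per-trial behavioural outcomes (NA for training).
#' @export
setMethod("trialOutcomes", "TrialPatternDataset", function(x) {
  oc <- colData(x)$outcome
  if (is.null(oc)) rep(NA_character_, ncol(x)) else as.character(oc)
})

#' @rdname accessors
#' @export
setGeneric("boldSignal", function(x) standardGeneric("boldSignal"))

#' @describeIn accessors scan x voxel BOLD signal matrix.
#' @export
setMethod("boldSignal", "BoldRun", function(x) t(assay(x, "bold")))

#' @rdname accessors
#' @export
setGeneric("boldTr", function(x) standardGeneric("boldTr"))

#' @describeIn accessors repetition time of the run, seconds.
#' @export
setMethod("boldTr", "BoldRun", function(x) metadata(x)$trS)

#' @rdname accessors
#' @export
setGeneric("boldGridDim", function(x) standardGeneric("boldGridDim"))

#' @describeIn accessors 3-D voxel grid dimensions of the run.
#' @export
setMethod("boldGridDim", "BoldRun", function(x) metadata(x)$gridDim)

#' @rdname accessors
#' @export
setGeneric("nuisance", function(x) standardGeneric("nuisance"))

#' @describeIn accessors scan x 7 matrix of nuisance series (six motion-like
#'   columns and the global signal).
#' @export
setMethod("nuisance", "BoldRun", function(x) {
  cd <- colData(x)
  as.matrix(as.data.frame(cd[, c(paste0("motion_", 1:6), "global_signal")]))
})

#' @rdname accessors
#' @export
setGeneric("runEvents", function(x) standardGeneric("runEvents"))

#' @describeIn accessors the event table of the run.
#' @export
setMethod("runEvents", "BoldRun", function(x) metadata(x)$events)

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @describeIn accessors weight vector of a linear model.
#' @export
setMethod("modelWeights", "LinearModel", function(x) x@weights)

#' @describeIn accessors fold-averaged weight vector of a decoding result.
#' @export
setMethod("modelWeights", "DecodingResult", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("modelIntercept", function(x) standardGeneric("modelIntercept"))

#' @describeIn accessors intercept of a linear model.
#' @export
setMethod("modelIntercept", "LinearModel", function(x) x@intercept)

#' @rdname accessors
#' @export
setGeneric("labelOrder", function(x) standardGeneric("labelOrder"))

#' @describeIn accessors stored class-label order (first label is the
#'   positive decision side).
#' @export
setMethod("labelOrder", "LinearModel", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))

#' @describeIn accessors per-fold held-out accuracies.
#' @export
setMethod("foldAccuracies", "DecodingResult", function(x) x@foldAccuracies)

#' @rdname accessors
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))

#' @describeIn accessors mean cross-validated accuracy.
#' @export
setMethod("meanAccuracy", "DecodingResult", function(x) x@meanAccuracy)

#' @rdname accessors
#' @export
setGeneric("nullDistribution", function(x) standardGeneric("nullDistribution"))

#' @describeIn accessors permutation-null accuracies.
#' @export
setMethod("nullDistribution", "DecodingResult", function(x) x@nullAccuracies)

#' @describeIn accessors permutation-null IMG proportions.
#' @export
setMethod("nullDistribution", "TransferResult", function(x) x@nullProportions)

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @describeIn accessors permutation p-value of the decoding result.
#' @export
setMethod("pValue", "DecodingResult", function(x) x@pValue)

#' @describeIn accessors permutation p-value of the transfer result.
#' @export
setMethod("pValue", "TransferResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("imgProportionOf", function(x) standardGeneric("imgProportionOf"))

#' @describeIn accessors observed IMG proportion on correct transfer trials.
#' @export
setMethod("imgProportionOf", "TransferResult", function(x) x@imgProportion)

#' @rdname accessors
#' @export
setGeneric("transferPredictions", function(x) standardGeneric("transferPredictions"))

#' @describeIn accessors predicted label per transfer trial.
#' @export
setMethod("transferPredictions", "TransferResult", function(x) x@predictions)

#' @rdname accessors
#' @export
setGeneric("groupStats", function(x) standardGeneric("groupStats"))

#' @describeIn accessors named list of the group-level statistics.
#' @export
setMethod("groupStats", "CrossClassResult", function(x) {
  list(mean = x@groupMean, sd = x@groupSd, t = x@groupT, df = x@groupDf,
       p = x@groupP, nSignificant = x@nSignificant, alpha = x@alpha)
})

#' @rdname accessors
#' @export
setGeneric("armSummary", function(x) standardGeneric("armSummary"))

#' @describeIn accessors arm x metric summary of a confound report.
#' @export
setMethod("armSummary", "ConfoundReport", function(x) x@arms)

setMethod("show", "GeneratorConfig", function(object) {
  cat("GeneratorConfig:",
      object@nSubjects, "subject(s),", object@nVoxels, "voxels\n")
  cat(sprintf(
    "  training: %d runs x %d mini-blocks x %d trials (%s, %s order)\n",
    object@nTrainingRuns, object@miniblocksPerRun, object@trialsPerMiniblock,
    object@design, object@instructionOrder))
  cat(sprintf("  transfer: %d trials | TR %.1f s\n",
              object@nTransferTrials, object@trS))
  cat(sprintf(
    "  signal %.3g (overlap %.2f) | noise sd %.3g ar1 %.2f drift %.3g\n",
    object@signalAmplitude, object@patternOverlap, object@noiseSd,
    object@ar1Coef, object@driftAmplitude))
  cat(sprintf("  P(correct) %.2f, P(IMG|correct) %.3f, seed %d\n",
              object@pCorrect, object@pImgGivenCorrect, object@seed))
})

setMethod("show", "BoldRun", function(object) {
  cat(sprintf("BoldRun: %d voxels x %d scans (TR %.1f s, grid %s), %d events\n",
              nrow(object), ncol(object), metadata(object)$trS,
              paste(metadata(object)$gridDim, collapse = "x"),
              nrow(metadata(object)$events %||% data.frame())))
})

setMethod("show", "TrialPatternDataset", function(object) {
  lb <- table(colData(object)$label)
  cat(sprintf("TrialPatternDataset: %d trials x %d voxels (%s)\n",
              ncol(object), nrow(object),
              paste(sprintf("%s=%d", names(lb), lb), collapse = ", ")))
})

setMethod("show", "LinearModel", function(object) {
  cat(sprintf("LinearModel: %d weights, intercept %.4g, labels %s > 0 > %s\n",
              length(object@weights), object@intercept,
              object@labels[1], object@labels[2]))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: mean accuracy %.3f over %d folds",
              object@meanAccuracy, length(object@foldAccuracies)))
  if (length(object@nullAccuracies))
    cat(sprintf(", permutation p = %.4g (%d shuffles)",
                object@pValue, length(object@nullAccuracies)))
  cat("\n")
})

setMethod("show", "TransferResult", function(object) {
  cat(sprintf("TransferResult: IMG proportion on correct trials %.3f",
              object@imgProportion))
  if (length(object@nullProportions))
    cat(sprintf(", permutation p = %.4g", object@pValue))
  cat("\n")
})

setMethod("show", "CrossClassResult", function(object) {
  cat(sprintf(
    "CrossClassResult: %d subjects, mean IMG proportion %.3f (SD %.3f)\n",
    length(object@subjectProportions), object@groupMean, object@groupSd))
  cat(sprintf("  t(%d) = %.3f, p = %.4g; %d subject(s) above chance at alpha %.2g\n",
              object@groupDf, object@groupT, object@groupP,
              object@nSignificant, object@alpha))
})

setMethod("show", "ConfoundReport", function(object) {
  cat(sprintf("ConfoundReport over %d replicates per arm:\n", object@nReplicates))
  print(object@arms, row.names = FALSE)
})

setMethod("show", "SubjectStudy", function(object) {
  cat(sprintf("SubjectStudy %d: %d training runs + transfer (%d voxels)\n",
              object@subject, length(object@trainingRuns),
              object@config@nVoxels))
})
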