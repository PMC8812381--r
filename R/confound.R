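#' Default arms for the blocked-design inflation experiment
#'
#' Two generator configurations under the global null (zero condition
#' signal): a `blocked` arm with run-blocked instructions, autocorrelated
#' noise (AR(1) coefficient 0.6) and strong low-frequency drift — the
#' mechanism by which within-task cross-validation becomes optimistic — and
#' an `interleaved` arm with randomised within-run labels and temporally
#' unstructured (white, drift-free) noise, the exchangeable null under which
#' cross-validation is exactly calibrated. Temporal dependence distorts
#' cross-validated accuracy in a design-dependent direction (upward when
#' conditions are run-blocked, downward when interleaved trials share slow
#' noise), so the calibrated control must remove the dependence, not merely
#' interleave the labels.
#'
#' Dimensions are reduced (125 voxels, 24 transfer trials) so a replicate is
#' cheap; the mathematics is unchanged.
#'
#' @param nVoxels voxels per subject.
#' @param nTransferTrials transfer trials per subject.
#' @param seed root seed stored in both configs (replicates re-derive it).
#' @return named list of two [GeneratorConfig-class] objects.
#' @export
confoundArms <- function(nVoxels = 125L, nTransferTrials = 24L, seed = 1L) {
  base <- function(design, ar1, drift) {
    generatorConfig(
      nVoxels = nVoxels, nTransferTrials = nTransferTrials,
      signalAmplitude = 0, design = design,
      ar1Coef = ar1, driftAmplitude = drift,
      pCorrect = 0.5, pImgGivenCorrect = 0.5, pImgGivenIncorrect = 0.5,
      seed = seed
    )
  }
  list(blocked = base("blocked", ar1 = 0.6, drift = 2),
       interleaved = base("interleaved", ar1 = 0, drift = 0))
}

#' Run the blocked-design inflation experiment
#'
#' For each replicate and arm, a null subject (zero condition signal) is
#' simulated, first-level patterns are estimated, and two metrics are
#' recorded: the within-task stratified 10-fold cross-validated accuracy and
#' the cross-classification IMG proportion on correct transfer trials
#' (single full-model fit, no permutation). Means and Monte-Carlo standard
#' errors per arm quantify whether run-blocked conditions plus temporal
#' autocorrelation inflate cross-validated accuracy above chance while the
#' cross-task statistic stays at 0.5.
#'
#' @param arms named list of [GeneratorConfig-class] objects, all with
#'   `signalAmplitude = 0` (the experiment is defined under the null).
#' @param nReplicates simulated subjects per arm.
#' @param seed root seed; replicate r of arm a uses a derived child stream.
#' @param kFolds cross-validation folds.
#' @param fwhmMm smoothing FWHM passed to first-level processing.
#' @return a [ConfoundReport-class].
#' @export
runInflationExperiment <- function(arms = confoundArms(), nReplicates = 50L,
                                   seed = 1L, kFolds = 10L, fwhmMm = 5) {
  if (is.null(names(arms)) || any(names(arms) == ""))
    stop("arms must be a named list of GeneratorConfig objects")
  for (nm in names(arms)) {
    cfg <- arms[[nm]]
    validObject(cfg)
    if (cfg@signalAmplitude != 0)
      stop(sprintf(
        "arm '%s' has signalAmplitude %g; the experiment is defined under the null",
        nm, cfg@signalAmplitude))
  }
  if (nReplicates < 1L) stop("nReplicates must be positive")

  rows <- vector("list", length(arms) * nReplicates)
  i <- 0L
  for (a in seq_along(arms)) {
    cfg <- arms[[a]]
    for (r in seq_len(nReplicates)) {
      repCfg <- cfg
      repCfg@seed <- subjectSeed(seed, (a - 1L) * nReplicates + r)
      study <- simulateSubject(repCfg)
      pats <- trialPatterns(study, fwhmMm = fwhmMm)
      cv <- crossValidate(pats$training, k = kFolds,
                          seed = subjectSeed(repCfg@seed, 1L))
      tr <- crossClassifySubject(pats$training, pats$transfer, nPerm = 0L)
      i <- i + 1L
      rows[[i]] <- data.frame(
        arm = names(arms)[a], replicate = r,
        cv_accuracy = cv$meanAccuracy,
        crossclass_proportion = imgProportionOf(tr)
      )
    }
  }
  per <- do.call(rbind, rows)
  armTab <- do.call(rbind, lapply(split(per, per$arm), function(d) {
    data.frame(
      arm = d$arm[1],
      metric = c("null_cv_accuracy", "null_crossclass_proportion"),
      mean = c(mean(d$cv_accuracy), mean(d$crossclass_proportion)),
      se = c(sd(d$cv_accuracy), sd(d$crossclass_proportion)) /
        sqrt(nrow(d))
    )
  }))
  rownames(armTab) <- NULL
  new("ConfoundReport", arms = armTab, perReplicate = per,
      nReplicates = as.integer(nReplicates),
      configs = arms)
}
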