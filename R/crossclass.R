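#' Fit the transfer classifier on all training trials
#'
#' A single linear SVM refit on the complete (balanced) two-class training
#' set; this is the model that is carried across tasks.
#'
#' @param training a [TrialPatternDataset-class] of training-task trials,
#'   or a trial x voxel matrix with `y` given.
#' @param y labels when `training` is a plain matrix.
#' @param cost SVM soft-margin constant.
#' @return a [LinearModel-class].
#' @export
fitFullModel <- function(training, y = NULL, cost = 1) {
  if (is(training, "TrialPatternDataset")) {
    X <- zMatrix(training)
    y <- trialLabels(training)
  } else {
    X <- as.matrix(training)
  }
  tab <- table(y)
  if (length(tab) != 2L || length(unique(tab)) != 1L)
    warning("training labels are not exactly balanced")
  trainLinearSvm(X, y, cost = cost)
}

#' Predict transfer-trial labels
#'
#' Applies the training-task decision rule to every penalty-reading trial,
#' classifying each as ATT or IMG.
#'
#' @param model a [LinearModel-class].
#' @param transfer a [TrialPatternDataset-class] or trial x voxel matrix.
#' @return character vector of predicted labels, one per transfer trial.
#' @export
predictTransfer <- function(model, transfer) {
  X <- if (is(transfer, "TrialPatternDataset")) zMatrix(transfer)
       else as.matrix(transfer)
  predictLinear(model, X)
}

#' Proportion of IMG predictions on correctly anticipated trials
#'
#' The cross-classification statistic: among transfer trials whose direction
#' was correctly anticipated, the fraction the classifier labels IMG
#' (equivalently, the classifier's recall with correct trials as the
#' positive class).
#'
#' @param predictions predicted label per transfer trial.
#' @param outcomes `"correct"`/`"incorrect"` per transfer trial.
#' @return proportion in \[0, 1\].
#' @export
imgProportion <- function(predictions, outcomes) {
  if (length(predictions) != length(outcomes))
    stop("predictions and outcomes differ in length")
  correct <- outcomes == "correct"
  if (!any(correct))
    stop("undefined statistic: no correctly anticipated transfer trials")
  mean(predictions[correct] == "IMG")
}

#' Per-subject permutation null of the cross-classification statistic
#'
#' Each iteration shuffles the training labels, refits the full model, and
#' recomputes the IMG proportion on the (unchanged) transfer trials. The
#' one-sided p-value uses the add-one convention
#' `p = (1 + #\{null >= observed\}) / (1 + nPerm)`.
#'
#' @param training training-task [TrialPatternDataset-class] or matrix.
#' @param transfer transfer-task [TrialPatternDataset-class] or matrix.
#' @param y training labels when `training` is a plain matrix.
#' @param outcomes transfer outcomes when `transfer` is a plain matrix.
#' @param nPerm number of label shuffles.
#' @param seed optional integer for a local RNG stream.
#' @param cost SVM soft-margin constant.
#' @return a [TransferResult-class].
#' @export
subjectPermutationNull <- function(training, transfer, y = NULL,
                                   outcomes = NULL, nPerm = 1000L,
                                   seed = NULL, cost = 1) {
  if (nPerm < 1L) stop("nPerm must be at least 1")
  if (is(training, "TrialPatternDataset")) {
    Xtr <- zMatrix(training)
    y <- trialLabels(training)
  } else Xtr <- as.matrix(training)
  if (is(transfer, "TrialPatternDataset")) {
    Xte <- zMatrix(transfer)
    outcomes <- trialOutcomes(transfer)
  } else Xte <- as.matrix(transfer)
  y <- as.character(y)
  outcomes <- as.character(outcomes)

  withSeed(seed, {
    model <- trainLinearSvm(Xtr, y, cost = cost)
    preds <- predictLinear(model, Xte)
    observed <- imgProportion(preds, outcomes)
    nullProp <- vapply(seq_len(nPerm), function(i) {
      m <- trainLinearSvm(Xtr, sample(y), cost = cost)
      imgProportion(predictLinear(m, Xte), outcomes)
    }, numeric(1))
    new("TransferResult",
        predictions = preds, outcomes = outcomes,
        imgProportion = observed, nullProportions = nullProp,
        pValue = (1 + sum(nullProp >= observed)) / (1 + nPerm))
  })
}

#' Cross-classify one subject
#'
#' Convenience wrapper: fit the full training model, predict the transfer
#' trials, compute the IMG proportion on correct trials, and (optionally)
#' run the per-subject label-permutation test.
#'
#' @inheritParams subjectPermutationNull
#' @param nPerm label shuffles (0 skips the permutation null).
#' @return a [TransferResult-class].
#' @export
crossClassifySubject <- function(training, transfer, nPerm = 1000L,
                                 seed = NULL, cost = 1) {
  if (nPerm > 0L)
    return(subjectPermutationNull(training, transfer, nPerm = nPerm,
                                  seed = seed, cost = cost))
  model <- fitFullModel(training, cost = cost)
  preds <- predictTransfer(model, transfer)
  outcomes <- trialOutcomes(transfer)
  new("TransferResult",
      predictions = preds, outcomes = outcomes,
      imgProportion = imgProportion(preds, outcomes),
      nullProportions = numeric(0), pValue = numeric(0))
}

#' Group-level test of the IMG proportion against chance
#'
#' One-sample t-test of the per-subject proportions against 0.5 (two-sided),
#' with `df = nSubjects - 1`. Zero across-subject variance yields an
#' infinite sentinel t with `p = NA`.
#'
#' @param proportions one IMG proportion per subject.
#' @return list with `mean`, `sd`, `t`, `df`, `p`.
#' @export
groupProportionTest <- function(proportions) {
  proportions <- as.numeric(proportions)
  n <- length(proportions)
  if (n < 3L) stop("at least 3 subjects are required")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  m <- mean(proportions)
  s <- sd(proportions)
  if (s == 0) {
    t <- if (m == 0.5) 0 else sign(m - 0.5) * Inf
    p <- if (m == 0.5) 1 else NA_real_
  } else {
    tt <- t.test(proportions, mu = 0.5)
    t <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(mean = m, sd = s, t = t, df = n - 1L, p = p)
}

#' Count subjects individually above chance
#'
#' @param pValues per-subject one-sided (greater-than-chance) p-values.
#' @param alpha significance level.
#' @return number of subjects with `p < alpha`.
#' @export
countSignificantSubjects <- function(pValues, alpha = 0.05) {
  pValues <- as.numeric(pValues)
  if (any(pValues <= 0 | pValues > 1))
    stop("p-values must lie in (0, 1]")
  sum(pValues < alpha)
}

#' Assemble the group cross-classification result
#'
#' @param results list of per-subject [TransferResult-class] objects.
#'   Subjects whose statistic is undefined (no correct trials) must already
#'   be excluded upstream.
#' @param alpha per-subject significance level.
#' @return a [CrossClassResult-class].
#' @export
groupCrossClass <- function(results, alpha = 0.05) {
  props <- vapply(results, imgProportionOf, numeric(1))
  pvals <- unlist(lapply(results, function(r)
    if (length(r@pValue)) r@pValue else NULL))
  g <- groupProportionTest(props)
  nSig <- if (length(pvals)) countSignificantSubjects(pvals, alpha) else 0L
  new("CrossClassResult",
      subjectProportions = props,
      subjectPValues = as.numeric(pvals %||% numeric(0)),
      groupMean = g$mean, groupSd = g$sd, groupT = g$t,
      groupDf = as.integer(g$df), groupP = g$p,
      nSignificant = as.integer(nSig), alpha = alpha)
}
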