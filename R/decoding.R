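#' Train a two-class linear support-vector classifier
#'
#' Soft-margin linear SVM with regularisation constant 1 (the library
#' default), no feature scaling, deterministic for a fixed input order.
#' The fitted hyperplane is returned as an explicit weight vector and
#' intercept with a stored label order: `weights . x + intercept >= 0`
#' predicts the first stored label.
#'
#' @param X trial x voxel feature matrix.
#' @param y per-trial class labels (exactly two classes).
#' @param cost soft-margin constant.
#' @return a [LinearModel-class].
#' @export
trainLinearSvm <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  labs <- sort(unique(y))
  if (length(labs) != 2L)
    stop(sprintf("exactly two classes required, got: %s",
                 paste(labs, collapse = ", ")))
  fit <- e1071::svm(X, factor(y, levels = labs), kernel = "linear",
                    cost = cost, scale = FALSE)
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # orient the hyperplane so score >= 0 <=> libsvm predicts labs[1]
  scores <- as.numeric(X %*% w + b)
  preds <- as.character(stats::predict(fit, X))
  ruled <- ifelse(scores >= 0, labs[1], labs[2])
  disagree <- sum(ruled != preds)
  if (disagree > sum(ruled == preds)) {
    w <- -w
    b <- -b
  }
  new("LinearModel", weights = w, intercept = b, labels = labs)
}

#' Predict labels with a linear model
#'
#' @param model a [LinearModel-class].
#' @param X trial x voxel matrix with matching voxel dimension.
#' @return character vector of predicted labels; decision-boundary ties go
#'   to the first stored label.
#' @export
predictLinear <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model@weights))
    stop(sprintf("voxel dimension mismatch: model has %d, data has %d",
                 length(model@weights), ncol(X)))
  s <- as.numeric(X %*% model@weights + model@intercept)
  ifelse(s >= 0, model@labels[1], model@labels[2])
}

# stratified fold assignment: shuffle within class, deal round-robin so
# every fold keeps the class balance to within one trial.
stratifiedFolds <- function(y, k) {
  y <- as.character(y)
  if (k < 2L) stop("k must be at least 2")
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop(sprintf("class '%s' has %d trials, fewer than k = %d folds",
                   cl, length(idx), k))
    fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validated decoding
#'
#' @param data a [TrialPatternDataset-class], or a trial x voxel matrix if
#'   `y` is given.
#' @param y labels (taken from the dataset when omitted).
#' @param k number of folds.
#' @param seed optional integer for a local RNG stream (fold assignment).
#' @param cost SVM soft-margin constant.
#' @return list with `foldAccuracies`, `meanAccuracy`, `foldModels` (list of
#'   [LinearModel-class]) and the fold assignment.
#' @export
crossValidate <- function(data, y = NULL, k = 10L, seed = NULL, cost = 1) {
  if (is(data, "TrialPatternDataset")) {
    X <- zMatrix(data)
    y <- trialLabels(data)
  } else {
    X <- as.matrix(data)
    if (is.null(y)) stop("y is required when data is a plain matrix")
    y <- as.character(y)
  }
  withSeed(seed, {
    fold <- stratifiedFolds(y, k)
    acc <- numeric(k)
    models <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fold != f
      m <- trainLinearSvm(X[tr, , drop = FALSE], y[tr], cost = cost)
      acc[f] <- mean(predictLinear(m, X[!tr, , drop = FALSE]) == y[!tr])
      models[[f]] <- m
    }
    list(foldAccuracies = acc, meanAccuracy = mean(acc),
         foldModels = models, fold = fold)
  })
}

#' Permutation test of cross-validated accuracy
#'
#' Each iteration shuffles the class labels, reruns the full k-fold
#' cross-validation, and records the mean accuracy. The p-value uses the
#' add-one convention `p = (1 + #\{null >= observed\}) / (1 + nPerm)`.
#'
#' @inheritParams crossValidate
#' @param nPerm number of label shuffles.
#' @return list with `observed`, `nullAccuracies`, `pValue`.
#' @export
permutationTestAccuracy <- function(data, y = NULL, k = 10L, nPerm = 1000L,
                                    seed = NULL, cost = 1) {
  if (nPerm < 1L) stop("nPerm must be at least 1")
  if (is(data, "TrialPatternDataset")) {
    X <- zMatrix(data)
    y <- trialLabels(data)
  } else {
    X <- as.matrix(data)
    y <- as.character(y)
  }
  withSeed(seed, {
    observed <- crossValidate(X, y, k = k, cost = cost)$meanAccuracy
    nullAcc <- vapply(seq_len(nPerm), function(i) {
      crossValidate(X, sample(y), k = k, cost = cost)$meanAccuracy
    }, numeric(1))
    list(observed = observed, nullAccuracies = nullAcc,
         pValue = (1 + sum(nullAcc >= observed)) / (1 + nPerm))
  })
}

#' Average classifier weights across folds
#'
#' @param models list of [LinearModel-class] fold models with identical
#'   voxel dimension and label order.
#' @return list with the element-wise mean `weights` and `intercept`.
#' @export
averageFoldWeights <- function(models) {
  if (!length(models)) stop("at least one fold model is required")
  dims <- vapply(models, function(m) length(m@weights), integer(1))
  if (length(unique(dims)) != 1L)
    stop("fold models have inconsistent weight dimensions")
  labs <- models[[1]]@labels
  W <- vapply(models, function(m) {
    if (!identical(m@labels, labs)) stop("fold models disagree on label order")
    m@weights
  }, numeric(dims[1]))
  list(weights = rowMeans(W),
       intercept = mean(vapply(models, function(m) m@intercept, numeric(1))),
       labels = labs)
}

#' Full within-task decoding for one subject
#'
#' Cross-validated accuracy, label-permutation inference and fold-averaged
#' weights in one call.
#'
#' @param data a [TrialPatternDataset-class] of training-task trials.
#' @param k folds.
#' @param nPerm label shuffles (0 skips inference).
#' @param seed optional integer for a local RNG stream.
#' @return a [DecodingResult-class].
#' @export
decodeSubject <- function(data, k = 10L, nPerm = 1000L, seed = NULL) {
  withSeed(seed, {
    cv <- crossValidate(data, k = k)
    avg <- averageFoldWeights(cv$foldModels)
    if (nPerm > 0L) {
      perm <- permutationTestAccuracy(data, k = k, nPerm = nPerm)
      nullAcc <- perm$nullAccuracies
      p <- (1 + sum(nullAcc >= cv$meanAccuracy)) / (1 + nPerm)
    } else {
      nullAcc <- numeric(0)
      p <- numeric(0)
    }
    new("DecodingResult",
        foldAccuracies = cv$foldAccuracies, meanAccuracy = cv$meanAccuracy,
        nullAccuracies = nullAcc, pValue = p,
        weights = avg$weights, intercept = avg$intercept,
        labels = avg$labels)
  })
}

#' Group-level t-map of classifier weights
#'
#' Per-voxel one-sample t-test of the subjects' fold-averaged weights
#' against zero. Voxels with zero across-subject variance get an infinite
#' sentinel and are flagged.
#'
#' @param weights subject x voxel matrix of fold-averaged weights.
#' @param gridDim optional 3-D grid dimensions carried into the result for
#'   cluster thresholding.
#' @return a [GroupWeightStats-class] with `df = nSubjects - 1`.
#' @export
groupWeightTtest <- function(weights, gridDim = NULL) {
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n < 3L) stop("at least 3 subjects are required")
  mu <- colMeans(weights)
  s <- apply(weights, 2, sd)
  zeroVar <- s == 0
  t <- ifelse(zeroVar, sign(mu) * Inf, mu / (s / sqrt(n)))
  t[zeroVar & mu == 0] <- 0
  if (is.null(gridDim)) gridDim <- gridDims(ncol(weights))
  new("GroupWeightStats", tValues = as.numeric(t), df = n - 1L,
      zeroVariance = zeroVar, gridDim = as.integer(gridDim))
}
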