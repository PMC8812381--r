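# Shared fixtures, all generated in code.

# Small grid config for fast end-to-end runs.
tinyConfig <- function(...) {
  args <- list(...)
  defaults <- list(nVoxels = 125L, seed = 11L)
  do.call(generatorConfig, utils::modifyList(defaults, args))
}

# Two linearly separable Gaussian clouds (trial x voxel), labelled ATT/IMG.
separableData <- function(n = 40L, V = 20L, sep = 4, seed = 1) {
  set.seed(seed)
  half <- n %/% 2L
  mu <- rnorm(V)
  mu <- mu / sqrt(sum(mu^2))
  X <- rbind(
    matrix(rnorm(half * V), half, V) + matrix(sep * mu, half, V, byrow = TRUE),
    matrix(rnorm(half * V), half, V) - matrix(sep * mu, half, V, byrow = TRUE)
  )
  list(X = X, y = rep(c("ATT", "IMG"), each = half), direction = mu)
}

# Wrap a plain trial x voxel matrix as a TrialPatternDataset.
asPatternDataset <- function(X, labels, outcomes = NULL, runId = 1L) {
  n <- nrow(X)
  cd <- S4Vectors::DataFrame(
    label = labels,
    run_id = rep(runId, length.out = n),
    trial_id = seq_len(n),
    outcome = if (is.null(outcomes)) rep(NA_character_, n) else outcomes
  )
  rownames(cd) <- paste0("trial", seq_len(n))
  rd <- S4Vectors::DataFrame(row.names = paste0("v", seq_len(ncol(X))))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = t(unname(as.matrix(X)))),
    rowData = rd, colData = cd,
    metadata = list(gridDim = crossdecode:::gridDims(ncol(X)))
  )
  new("TrialPatternDataset", se)
}

# One high-SNR subject with first-level patterns, computed once per test
# run and reused across files. Smoothing is off here: the generator's
# prototypes are spatially white, so recovery is assessed against the
# unsmoothed estimates. The amplitude is chosen so condition-mean patterns
# clear the recovery bound with margin; shared run-level noise (drift and
# AR(1) components common to trials of a blocked run) keeps the correlation
# well below 1 even at high amplitude.
.sharedEnv <- new.env(parent = emptyenv())
sharedSubjectPatterns <- function() {
  if (is.null(.sharedEnv$pats)) {
    cfg <- tinyConfig(signalAmplitude = 12, seed = 42L)
    study <- simulateSubject(cfg)
    .sharedEnv$study <- study
    .sharedEnv$pats <- trialPatterns(study, fwhmMm = 0)
  }
  list(study = .sharedEnv$study, pats = .sharedEnv$pats)
}
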