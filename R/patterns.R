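#' Sample condition prototype patterns
#'
#' Draws two unit-norm, mean-zero voxel patterns (rows "ATT" and "IMG")
#' whose Pearson correlation equals `patternOverlap` exactly (up to floating
#' point): a random direction is drawn, a second is orthogonalised against
#' it, and the IMG prototype is the overlap-weighted combination.
#'
#' @param config a [GeneratorConfig-class].
#' @param seed optional integer for a local RNG stream.
#' @return 2 x nVoxels matrix with rownames `c("ATT", "IMG")`.
#' @export
sampleConditionPatterns <- function(config = generatorConfig(), seed = NULL) {
  validObject(config)
  rho <- config@patternOverlap
  V <- config@nVoxels
  withSeed(seed, {
    unitCentered <- function(z) {
      z <- z - mean(z)
      z / sqrt(sum(z^2))
    }
    u <- unitCentered(rnorm(V))
    w <- rnorm(V)
    w <- w - mean(w)
    w <- w - sum(w * u) * u
    w <- w / sqrt(sum(w^2))
    p <- rbind(ATT = u, IMG = rho * u + sqrt(1 - rho^2) * w)
    colnames(p) <- paste0("v", seq_len(V))
    p
  })
}

#' Assign latent ground truth to transfer trials
#'
#' Each penalty-reading trial gets a behavioural outcome
#' (`correct`/`incorrect`, Bernoulli with `pCorrect`) and a latent strategy
#' (`IMG`/`ATT`, Bernoulli with `pImgGivenCorrect` or `pImgGivenIncorrect`
#' conditional on the outcome). The strategy selects which condition
#' prototype drives the trial's BOLD pattern; the cross-classification
#' statistic estimates `pImgGivenCorrect`.
#'
#' @param config a [GeneratorConfig-class].
#' @param seed optional integer for a local RNG stream.
#' @return `data.frame` with columns `trial_id`, `outcome`, `strategy`.
#' @export
assignTransferTruth <- function(config = generatorConfig(), seed = NULL) {
  validObject(config)
  n <- config@nTransferTrials
  withSeed(seed, {
    correct <- rbinom(n, 1L, config@pCorrect) == 1L
    pImg <- ifelse(correct, config@pImgGivenCorrect, config@pImgGivenIncorrect)
    img <- rbinom(n, 1L, pImg) == 1L
    data.frame(
      trial_id = seq_len(n),
      outcome = ifelse(correct, "correct", "incorrect"),
      strategy = ifelse(img, "IMG", "ATT")
    )
  })
}

#' Simulate a uniform random responder on an n-alternative task
#'
#' Monte-Carlo check of the chance level of the 4-alternative penalty
#' direction judgement (left/right x high/low): both the true direction and
#' the response are drawn uniformly, so expected accuracy is
#' `1/nAlternatives` (25% for the 4-choice task).
#'
#' @param nTrials number of simulated trials.
#' @param nAlternatives number of response alternatives.
#' @param seed optional integer for a local RNG stream.
#' @return observed accuracy (fraction of matches).
#' @export
randomResponderAccuracy <- function(nTrials, nAlternatives = 4L, seed = NULL) {
  stopifnot(nTrials >= 1L, nAlternatives >= 2L)
  withSeed(seed, {
    truth <- sample.int(nAlternatives, nTrials, replace = TRUE)
    resp <- sample.int(nAlternatives, nTrials, replace = TRUE)
    mean(truth == resp)
  })
}
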