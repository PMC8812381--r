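#' Sample an event schedule
#'
#' Draws trial onsets and durations for either the two-condition training
#' task or the penalty-reading transfer task. Clip durations are uniform on
#' the configured interval; inter-trial intervals and mini-block breaks are
#' jittered uniformly on a 0.1-s grid within their configured bounds. Each
#' run opens with an instruction cue of `cueDurationS` followed by a
#' break-length jittered interval before the first clip.
#'
#' In the blocked design, every training run carries a single instruction,
#' with the first half of the runs under one instruction and the second half
#' under the other according to `instructionOrder` (`"AABB"`: ATT first).
#' In the interleaved design, a balanced random label sequence is drawn
#' within each run.
#'
#' @param task `"training"` or `"transfer"`.
#' @param config a [GeneratorConfig-class].
#' @param seed optional integer; when given the draw is made under a local
#'   RNG stream so the ambient RNG is untouched.
#' @return a `data.frame` with columns `onset`, `duration`, `trial_type`,
#'   `run_id`, `miniblock_id`, `trial_id` and `outcome` (NA for training;
#'   filled in later for transfer trials by [assignTransferTruth()]).
#' @examples
#' ev <- sampleEventSchedule("training", generatorConfig(seed = 1), seed = 1)
#' head(ev)
#' @export
sampleEventSchedule <- function(task = c("training", "transfer"),
                                config = generatorConfig(), seed = NULL) {
  task <- match.arg(task)
  validObject(config)
  withSeed(seed, {
    if (task == "training") .sampleTrainingSchedule(config)
    else .sampleTransferSchedule(config)
  })
}

.sampleRunOnsets <- function(nTrials, perBlock, config) {
  # cue at t = 0, first clip after a break-length jittered interval
  onset <- config@cueDurationS + sampleOnGrid(1, config@breakRangeS)
  durations <- stats::runif(nTrials, config@clipDurationRangeS[1],
                            config@clipDurationRangeS[2])
  onsets <- numeric(nTrials)
  for (i in seq_len(nTrials)) {
    onsets[i] <- onset
    gap <- if (i %% perBlock == 0L) sampleOnGrid(1, config@breakRangeS)
           else sampleOnGrid(1, config@itiRangeS)
    onset <- onset + durations[i] + gap
  }
  data.frame(onset = onsets, duration = durations,
             miniblock_id = (seq_len(nTrials) - 1L) %/% perBlock + 1L)
}

.sampleTrainingSchedule <- function(config) {
  nRuns <- config@nTrainingRuns
  perRun <- config@miniblocksPerRun * config@trialsPerMiniblock
  half <- nRuns %/% 2L
  first <- if (config@instructionOrder == "AABB") "ATT" else "IMG"
  second <- setdiff(c("ATT", "IMG"), first)
  out <- vector("list", nRuns)
  tid <- 0L
  for (r in seq_len(nRuns)) {
    sch <- .sampleRunOnsets(perRun, config@trialsPerMiniblock, config)
    if (config@design == "blocked") {
      sch$trial_type <- if (r <= half) first else second
    } else {
      # balanced random interleaving within run
      lab <- sample(rep(c("ATT", "IMG"), length.out = perRun))
      sch$trial_type <- lab
    }
    sch$run_id <- r
    sch$trial_id <- tid + seq_len(perRun)
    tid <- tid + perRun
    out[[r]] <- sch
  }
  ev <- do.call(rbind, out)
  ev$outcome <- NA_character_
  ev[, c("onset", "duration", "trial_type", "run_id", "miniblock_id",
         "trial_id", "outcome")]
}

.sampleTransferSchedule <- function(config) {
  sch <- .sampleRunOnsets(config@nTransferTrials, 3L, config)
  sch$trial_type <- "penalty"
  sch$run_id <- 1L
  sch$trial_id <- seq_len(config@nTransferTrials)
  sch$outcome <- NA_character_
  sch[, c("onset", "duration", "trial_type", "run_id", "miniblock_id",
          "trial_id", "outcome")]
}

# Structural validation shared by generator and readers.
validateEvents <- function(events, file = NULL) {
  where <- if (is.null(file)) "" else paste0(" in ", file)
  need <- c("onset", "duration", "trial_type", "run_id", "trial_id")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop(sprintf("missing event column(s)%s: %s", where,
                 paste(miss, collapse = ", ")))
  if (any(events$onset < 0))
    stop(sprintf("negative onset%s", where))
  if (any(events$duration <= 0))
    stop(sprintf("non-positive duration%s", where))
  for (r in unique(events$run_id)) {
    on <- events$onset[events$run_id == r]
    if (is.unsorted(on, strictly = TRUE))
      stop(sprintf("onsets not strictly increasing in run %s%s", r, where))
  }
  invisible(events)
}
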