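#' Write a pipeline configuration as YAML
#'
#' @param config a [PipelineConfig-class].
#' @param path output YAML path.
#' @return the path, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  validObject(config)
  hrf <- config@hrf
  lst <- list(
    generator = configAsList(config@generator),
    hrf = list(peakDelayS = hrf@peakDelayS,
               undershootDelayS = hrf@undershootDelayS,
               peakDispersionS = hrf@peakDispersionS,
               undershootDispersionS = hrf@undershootDispersionS,
               undershootRatio = hrf@undershootRatio,
               kernelLengthS = hrf@kernelLengthS,
               oversampling = hrf@oversampling),
    cutoffS = config@cutoffS, fwhmMm = config@fwhmMm,
    voxelSizeMm = config@voxelSizeMm, kFolds = config@kFolds,
    nPermDecoding = config@nPermDecoding,
    nPermTransfer = config@nPermTransfer, tThresh = config@tThresh,
    minClusterVoxels = config@minClusterVoxels,
    connectivity = config@connectivity, alpha = config@alpha,
    seed = config@seed
  )
  yaml::write_yaml(lst, path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML path written by [writePipelineConfig()].
#' @return a validated [PipelineConfig-class].
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(paste("no such config file:", path))
  lst <- yaml::read_yaml(path)
  pipelineConfig(
    generator = configFromList(lst$generator),
    hrf = do.call(hrfParams, lst$hrf),
    cutoffS = lst$cutoffS, fwhmMm = lst$fwhmMm,
    voxelSizeMm = lst$voxelSizeMm, kFolds = lst$kFolds,
    nPermDecoding = lst$nPermDecoding, nPermTransfer = lst$nPermTransfer,
    tThresh = lst$tThresh, minClusterVoxels = lst$minClusterVoxels,
    connectivity = lst$connectivity, alpha = lst$alpha, seed = lst$seed
  )
}

.stage <- function(stage, subject, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for subject %d: %s",
                 stage, subject, conditionMessage(e)), call. = FALSE))
}

#' Run the full study pipeline
#'
#' Simulate every subject, estimate single-trial patterns, decode the
#' training task (stratified k-fold cross-validation plus label-permutation
#' inference), cross-classify the penalty-reading task, and aggregate to the
#' group level (t-test of the IMG proportion against 0.5; group t-map of
#' fold-averaged classifier weights with cluster thresholding when at least
#' three subjects are available). All outputs are written under `outDir` and
#' listed in a manifest with MD5 hashes; identical configuration and seed
#' give byte-identical text outputs.
#'
#' @param config a [PipelineConfig-class].
#' @param outDir output directory (created if needed).
#' @param writeRaw also write the simulated BOLD datasets.
#' @return list with `summary` (per-subject data.frame), `group`
#'   (a [CrossClassResult-class]), `groupWeights`
#'   (a [GroupWeightStats-class] or NULL), `clusters` (list or NULL) and
#'   `manifest` (data.frame of files and MD5 hashes).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, writeRaw = FALSE) {
  validObject(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  gen <- config@generator
  nSub <- gen@nSubjects
  files <- character(0)

  rows <- vector("list", nSub)
  transferResults <- vector("list", nSub)
  weightMat <- matrix(NA_real_, nSub, gen@nVoxels)
  for (s in seq_len(nSub)) {
    study <- .stage("simulate", s, simulateSubject(gen, subject = s,
                                                   hrf = config@hrf))
    if (writeRaw) {
      mf <- .stage("write_raw", s, writeDataset(study, file.path(outDir, "raw")))
      files <- c(files, mf$file)
    }
    pats <- .stage("glm", s, trialPatterns(
      study, hrf = config@hrf, cutoffS = config@cutoffS,
      fwhmMm = config@fwhmMm, voxelSizeMm = config@voxelSizeMm))
    dec <- .stage("decode", s, decodeSubject(
      pats$training, k = config@kFolds, nPerm = config@nPermDecoding,
      seed = subjectSeed(config@seed, s)))
    tr <- .stage("crossclassify", s, crossClassifySubject(
      pats$training, pats$transfer, nPerm = config@nPermTransfer,
      seed = subjectSeed(config@seed, nSub + s)))
    weightMat[s, ] <- modelWeights(dec)
    transferResults[[s]] <- tr
    rows[[s]] <- data.frame(
      subject = s,
      cv_accuracy = meanAccuracy(dec),
      decoding_p = if (length(pValue(dec))) pValue(dec) else NA_real_,
      img_proportion = imgProportionOf(tr),
      transfer_p = if (length(pValue(tr))) pValue(tr) else NA_real_
    )
    resFile <- file.path(outDir, sprintf("sub-%02d_results.json", s))
    jsonlite::write_json(
      list(subject = s,
           fold_accuracies = foldAccuracies(dec),
           mean_accuracy = meanAccuracy(dec),
           decoding_p = pValue(dec),
           transfer_predictions = transferPredictions(tr),
           img_proportion = imgProportionOf(tr),
           transfer_p = pValue(tr)),
      resFile, auto_unbox = TRUE, digits = NA)
    files <- c(files, resFile)
  }
  summary <- do.call(rbind, rows)

  group <- groupCrossClass(transferResults, alpha = config@alpha)
  groupWeights <- NULL
  clusters <- NULL
  if (nSub >= 3L) {
    groupWeights <- groupWeightTtest(weightMat, gridDim = gridDims(gen@nVoxels))
    clusters <- list(
      positive = thresholdClusters(groupWeights, tThresh = config@tThresh,
                                   minSize = config@minClusterVoxels,
                                   sign = "positive",
                                   connectivity = config@connectivity),
      negative = thresholdClusters(groupWeights, tThresh = config@tThresh,
                                   minSize = config@minClusterVoxels,
                                   sign = "negative",
                                   connectivity = config@connectivity)
    )
  }

  sumFile <- file.path(outDir, "study_summary.tsv")
  fmt <- summary
  for (cn in setdiff(names(fmt), "subject"))
    fmt[[cn]] <- sprintf("%.10g", fmt[[cn]])
  utils::write.table(fmt, sumFile, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  files <- c(files, sumFile)

  grpFile <- file.path(outDir, "group_summary.json")
  gs <- groupStats(group)
  jsonlite::write_json(
    list(group = gs,
         cluster_sizes = if (!is.null(clusters))
           list(positive = clusters$positive$sizes,
                negative = clusters$negative$sizes)
         else NULL,
         n_subjects = nSub, seed = config@seed),
    grpFile, auto_unbox = TRUE, digits = NA)
  files <- c(files, grpFile)

  manifest <- data.frame(file = files, md5 = unname(tools::md5sum(files)),
                         row.names = NULL)
  manFile <- file.path(outDir, "manifest.tsv")
  utils::write.table(manifest, manFile, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  list(summary = summary, group = group, groupWeights = groupWeights,
       clusters = clusters, manifest = manifest)
}
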