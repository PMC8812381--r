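#' @name dataset-io
#' @title Readers and writers for the on-disk study layout
#' @description BIDS-style layout: one 4-D NIfTI (float32) per run, one
#'   `*_events.tsv` and one `*_confounds.tsv` per run, and one JSON sidecar
#'   per subject holding the generator configuration and the latent ground
#'   truth. All round-trips are lossless at stored precision.
NULL

# ---- events TSV ----

#' Write an event table as a BIDS-style TSV
#'
#' Columns: onset, duration, trial_type, run_id, miniblock_id, trial_id,
#' outcome; missing outcomes are written as `n/a`.
#'
#' @param events event table data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEventsTsv <- function(events, path) {
  validateEvents(events)
  out <- events
  out$outcome[is.na(out$outcome)] <- "n/a"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a BIDS-style events TSV
#'
#' @param path file path.
#' @return validated event table data.frame (`n/a` outcomes become NA).
#' @export
readEventsTsv <- function(path) {
  if (!file.exists(path)) stop(paste("no such events file:", path))
  ev <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(outcome = "character"))
  need <- c("onset", "duration", "trial_type", "run_id", "trial_id")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")))
  ev$outcome[ev$outcome == "n/a"] <- NA_character_
  validateEvents(ev, file = path)
}

# ---- confounds TSV ----

#' Write a confounds TSV (six motion columns plus global signal)
#'
#' @param confounds scan x 7 matrix or data.frame.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeConfoundsTsv <- function(confounds, path) {
  confounds <- as.data.frame(confounds)
  need <- c(paste0("motion_", 1:6), "global_signal")
  miss <- setdiff(need, names(confounds))
  if (length(miss))
    stop(paste("missing confound column(s):", paste(miss, collapse = ", ")))
  utils::write.table(format(confounds[, need], digits = 17, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a confounds TSV
#'
#' @param path file path.
#' @return scan x 7 numeric matrix.
#' @export
readConfoundsTsv <- function(path) {
  if (!file.exists(path)) stop(paste("no such confounds file:", path))
  cf <- utils::read.delim(path, sep = "\t")
  need <- c(paste0("motion_", 1:6), "global_signal")
  miss <- setdiff(need, names(cf))
  if (length(miss))
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")))
  as.matrix(cf[, need])
}

# ---- NIfTI ----

#' Write a BOLD run as a 4-D NIfTI volume
#'
#' Voxels are unfolded onto the run's rectangular grid in column-major
#' order; data are stored as float32 with isotropic `voxelSizeMm` spatial
#' pixdims and the TR as the fourth.
#'
#' @param run a [BoldRun-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSizeMm isotropic voxel size, millimetres.
#' @return the path, invisibly.
#' @export
writeBoldNifti <- function(run, path, voxelSizeMm = 3) {
  gd <- boldGridDim(run)
  sig <- assay(run, "bold") # voxel x scan
  arr <- array(sig, dim = c(gd, ncol(sig)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(rep(voxelSizeMm, 3), boldTr(run))
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a 4-D NIfTI volume into a scan x voxel matrix
#'
#' @param path file path.
#' @return list with `signal` (scan x voxel), `gridDim`, `trS`.
#' @export
readBoldNifti <- function(path) {
  if (!file.exists(path)) stop(paste("no such NIfTI file:", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4-D volume in %s, got dimensions [%s]",
                 path, paste(d, collapse = ", ")))
  pd <- RNifti::pixdim(img)
  list(signal = t(matrix(img, nrow = prod(d[1:3]), ncol = d[4])),
       gridDim = as.integer(d[1:3]),
       trS = if (length(pd) >= 4) pd[4] else NA_real_)
}

# Rebuild a BoldRun from its three on-disk pieces.
assembleBoldRun <- function(niftiPath, eventsPath, confoundsPath) {
  vol <- readBoldNifti(niftiPath)
  events <- readEventsTsv(eventsPath)
  conf <- readConfoundsTsv(confoundsPath)
  if (nrow(conf) != nrow(vol$signal))
    stop(sprintf("confounds in %s have %d rows but the volume has %d scans",
                 confoundsPath, nrow(conf), nrow(vol$signal)))
  nScans <- nrow(vol$signal)
  V <- ncol(vol$signal)
  coords <- arrayInd(seq_len(V), vol$gridDim)
  cd <- DataFrame(as.data.frame(conf))
  rownames(cd) <- paste0("scan", seq_len(nScans))
  rd <- DataFrame(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  rownames(rd) <- paste0("v", seq_len(V))
  se <- SummarizedExperiment(
    assays = list(bold = t(vol$signal)),
    rowData = rd, colData = cd,
    metadata = list(trS = vol$trS, gridDim = vol$gridDim, events = events)
  )
  new("BoldRun", se)
}

# ---- trial-pattern TSV ----

#' Write a trial-pattern dataset as TSV plus JSON sidecar
#'
#' The TSV holds one row per trial: `trial_id`, `label`, `run_id`,
#' `outcome`, then one column per voxel. The sidecar records the grid.
#'
#' @param data a [TrialPatternDataset-class].
#' @param path output TSV path; the sidecar replaces the extension by
#'   `.json`.
#' @return the path, invisibly.
#' @export
writePatternTsv <- function(data, path) {
  info <- trialInfo(data)
  Z <- zMatrix(data)
  out <- cbind(
    data.frame(trial_id = info$trial_id, label = info$label,
               run_id = info$run_id,
               outcome = ifelse(is.na(info$outcome), "n/a", info$outcome)),
    as.data.frame(format(Z, digits = 17, trim = TRUE))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  side <- sub("\\.tsv$", ".json", path)
  jsonlite::write_json(list(gridDim = metadata(data)$gridDim,
                            nTrials = ncol(data), nVoxels = nrow(data)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a trial-pattern TSV written by [writePatternTsv()]
#'
#' @param path TSV path (sidecar JSON expected alongside).
#' @return a [TrialPatternDataset-class].
#' @export
readPatternTsv <- function(path) {
  if (!file.exists(path)) stop(paste("no such pattern file:", path))
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = c(outcome = "character"))
  need <- c("trial_id", "label", "run_id", "outcome")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("missing column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")))
  side <- sub("\\.tsv$", ".json", path)
  gd <- if (file.exists(side))
    as.integer(jsonlite::read_json(side)$gridDim)
  else gridDims(ncol(tab) - 4L)
  Z <- as.matrix(tab[, setdiff(names(tab), need), drop = FALSE])
  cd <- DataFrame(label = tab$label, run_id = tab$run_id,
                  trial_id = tab$trial_id,
                  outcome = ifelse(tab$outcome == "n/a", NA_character_,
                                   tab$outcome))
  rownames(cd) <- paste0("trial", tab$trial_id)
  rd <- DataFrame(row.names = paste0("v", seq_len(ncol(Z))))
  se <- SummarizedExperiment(assays = list(z = t(unname(Z))),
                             rowData = rd, colData = cd,
                             metadata = list(gridDim = gd))
  new("TrialPatternDataset", se)
}

# ---- dataset writer / reader ----

.subjectPrefix <- function(subject) sprintf("sub-%02d", subject)

#' Write a simulated subject to disk
#'
#' Emits, per run, a 4-D NIfTI, an events TSV and a confounds TSV, plus one
#' JSON sidecar with the generator configuration and the latent ground
#' truth. Returns a manifest of every file written.
#'
#' @param study a [SubjectStudy-class].
#' @param dir output directory (created if needed).
#' @return data.frame manifest with columns `file` and `md5`.
#' @export
writeDataset <- function(study, dir) {
  stopifnot(is(study, "SubjectStudy"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop(paste("directory not writable:", dir))
  pre <- file.path(dir, .subjectPrefix(study@subject))
  files <- character(0)
  writeRun <- function(run, task, idx) {
    base <- sprintf("%s_task-%s_run-%02d", pre, task, idx)
    writeBoldNifti(run, paste0(base, "_bold.nii.gz"))
    writeEventsTsv(runEvents(run), paste0(base, "_events.tsv"))
    writeConfoundsTsv(as.data.frame(colData(run)), paste0(base, "_confounds.tsv"))
    paste0(base, c("_bold.nii.gz", "_events.tsv", "_confounds.tsv"))
  }
  for (i in seq_along(study@trainingRuns))
    files <- c(files, writeRun(study@trainingRuns[[i]], "training", i))
  files <- c(files, writeRun(study@transferRun, "transfer", 1L))

  sidecar <- paste0(pre, "_truth.json")
  jsonlite::write_json(
    list(config = configAsList(study@config),
         subject = study@subject,
         truth = study@truth,
         prototypes = list(ATT = unname(study@prototypes["ATT", ]),
                           IMG = unname(study@prototypes["IMG", ]))),
    sidecar, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  files <- c(files, sidecar)
  data.frame(file = files, md5 = unname(tools::md5sum(files)),
             row.names = NULL)
}

#' Read a subject dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @param subject subject index.
#' @return list with `trainingRuns` (list of [BoldRun-class]), `transferRun`,
#'   `truth`, `config` (as a list) and `prototypes`.
#' @export
readSubjectDataset <- function(dir, subject = 1L) {
  pre <- file.path(dir, .subjectPrefix(subject))
  trainNii <- sort(Sys.glob(paste0(pre, "_task-training_run-*_bold.nii.gz")))
  if (!length(trainNii))
    stop(paste("no training runs found for", .subjectPrefix(subject), "in", dir))
  readRun <- function(nii) {
    base <- sub("_bold\\.nii\\.gz$", "", nii)
    assembleBoldRun(nii, paste0(base, "_events.tsv"),
                    paste0(base, "_confounds.tsv"))
  }
  training <- lapply(trainNii, readRun)
  names(training) <- paste0("run", seq_along(training))
  transfer <- readRun(paste0(pre, "_task-transfer_run-01_bold.nii.gz"))
  side <- jsonlite::read_json(paste0(pre, "_truth.json"),
                              simplifyVector = TRUE)
  list(trainingRuns = training, transferRun = transfer,
       truth = side$truth, config = side$config,
       prototypes = side$prototypes)
}

# GeneratorConfig <-> plain list (for JSON/YAML serialisation)
configAsList <- function(config) {
  sl <- slotNames(class(config))
  out <- lapply(sl, function(s) slot(config, s))
  names(out) <- sl
  out
}

configFromList <- function(lst) {
  do.call(generatorConfig, lapply(lst, function(x)
    if (is.list(x)) unlist(x) else x))
}
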