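#' @include AllClasses.R AllGenerics.R
NULL

#' Default pipeline configuration
#'
#' Nested configuration for every stage with the study defaults: 1 s
#' sampling trimmed at 120 s, oracle detector (ground-truth replay; switch
#' to \code{"background"} for the median-background detector), 35\% crop
#' padding at 224x224 (the generous padding keeps a background margin around
#' the subject-centred crop, without which short-term motion is invisible
#' after cropping), GrayST enabled with stride 1, pixel-statistics embedding
#' (8x8 cross-channel-range grid + 16-bin per-channel histograms), naive
#' Bayes variance smoothing 1e-9, Top-20 selection, and 4 validation
#' subjects per leave-one-subject-out fold. Unknown keys are rejected.
#'
#' @param ... named overrides, either nested lists
#'   (\code{selection = list(n = 10)}) or dotted keys
#'   (\code{selection.n = 10}).
#' @return nested configuration list.
#' @examples
#' cfg <- runConfig(grayst = list(enabled = FALSE), selection.n = 10)
#' @export
runConfig <- function(...) {
  cfg <- list(
    sampling = list(intervalS = 1, maxDurationS = 120),
    detector = list(kind = "oracle", threshold = 25),
    crop = list(padFrac = 0.35, outSize = c(224L, 224L)),
    grayst = list(enabled = TRUE, stride = 1L),
    backend = list(kind = "pixel_stats", grid = 8L, histBins = 16L,
                   channelRange = TRUE, channelGrid = FALSE),
    head = list(varSmoothing = 1e-9),
    selection = list(n = 20L),
    evaluation = list(nVal = 4L, seed = 1L))
  mergeConfig(cfg, list(...))
}

mergeConfig <- function(cfg, over, prefix = character()) {
  for (nm in names(over)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    node <- over[[nm]]
    if (length(parts) == 2) {
      cfg <- mergeConfig(cfg, setNames(list(setNames(list(node), parts[2])),
                                       parts[1]), prefix)
      next
    }
    if (!nm %in% names(cfg))
      stop(sprintf("unknown config key '%s'",
                   paste(c(prefix, nm), collapse = ".")), call. = FALSE)
    if (is.list(cfg[[nm]]) && is.list(node))
      cfg[[nm]] <- mergeConfig(cfg[[nm]], node, c(prefix, nm))
    else cfg[[nm]] <- node
  }
  cfg
}

#' Read a YAML run configuration
#'
#' Values in the file override the \code{\link{runConfig}} defaults; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return nested configuration list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path))
    stop(sprintf("I/O error: config '%s' not found", path), call. = FALSE)
  mergeConfig(runConfig(), yaml::read_yaml(path))
}

makeBackend <- function(cfg) {
  switch(cfg$backend$kind,
    pixel_stats = pixelStatsBackend(grid = cfg$backend$grid,
                                    histBins = cfg$backend$histBins,
                                    channelRange = cfg$backend$channelRange,
                                    channelGrid = cfg$backend$channelGrid),
    stop(sprintf("capability error: embedder backend '%s' is not available",
                 cfg$backend$kind), call. = FALSE))
}

#' Preprocess and embed every video of a dataset
#'
#' Runs the frame pipeline once per video — sample at the configured
#' interval, detect and crop the subject, optionally GrayST-stack, embed —
#' and binds the per-frame embeddings of all videos into one
#' \code{SummarizedExperiment}. Embeddings depend only on pixels and config
#' (no trained state), so cross-validation computes them once and subsets by
#' subject per fold. Frames dropped by detection are counted in
#' \code{metadata(se)$dropped}.
#'
#' @param dataset a \linkS4class{SyntheticVideoSet} (or fixture read back
#'   with \code{\link{readFixture}}).
#' @param config list from \code{\link{runConfig}}.
#' @return a \code{SummarizedExperiment} of embeddings with per-frame column
#'   data.
#' @export
prepareEmbeddings <- function(dataset, config = runConfig()) {
  stopifnot(is(dataset, "SyntheticVideoSet"))
  backend <- makeBackend(config)
  oracle <- if (config$detector$kind == "oracle") oracleDetector(dataset)
  sets <- list(); droppedTotal <- 0L; sampledTotal <- 0L
  for (v in datasetVideos(dataset)) {
    fs <- sampleFrames(v, intervalS = config$sampling$intervalS,
                       maxDurationS = config$sampling$maxDurationS)
    sampledTotal <- sampledTotal + nFrames(fs)
    if (!nFrames(fs)) next
    detector <- switch(config$detector$kind,
      oracle = oracle,
      background = backgroundDetector(fs, threshold = config$detector$threshold),
      stop(sprintf("unknown detector kind '%s'", config$detector$kind),
           call. = FALSE))
    cr <- cropFrames(fs, detector, padFrac = config$crop$padFrac,
                     outSize = config$crop$outSize)
    droppedTotal <- droppedTotal + cr$dropped[["no_detection"]]
    out <- if (isTRUE(config$grayst$enabled))
      stackGrayST(cr$frames, stride = config$grayst$stride) else cr$frames
    if (nFrames(out)) sets[[length(sets) + 1L]] <- out
  }
  se <- embedFrames(bindFrameSets(sets), backend)
  S4Vectors::metadata(se)$dropped <- c(no_detection = droppedTotal)
  S4Vectors::metadata(se)$sampled <- sampledTotal
  se
}

#' Select the Top-N most confident frames per subject and class
#'
#' For each training subject and each class, the frames of that subject's
#' video carrying that class label are ranked by the model's confidence in
#' the video's (known) label — descending, ties broken by earlier timestamp
#' then lower videoId — and the first \code{min(N, available)} are kept.
#' Ranking by the known label (not the predicted class) is what builds a
#' labelled Top-N training set per class per subject. A subject missing a
#' class's video yields a warning and an empty cell.
#'
#' @param model a stage-1 \linkS4class{GnbModel}.
#' @param se embedding \code{SummarizedExperiment} of the training subjects.
#' @param n frames kept per subject-class cell (default 20).
#' @return a \linkS4class{TopFrameSet}.
#' @export
selectTopFrames <- function(model, se, n = 20L) {
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  probs <- gnbPredictProba(model, se)
  conf <- confidenceOf(probs, cd$label)
  d <- data.frame(subjectId = cd$subjectId, class = cd$label,
                  videoId = cd$videoId, sampleIndex = cd$sampleIndex,
                  timestampS = cd$timestampS, confidence = conf)
  cells <- split(d, list(d$subjectId, d$class), drop = TRUE)
  sel <- lapply(cells, function(cell) {
    o <- order(-cell$confidence, cell$timestampS, cell$videoId)
    cell[o[seq_len(min(n, nrow(cell)))], , drop = FALSE]
  })
  out <- do.call(rbind, sel)
  rownames(out) <- NULL
  missing <- outer(unique(d$subjectId), painClasses(), paste) |>
    setdiff(unique(paste(out$subjectId, out$class)))
  if (length(missing))
    warning("no frames for subject-class cell(s): ",
            paste(missing, collapse = ", "), call. = FALSE)
  new("TopFrameSet", selection = out, n = as.integer(n))
}

# subset an embedding SE to the frames referenced by a TopFrameSet
subsetByRefs <- function(se, refs) {
  cd <- SummarizedExperiment::colData(se)
  keep <- paste(cd$videoId, cd$sampleIndex) %in%
    paste(refs$videoId, refs$sampleIndex)
  se[, keep]
}

#' Train a Gaussian naive Bayes head on embedded frames
#'
#' Stage-1 training ("Model 1") fits on all training-subject frames; stage-2
#' training ("Model 2") fits on the Top-N selection only via
#' \code{\link{trainModel2}}. Both are plain \code{\link{gnbFit}} calls with
#' the class order fixed to (no_pain, pain).
#'
#' @param se embedding \code{SummarizedExperiment} with a \code{label}
#'   column.
#' @param varSmoothing variance smoothing passed to \code{\link{gnbFit}}.
#' @return a \linkS4class{GnbModel}.
#' @export
trainModel1 <- function(se, varSmoothing = 1e-9) {
  gnbFit(se, varSmoothing = varSmoothing, classes = painClasses())
}

#' @rdname trainModel1
#' @param top a \linkS4class{TopFrameSet} from \code{\link{selectTopFrames}}.
#' @export
trainModel2 <- function(top, se, varSmoothing = 1e-9) {
  stopifnot(is(top, "TopFrameSet"))
  sub <- subsetByRefs(se, selectionTable(top))
  gnbFit(sub, varSmoothing = varSmoothing, classes = painClasses())
}

#' Run the two-stage pipeline on one cross-validation fold
#'
#' Stage 1 fits on all frames of the fold's training subjects; the Top-N set
#' is selected from those same frames (validation subjects pass through and
#' the held-out subject never contributes); stage 2 refits on the selection;
#' both models then score every frame of the test subject's videos. Training
#' frame references and md5 digests of each model's serialized design matrix
#' are stored for the no-leakage audit.
#'
#' @param se embedding \code{SummarizedExperiment} for the whole dataset.
#' @param fold a \linkS4class{FoldSplit}.
#' @param config list from \code{\link{runConfig}}.
#' @return a \linkS4class{PipelineRun}.
#' @export
runTwoStage <- function(se, fold, config = runConfig()) {
  stopifnot(is(fold, "FoldSplit"))
  validObject(fold)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  if (anyDuplicated(c(fold@train, fold@val, fold@test)))
    stop("validation error: subject overlap between splits", call. = FALSE)
  trainSe <- se[, cd$subjectId %in% fold@train]
  testSe <- se[, cd$subjectId %in% fold@test]
  vs <- config$head$varSmoothing
  m1 <- trainModel1(trainSe, varSmoothing = vs)
  top <- selectTopFrames(m1, trainSe, n = config$selection$n)
  m2 <- trainModel2(top, trainSe, varSmoothing = vs)
  refCols <- c("subjectId", "videoId", "sampleIndex")
  refs1 <- as.data.frame(SummarizedExperiment::colData(trainSe))[, refCols]
  refs2 <- as.data.frame(SummarizedExperiment::colData(
    subsetByRefs(trainSe, selectionTable(top))))[, refCols]
  rownames(refs1) <- rownames(refs2) <- NULL
  p1 <- gnbPredictProba(m1, testSe)
  p2 <- gnbPredictProba(m2, testSe)
  testCd <- as.data.frame(SummarizedExperiment::colData(testSe))
  preds <- data.frame(testCd[, c(refCols, "label", "timestampS")],
                      m1_no_pain = p1[, "no_pain"], m1_pain = p1[, "pain"],
                      m2_no_pain = p2[, "no_pain"], m2_pain = p2[, "pain"])
  rownames(preds) <- NULL
  new("PipelineRun", model1 = m1, model2 = m2, topFrames = top, fold = fold,
      predictions = preds, trainRefs1 = refs1, trainRefs2 = refs2,
      trainHash1 = objectMd5(SummarizedExperiment::assay(trainSe)),
      trainHash2 = objectMd5(SummarizedExperiment::assay(
        subsetByRefs(trainSe, selectionTable(top)))),
      counts = c(total = ncol(se), train = ncol(trainSe),
                 selected = nrow(selectionTable(top)), test = ncol(testSe)))
}
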