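#' @import methods
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Configuration for the synthetic video generator
#'
#' Holds every knob of the seeded synthetic dataset: subject count, recording
#' parameters (fps, duration, frame size), class-conditional motion amplitudes
#' (pain subjects move less, encoding the behavioural premise that reduced
#' movement indicates pain), cage-bar occlusion geometry, per-frame noise
#' probabilities (motion blur, subject absent/off-camera) and an optional
#' class-conditional appearance shift that adds a purely static texture cue.
#'
#' @slot nSubjects integer, number of subjects (two videos each).
#' @slot fps numeric, native recording rate in frames per second.
#' @slot durationS numeric, video length in seconds.
#' @slot frameSize integer(2), frame height and width in pixels.
#' @slot motionAmplitudeNoPain numeric, random-walk step SD (px/frame) for
#'   no-pain videos.
#' @slot motionAmplitudePain numeric, step SD for pain videos; must be
#'   strictly smaller than the no-pain amplitude.
#' @slot occlusionBarCount integer, number of vertical cage bars.
#' @slot occlusionBarWidth integer, bar width in pixels.
#' @slot blurProb numeric in [0,1], per-frame probability of motion blur.
#' @slot absentFrameProb numeric in [0,1], per-frame probability that the
#'   subject is absent (background only).
#' @slot appearanceShift numeric in [0,1], class-conditional intensity offset
#'   added to the pain subject's texture (0 = motion is the only class signal).
#' @slot seed integer RNG seed.
#' @exportClass SyntheticConfig
setClass("SyntheticConfig", representation(
  nSubjects = "integer", fps = "numeric", durationS = "numeric",
  frameSize = "integer", motionAmplitudeNoPain = "numeric",
  motionAmplitudePain = "numeric", occlusionBarCount = "integer",
  occlusionBarWidth = "integer", blurProb = "numeric",
  absentFrameProb = "numeric", appearanceShift = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  chkProb <- function(x, nm) if (length(x) != 1 || is.na(x) || x < 0 || x > 1)
    sprintf("'%s' must be a single value in [0, 1]", nm) else NULL
  if (length(object@nSubjects) != 1 || is.na(object@nSubjects) || object@nSubjects < 2L)
    msg <- c(msg, "'nSubjects' must be an integer >= 2")
  if (length(object@fps) != 1 || is.na(object@fps) || object@fps <= 0)
    msg <- c(msg, "'fps' must be a positive number")
  if (length(object@durationS) != 1 || is.na(object@durationS) || object@durationS <= 0)
    msg <- c(msg, "'durationS' must be a positive number")
  if (length(object@frameSize) != 2 || any(is.na(object@frameSize)) || any(object@frameSize < 16L))
    msg <- c(msg, "'frameSize' must be two integers >= 16 (height, width)")
  if (!is.na(object@motionAmplitudePain) && !is.na(object@motionAmplitudeNoPain) &&
      object@motionAmplitudePain >= object@motionAmplitudeNoPain)
    msg <- c(msg, "'motionAmplitudePain' must be < 'motionAmplitudeNoPain'")
  if (any(c(object@motionAmplitudePain, object@motionAmplitudeNoPain) < 0))
    msg <- c(msg, "motion amplitudes must be >= 0")
  if (object@occlusionBarCount < 0L) msg <- c(msg, "'occlusionBarCount' must be >= 0")
  if (object@occlusionBarCount > 0L && object@occlusionBarWidth < 1L)
    msg <- c(msg, "'occlusionBarWidth' must be >= 1 when bars are drawn")
  for (nm in c("blurProb", "absentFrameProb", "appearanceShift")) {
    m <- chkProb(slot(object, nm), nm)
    if (!is.null(m)) msg <- c(msg, m)
  }
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' A generated synthetic video dataset
#'
#' Container for the generator output: one pair of videos per subject (one
#' pain, one no-pain), per-frame ground-truth bounding boxes or absent
#' markers, and a tabular manifest.
#'
#' @slot videos list; each element holds subjectId, videoId, label, fps, a
#'   list of HxWx3 integer frames, and a per-frame box table
#'   (frameIndex, xMin, yMin, xMax, yMax in 0-based half-open pixel
#'   coordinates, absent flag, continuous centroid cx, cy).
#' @slot manifest data.frame indexing all videos
#'   (subjectId, videoId, label, fps, nFrames).
#' @slot config the \linkS4class{SyntheticConfig} used.
#' @exportClass SyntheticVideoSet
setClass("SyntheticVideoSet", representation(
  videos = "list", manifest = "data.frame", config = "SyntheticConfig"))

setValidity("SyntheticVideoSet", function(object) {
  msg <- character()
  if (length(object@videos) != nrow(object@manifest))
    msg <- c(msg, "manifest rows must match the number of videos")
  labs <- split(object@manifest$label, object@manifest$subjectId)
  if (!all(vapply(labs, function(x) identical(sort(x), c("no_pain", "pain")), logical(1))))
    msg <- c(msg, "every subject needs exactly one 'pain' and one 'no_pain' video")
  if (length(msg)) msg else TRUE
})

#' Handle to a single on-disk video
#'
#' Lazy reference to a frame-directory video: frames are only read when
#' sampled. Produced by \code{\link{loadManifest}}.
#'
#' @slot source character path to the per-video frame directory.
#' @slot nativeFps numeric recording rate (frames/second).
#' @slot frameCount integer number of stored frames.
#' @slot subjectId,videoId character identifiers.
#' @slot label character, one of \code{"pain"}, \code{"no_pain"},
#'   \code{"unlabeled"}.
#' @exportClass VideoHandle
setClass("VideoHandle", representation(
  source = "character", nativeFps = "numeric", frameCount = "integer",
  subjectId = "character", videoId = "character", label = "character"))

setValidity("VideoHandle", function(object) {
  msg <- character()
  if (object@nativeFps <= 0) msg <- c(msg, "'nativeFps' must be > 0")
  if (object@frameCount < 0L) msg <- c(msg, "'frameCount' must be >= 0")
  if (!object@label %in% c("pain", "no_pain", "unlabeled"))
    msg <- c(msg, "label must be 'pain', 'no_pain' or 'unlabeled'")
  if (length(msg)) msg else TRUE
})

#' An ordered collection of frames with per-frame metadata
#'
#' The workhorse container flowing through the pipeline. Each element of
#' \code{frames} is an HxWx3 integer array of 8-bit intensities; \code{meta}
#' carries one row per frame (subjectId, videoId, label, timestampS,
#' sampleIndex, frameIndex, and after stacking t0/t1/t2). Frames may differ
#' in size before cropping; they share a size afterwards.
#'
#' @slot frames list of HxWx3 integer arrays, values in 0..255.
#' @slot meta data.frame with one row per frame.
#' @exportClass FrameSet
setClass("FrameSet", representation(frames = "list", meta = "data.frame"))

setValidity("FrameSet", function(object) {
  msg <- character()
  if (length(object@frames) != nrow(object@meta))
    msg <- c(msg, "one meta row per frame required")
  need <- c("subjectId", "videoId", "label", "timestampS", "sampleIndex")
  miss <- setdiff(need, names(object@meta))
  if (length(miss))
    msg <- c(msg, paste0("meta lacks column(s): ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Virtual parent for subject detectors
#'
#' A detector backend turns frames into at most one bounding box per frame.
#' Implementations: \linkS4class{OracleDetector} (replays synthetic
#' ground-truth boxes) and \linkS4class{BackgroundDetector}
#' (median-background subtraction).
#'
#' @exportClass DetectorBackend
setClass("DetectorBackend", representation("VIRTUAL"))

#' Ground-truth replay detector
#'
#' Replays the synthetic generator's per-frame boxes, keyed by
#' (videoId, frameIndex). Decouples pipeline tests from detector quality.
#'
#' @slot boxes data.frame with videoId, frameIndex, xMin, yMin, xMax, yMax,
#'   absent.
#' @exportClass OracleDetector
setClass("OracleDetector", contains = "DetectorBackend",
         representation(boxes = "data.frame"))

#' Median-background subtraction detector
#'
#' Background model is the per-pixel median of one video's sampled grayscale
#' frames; a frame's detection is the bounding box of the largest 8-connected
#' component of |frame - background| > threshold, scored by its area fraction.
#' By construction it cannot detect a subject that never moves (the subject
#' is then part of the background); such frames yield no detection.
#'
#' @slot background numeric HxW matrix (grayscale median background).
#' @slot threshold numeric absolute intensity difference in 0..255.
#' @exportClass BackgroundDetector
setClass("BackgroundDetector", contains = "DetectorBackend",
         representation(background = "matrix", threshold = "numeric"))

#' Gaussian naive Bayes model
#'
#' Class priors plus per-class, per-feature Gaussian parameters with additive
#' variance smoothing. Fit with \code{\link{gnbFit}}; posterior class
#' probabilities with \code{\link{gnbPredictProba}}.
#'
#' @slot classes character vector of class names, in fixed prediction order.
#' @slot logPriors numeric per-class log prior probabilities.
#' @slot means numeric classes x features matrix of per-class feature means.
#' @slot variances numeric classes x features matrix of smoothed per-class
#'   population variances.
#' @slot eps numeric, the additive variance-smoothing floor actually used.
#' @exportClass GnbModel
setClass("GnbModel", representation(
  classes = "character", logPriors = "numeric", means = "matrix",
  variances = "matrix", eps = "numeric"))

setValidity("GnbModel", function(object) {
  msg <- character()
  k <- length(object@classes)
  if (k < 2) msg <- c(msg, "at least two classes required")
  if (length(object@logPriors) != k) msg <- c(msg, "one log prior per class required")
  if (abs(sum(exp(object@logPriors)) - 1) > 1e-8)
    msg <- c(msg, "priors must sum to 1")
  if (nrow(object@means) != k || !identical(dim(object@means), dim(object@variances)))
    msg <- c(msg, "means/variances must be classes x features matrices")
  if (object@eps <= 0) msg <- c(msg, "'eps' must be > 0")
  if (any(object@variances < object@eps))
    msg <- c(msg, "all variances must be >= eps")
  if (length(msg)) msg else TRUE
})

#' Confidence-ranked Top-N frame selection
#'
#' For each (subject, class) cell: the frames of that subject's video of that
#' class, ranked by the first-stage model's confidence in the video's label
#' (ties broken by earlier timestamp, then lower videoId), truncated to N.
#'
#' @slot selection data.frame with subjectId, class, videoId, sampleIndex,
#'   timestampS, confidence; confidences are non-increasing within each
#'   (subjectId, class) cell.
#' @slot n integer, the requested selection size per cell.
#' @exportClass TopFrameSet
setClass("TopFrameSet", representation(selection = "data.frame", n = "integer"))

setValidity("TopFrameSet", function(object) {
  msg <- character()
  need <- c("subjectId", "class", "videoId", "sampleIndex", "timestampS", "confidence")
  if (!all(need %in% names(object@selection)))
    msg <- c(msg, paste0("selection needs columns: ", paste(need, collapse = ", ")))
  else {
    byCell <- split(object@selection, paste(object@selection$subjectId, object@selection$class))
    if (!all(vapply(byCell, function(d) nrow(d) <= object@n &&
                      !is.unsorted(-d$confidence), logical(1))))
      msg <- c(msg, "each cell must hold <= n frames with non-increasing confidence")
  }
  if (length(msg)) msg else TRUE
})

#' One leave-one-subject-out fold
#'
#' Pairwise-disjoint train/validation/test subject sets with exactly one test
#' subject; the union covers all subjects.
#'
#' @slot train,val,test character vectors of subject ids.
#' @exportClass FoldSplit
setClass("FoldSplit", representation(
  train = "character", val = "character", test = "character"))

setValidity("FoldSplit", function(object) {
  msg <- character()
  all3 <- c(object@train, object@val, object@test)
  if (anyDuplicated(all3)) msg <- c(msg, "train/val/test subjects must be disjoint")
  if (length(object@test) != 1) msg <- c(msg, "exactly one test subject required")
  if (length(object@train) < 1) msg <- c(msg, "at least one training subject required")
  if (length(msg)) msg else TRUE
})

#' Artifacts of one two-stage pipeline run on one fold
#'
#' @slot model1,model2 fitted \linkS4class{GnbModel}s (stage 1: all training
#'   frames; stage 2: Top-N frames only).
#' @slot topFrames the \linkS4class{TopFrameSet} used for stage 2.
#' @slot fold the \linkS4class{FoldSplit}.
#' @slot predictions data.frame of held-out test-frame class probabilities
#'   for both models.
#' @slot trainRefs1,trainRefs2 data.frames of the frame references
#'   (subjectId, videoId, sampleIndex) each model was trained on.
#' @slot trainHash1,trainHash2 character md5 digests of each model's
#'   serialized training design matrix (leakage audit).
#' @slot counts named integer vector of per-stage frame counts.
#' @exportClass PipelineRun
setClass("PipelineRun", representation(
  model1 = "GnbModel", model2 = "GnbModel", topFrames = "TopFrameSet",
  fold = "FoldSplit", predictions = "data.frame",
  trainRefs1 = "data.frame", trainRefs2 = "data.frame",
  trainHash1 = "character", trainHash2 = "character", counts = "integer"))

#' Cross-validated evaluation report
#'
#' Pooled over leave-one-subject-out folds: per-frame and per-video held-out
#' predictions for both pipeline stages, plus classification metrics at both
#' levels recomputable from the stored confusion counts.
#'
#' @slot metrics data.frame with model, level, accuracy, recall, precision,
#'   f1 and TP/FP/FN/TN confusion counts (positive class: pain).
#' @slot videoPredictions data.frame of per-video averaged scores and labels.
#' @slot framePredictions data.frame of per-frame probabilities.
#' @slot folds list of \linkS4class{FoldSplit}.
#' @slot runs list of \linkS4class{PipelineRun}, one per fold.
#' @slot config list, the configuration snapshot used.
#' @exportClass EvalReport
setClass("EvalReport", representation(
  metrics = "data.frame", videoPredictions = "data.frame",
  framePredictions = "data.frame", folds = "list", runs = "list",
  config = "list"))
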