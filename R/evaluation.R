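#' @include AllClasses.R AllGenerics.R
NULL

#' Build leave-one-subject-out folds
#'
#' One fold per subject as test; \code{nVal} validation subjects are drawn
#' without replacement from the remainder using the seed; all other subjects
#' train. With 24 subjects and the default \code{nVal = 4} every fold is a
#' 19/4/1 split.
#'
#' @param subjects character vector of subject ids.
#' @param nVal validation subjects per fold (default 4).
#' @param seed RNG seed for the validation draws.
#' @return list of \linkS4class{FoldSplit}, one per subject.
#' @export
makeLosoFolds <- function(subjects, nVal = 4L, seed = 1L) {
  subjects <- unique(as.character(subjects))
  if (length(subjects) <= nVal + 1L)
    stop(sprintf(
      "configuration error: need more than nVal + 1 = %d subjects, got %d",
      nVal + 1L, length(subjects)), call. = FALSE)
  withSeed(seed, lapply(subjects, function(s) {
    rest <- setdiff(subjects, s)
    val <- if (nVal > 0) sample(rest, nVal) else character()
    new("FoldSplit", train = setdiff(rest, val), val = val, test = s)
  }))
}

#' Aggregate frame probabilities to a video prediction
#'
#' Average pooling: the per-class arithmetic mean of the frame probabilities,
#' predicting the class with the highest average. An exact tie resolves to
#' \code{no_pain} (do not flag pain without an evidence margin).
#'
#' @param probs n x classes matrix of frame probabilities for one video
#'   (columns named by class, \code{no_pain} first).
#' @param videoId id used in error messages.
#' @return list with \code{scores} (named class means) and \code{label}.
#' @examples
#' aggregateVideo(rbind(c(0.6, 0.4), c(0.2, 0.8), c(0.9, 0.1)))
#' @export
aggregateVideo <- function(probs, videoId = "<video>") {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, names(probs)))
  if (nrow(probs) == 0)
    stop(sprintf("aggregation error: no scored frames for video '%s'",
                 videoId), call. = FALSE)
  if (is.null(colnames(probs))) colnames(probs) <- painClasses()
  scores <- colMeans(probs)
  list(scores = scores, label = names(scores)[which.max(scores)])
}

#' Classification metrics from label vectors
#'
#' Accuracy, precision, recall and F1 with \code{pain} as the positive class
#' (configurable). Empty denominators yield 0 with a warning. Metrics are
#' returned alongside their confusion counts so they can be recomputed.
#'
#' @param truth,predicted equal-length label vectors.
#' @param positiveClass the positive class (default \code{"pain"}).
#' @return named list: accuracy, recall, precision, f1, TP, FP, FN, TN.
#' @examples
#' computeMetrics(rep(c("pain", "no_pain"), c(4, 4)),
#'                rep(c("pain", "no_pain", "pain", "no_pain"), c(3, 1, 1, 3)))
#' @export
computeMetrics <- function(truth, predicted, positiveClass = "pain") {
  if (length(truth) != length(predicted))
    stop("shape error: label vectors differ in length", call. = FALSE)
  pos <- truth == positiveClass
  ppos <- predicted == positiveClass
  TP <- sum(pos & ppos); FP <- sum(!pos & ppos)
  FN <- sum(pos & !ppos); TN <- sum(!pos & !ppos)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("empty denominator for %s; reporting 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  precision <- safe(TP, TP + FP, "precision")
  recall <- safe(TP, TP + FN, "recall")
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = safe(TP + TN, length(truth), "accuracy"),
       recall = recall, precision = precision, f1 = f1,
       TP = TP, FP = FP, FN = FN, TN = TN)
}

poolMetrics <- function(truth, predicted, model, level) {
  m <- computeMetrics(truth, predicted)
  data.frame(model = model, level = level, as.data.frame(m))
}

#' Leave-one-subject-out cross-validation of the two-stage pipeline
#'
#' Embeds every video once, then runs \code{\link{runTwoStage}} per fold and
#' pools the held-out predictions across folds: frame-level metrics over all
#' test frames, video-level metrics over the average-pooled per-video
#' predictions, for both Model 1 (all frames) and Model 2 (Top-N frames).
#'
#' @param dataset a \linkS4class{SyntheticVideoSet}, or a precomputed
#'   embedding \code{SummarizedExperiment} from
#'   \code{\link{prepareEmbeddings}}.
#' @param config list from \code{\link{runConfig}}.
#' @return an \linkS4class{EvalReport}.
#' @export
crossValidate <- function(dataset, config = runConfig()) {
  se <- if (is(dataset, "SyntheticVideoSet"))
    prepareEmbeddings(dataset, config) else dataset
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  subjects <- sort(unique(cd$subjectId))
  folds <- makeLosoFolds(subjects, nVal = config$evaluation$nVal,
                         seed = config$evaluation$seed)
  runs <- lapply(folds, function(f) runTwoStage(se, f, config))
  frames <- do.call(rbind, lapply(runs, function(r) r@predictions))
  vids <- split(frames, frames$videoId)
  vrows <- lapply(vids, function(v) {
    p1 <- as.matrix(v[, c("m1_no_pain", "m1_pain")])
    p2 <- as.matrix(v[, c("m2_no_pain", "m2_pain")])
    colnames(p1) <- colnames(p2) <- painClasses()
    a1 <- aggregateVideo(p1, v$videoId[1])
    a2 <- aggregateVideo(p2, v$videoId[1])
    data.frame(subjectId = v$subjectId[1], videoId = v$videoId[1],
               label = v$label[1], nFrames = nrow(v),
               m1_no_pain = a1$scores[[1]], m1_pain = a1$scores[[2]],
               m1_label = a1$label,
               m2_no_pain = a2$scores[[1]], m2_pain = a2$scores[[2]],
               m2_label = a2$label)
  })
  video <- do.call(rbind, vrows)
  rownames(video) <- NULL
  frameLab1 <- ifelse(frames$m1_pain > frames$m1_no_pain, "pain", "no_pain")
  frameLab2 <- ifelse(frames$m2_pain > frames$m2_no_pain, "pain", "no_pain")
  metrics <- rbind(
    poolMetrics(frames$label, frameLab1, "model1", "frame"),
    poolMetrics(frames$label, frameLab2, "model2", "frame"),
    poolMetrics(video$label, video$m1_label, "model1", "video"),
    poolMetrics(video$label, video$m2_label, "model2", "video"))
  rownames(metrics) <- NULL
  new("EvalReport", metrics = metrics, videoPredictions = video,
      framePredictions = frames, folds = folds, runs = runs, config = config)
}

#' Randomly permute video labels (null calibration)
#'
#' Shuffles the class labels across videos (frames keep their video's new
#' label). Destroys the class signal while preserving all image statistics,
#' so a sound pipeline scores at chance on the permuted data.
#'
#' @param se embedding \code{SummarizedExperiment}.
#' @param seed RNG seed for the shuffle.
#' @return the \code{SummarizedExperiment} with permuted labels.
#' @export
permuteVideoLabels <- function(se, seed = 1L) {
  cd <- SummarizedExperiment::colData(se)
  vids <- unique(cd$videoId)
  labs <- cd$label[match(vids, cd$videoId)]
  newLabs <- withSeed(seed, sample(labs))
  cd$label <- newLabs[match(cd$videoId, vids)]
  SummarizedExperiment::colData(se) <- cd
  se
}

#' Video-level accuracy of an evaluation report
#'
#' Convenience reader for the pooled video-level accuracy of one model.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param model \code{"model1"} or \code{"model2"}.
#' @param level \code{"video"} (default) or \code{"frame"}.
#' @return numeric accuracy in [0, 1].
#' @export
reportAccuracy <- function(report, model = "model2", level = "video") {
  m <- report@metrics
  m$accuracy[m$model == model & m$level == level]
}
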