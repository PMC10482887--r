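#' @include AllClasses.R
NULL

#' Accessors for pipeline containers
#'
#' Small accessor family: \code{frameImages} and \code{frameMeta} return a
#' \linkS4class{FrameSet}'s pixel arrays and per-frame metadata table;
#' \code{nFrames} its length; \code{videoManifest} and \code{datasetVideos}
#' expose a \linkS4class{SyntheticVideoSet}'s index table and raw videos;
#' \code{modelClasses}, \code{classPriors}, \code{classMeans} and
#' \code{classVariances} read a \linkS4class{GnbModel}'s parameters;
#' \code{selectionTable} returns a \linkS4class{TopFrameSet}'s ranked table.
#'
#' @param x the object.
#' @return the slot contents described above.
#' @name accessors
#' @aliases frameImages frameMeta nFrames videoManifest datasetVideos
#'   modelClasses classPriors classMeans classVariances selectionTable
NULL

#' @rdname accessors
#' @export
setGeneric("frameImages", function(x) standardGeneric("frameImages"))
#' @rdname accessors
#' @export
setGeneric("frameMeta", function(x) standardGeneric("frameMeta"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("videoManifest", function(x) standardGeneric("videoManifest"))
#' @rdname accessors
#' @export
setGeneric("datasetVideos", function(x) standardGeneric("datasetVideos"))
#' @rdname accessors
#' @export
setGeneric("modelClasses", function(x) standardGeneric("modelClasses"))
#' @rdname accessors
#' @export
setGeneric("classPriors", function(x) standardGeneric("classPriors"))
#' @rdname accessors
#' @export
setGeneric("classMeans", function(x) standardGeneric("classMeans"))
#' @rdname accessors
#' @export
setGeneric("classVariances", function(x) standardGeneric("classVariances"))
#' @rdname accessors
#' @export
setGeneric("selectionTable", function(x) standardGeneric("selectionTable"))

#' @rdname accessors
setMethod("frameImages", "FrameSet", function(x) x@frames)
#' @rdname accessors
setMethod("frameMeta", "FrameSet", function(x) x@meta)
#' @rdname accessors
setMethod("nFrames", "FrameSet", function(x) length(x@frames))
#' @rdname accessors
setMethod("videoManifest", "SyntheticVideoSet", function(x) x@manifest)
#' @rdname accessors
setMethod("datasetVideos", "SyntheticVideoSet", function(x) x@videos)
#' @rdname accessors
setMethod("modelClasses", "GnbModel", function(x) x@classes)
#' @rdname accessors
setMethod("classPriors", "GnbModel", function(x) setNames(exp(x@logPriors), x@classes))
#' @rdname accessors
setMethod("classMeans", "GnbModel", function(x) x@means)
#' @rdname accessors
setMethod("classVariances", "GnbModel", function(x) x@variances)
#' @rdname accessors
setMethod("selectionTable", "TopFrameSet", function(x) x@selection)

#' Sample frames at a fixed interval
#'
#' @param video a \linkS4class{VideoHandle} or an in-memory video (a list with
#'   elements \code{frames}, \code{fps}, \code{subjectId}, \code{videoId},
#'   \code{label}).
#' @param intervalS sampling interval in seconds (default 1).
#' @param maxDurationS trim point in seconds (default 120); shorter videos are
#'   used in full.
#' @return a \linkS4class{FrameSet}, one frame per interval.
#' @export
setGeneric("sampleFrames", function(video, intervalS = 1, maxDurationS = 120)
  standardGeneric("sampleFrames"))

#' Detect the subject in every frame of a FrameSet
#'
#' @param detector a \linkS4class{DetectorBackend}.
#' @param frameSet a \linkS4class{FrameSet}.
#' @return data.frame with one row per frame: xMin, yMin, xMax, yMax (0-based,
#'   half-open), score in [0,1], detected flag.
#' @export
setGeneric("detectFrames", function(detector, frameSet)
  standardGeneric("detectFrames"))

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d subjects, %g fps x %g s, %dx%d px\n",
              object@nSubjects, object@fps, object@durationS,
              object@frameSize[1], object@frameSize[2]))
  cat(sprintf("  motion (px/step): no_pain %g, pain %g; bars %d x %d px\n",
              object@motionAmplitudeNoPain, object@motionAmplitudePain,
              object@occlusionBarCount, object@occlusionBarWidth))
  cat(sprintf("  blurProb %g, absentFrameProb %g, appearanceShift %g, seed %d\n",
              object@blurProb, object@absentFrameProb, object@appearanceShift,
              object@seed))
})

setMethod("show", "SyntheticVideoSet", function(object) {
  cat(sprintf("SyntheticVideoSet: %d videos (%d subjects x 2 classes)\n",
              nrow(object@manifest), object@config@nSubjects))
})

setMethod("show", "FrameSet", function(object) {
  n <- length(object@frames)
  cat(sprintf("FrameSet: %d frames from %d video(s)\n",
              n, length(unique(object@meta$videoId))))
  if (n) {
    d <- dim(object@frames[[1]])
    cat(sprintf("  first frame %dx%dx%d; t = %g..%g s\n", d[1], d[2], d[3],
                min(object@meta$timestampS), max(object@meta$timestampS)))
  }
})

setMethod("show", "GnbModel", function(object) {
  cat(sprintf("GnbModel: %d classes x %d features; priors: %s; eps %.3g\n",
              length(object@classes), ncol(object@means),
              paste(sprintf("%s=%.3f", object@classes, exp(object@logPriors)),
                    collapse = ", "), object@eps))
})

setMethod("show", "TopFrameSet", function(object) {
  cells <- unique(object@selection[, c("subjectId", "class")])
  cat(sprintf("TopFrameSet: N=%d, %d frames in %d subject-class cells\n",
              object@n, nrow(object@selection), nrow(cells)))
})

setMethod("show", "FoldSplit", function(object) {
  cat(sprintf("FoldSplit: test=%s | %d train, %d val\n",
              object@test, length(object@train), length(object@val)))
})

setMethod("show", "PipelineRun", function(object) {
  cat(sprintf("PipelineRun: test=%s | frames total %d, train %d, top %d, test %d\n",
              object@fold@test, object@counts[["total"]],
              object@counts[["train"]], object@counts[["selected"]],
              object@counts[["test"]]))
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (pooled over", length(object@folds), "LOSO folds)\n")
  m <- object@metrics
  print(m[, c("model", "level", "accuracy", "recall", "precision", "f1")],
        row.names = FALSE, digits = 3)
})
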