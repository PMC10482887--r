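#' @include AllClasses.R AllGenerics.R
NULL

noDetection <- function() data.frame(xMin = NA_real_, yMin = NA_real_,
                                     xMax = NA_real_, yMax = NA_real_,
                                     score = NA_real_, detected = FALSE)

#' Ground-truth replay detector
#'
#' Builds a \linkS4class{OracleDetector} from a synthetic dataset's per-frame
#' ground-truth boxes. Useful to decouple pipeline behaviour from detector
#' quality: each sampled frame is looked up by (videoId, frameIndex) and its
#' stored box (or absent marker) is returned with score 1.
#'
#' @param dataset a \linkS4class{SyntheticVideoSet}, or a data.frame with
#'   columns videoId, frameIndex, xMin, yMin, xMax, yMax, absent.
#' @return an \linkS4class{OracleDetector}.
#' @export
oracleDetector <- function(dataset) {
  boxes <- if (is(dataset, "SyntheticVideoSet")) {
    do.call(rbind, lapply(dataset@videos, function(v)
      cbind(videoId = v$videoId,
            v$boxes[, c("frameIndex", "xMin", "yMin", "xMax", "yMax", "absent")])))
  } else as.data.frame(dataset)
  new("OracleDetector", boxes = boxes)
}

#' @describeIn detectFrames replay the stored ground-truth boxes.
#' @export
setMethod("detectFrames", signature("OracleDetector", "FrameSet"),
  function(detector, frameSet) {
    meta <- frameMeta(frameSet)
    key <- paste(detector@boxes$videoId, detector@boxes$frameIndex)
    hit <- match(paste(meta$videoId, meta$frameIndex), key)
    if (anyNA(hit))
      stop(sprintf("detector error: no ground-truth box for frame(s) %s",
                   paste(utils::head(meta$videoId[is.na(hit)]), collapse = ",")),
           call. = FALSE)
    b <- detector@boxes[hit, , drop = FALSE]
    out <- data.frame(xMin = b$xMin, yMin = b$yMin, xMax = b$xMax,
                      yMax = b$yMax, score = ifelse(b$absent, NA_real_, 1),
                      detected = !b$absent)
    rownames(out) <- NULL
    out
  })

#' Fit a median-background detector to one video's frames
#'
#' The background model is the per-pixel median of the video's sampled
#' grayscale frames. Detection thresholds the absolute grayscale difference
#' against the background and returns the bounding box of the largest
#' 8-connected foreground component, scored by its area fraction of the
#' frame. A subject that never moves is absorbed into the background and is
#' undetectable by construction.
#'
#' @param frameSet a \linkS4class{FrameSet} of one video (>= 1 frame).
#' @param threshold absolute intensity difference in 0..255 (default 25).
#' @return a \linkS4class{BackgroundDetector}.
#' @export
backgroundDetector <- function(frameSet, threshold = 25) {
  stopifnot(is(frameSet, "FrameSet"))
  if (nFrames(frameSet) < 1) stop("at least one frame required", call. = FALSE)
  grays <- lapply(frameImages(frameSet), rgbToGray)
  stack <- array(unlist(grays), c(dim(grays[[1]]), length(grays)))
  bg <- apply(stack, c(1, 2), stats::median)
  new("BackgroundDetector", background = bg, threshold = threshold)
}

# merge 4-connected labels across diagonal adjacencies -> 8-connectivity
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask + 0)
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i] <<- parent[parent[i]]; i }
  unionPairs <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    m <- unique(cbind(a[keep], b[keep]))
    if (length(m)) for (r in seq_len(nrow(m))) {
      ra <- findRoot(m[r, 1]); rb <- findRoot(m[r, 2])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  h <- nrow(lab); w <- ncol(lab)
  unionPairs(lab[-h, -w], lab[-1, -1])   # down-right diagonal
  unionPairs(lab[-h, -1], lab[-1, -w])   # down-left diagonal
  roots <- vapply(seq_len(n), findRoot, integer(1))
  out <- lab
  out[lab > 0] <- roots[lab[lab > 0]]
  out
}

#' @describeIn detectFrames threshold each frame against the median
#'   background and box the largest 8-connected changed component.
#' @export
setMethod("detectFrames", signature("BackgroundDetector", "FrameSet"),
  function(detector, frameSet) {
    out <- lapply(frameImages(frameSet), function(img) {
      g <- rgbToGray(img)
      if (!identical(dim(g), dim(detector@background)))
        stop("detector error: frame size differs from background model",
             call. = FALSE)
      mask <- abs(g - detector@background) > detector@threshold
      if (!any(mask)) return(noDetection())
      # close 1-2 px gaps (thin cage bars slice the silhouette apart)
      mask <- EBImage::closing(mask + 0, EBImage::makeBrush(3, "box")) > 0
      lab <- label8(mask)
      areas <- tabulate(lab[lab > 0])
      best <- which.max(areas)
      idx <- which(lab == best, arr.ind = TRUE)
      data.frame(xMin = min(idx[, 2]) - 1, yMin = min(idx[, 1]) - 1,
                 xMax = max(idx[, 2]), yMax = max(idx[, 1]),
                 score = areas[best] / length(g), detected = TRUE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })

#' Detect the subject in a single frame
#'
#' Convenience wrapper around \code{\link{detectFrames}} for one frame of a
#' \linkS4class{FrameSet}: at most one detection (the largest changed
#' component, or the stored ground-truth box), none when no subject is
#' found.
#'
#' @param detector a \linkS4class{DetectorBackend}.
#' @param frameSet a \linkS4class{FrameSet}.
#' @param i frame index within the set (default 1).
#' @return one-row data.frame: xMin, yMin, xMax, yMax, score, detected.
#' @export
detectSubject <- function(detector, frameSet, i = 1L) {
  if (i < 1L || i > nFrames(frameSet))
    stop(sprintf("detector error: no frame %d in set of %d", i,
                 nFrames(frameSet)), call. = FALSE)
  detectFrames(detector, subsetFrameSet(frameSet, i))
}

#' Crop a frame to a (padded) box and resize
#'
#' The box is expanded by \code{padFrac} of its width/height per side,
#' clipped to the frame, cropped and bilinearly resized to \code{outSize}.
#' Never reads pixels outside the source frame.
#'
#' @param image HxWx3 integer array.
#' @param box numeric (xMin, yMin, xMax, yMax), 0-based half-open pixel
#'   coordinates.
#' @param padFrac padding fraction per side (default 0.05).
#' @param outSize integer(2) output (height, width); \code{NULL} keeps the
#'   cropped size.
#' @return HxWx3 integer array of size \code{outSize}.
#' @export
cropAndResize <- function(image, box, padFrac = 0.05, outSize = c(224, 224)) {
  assertFrameArray(image)
  box <- as.numeric(box)
  if (length(box) != 4 || anyNA(box) || box[1] >= box[3] || box[2] >= box[4])
    stop("crop error: invalid box", call. = FALSE)
  h <- dim(image)[1]; w <- dim(image)[2]
  padX <- padFrac * (box[3] - box[1]); padY <- padFrac * (box[4] - box[2])
  x0 <- max(0, floor(box[1] - padX)); x1 <- min(w, ceiling(box[3] + padX))
  y0 <- max(0, floor(box[2] - padY)); y1 <- min(h, ceiling(box[4] + padY))
  if (x1 - x0 < 1 || y1 - y0 < 1)
    stop("crop error: box degenerate after clipping to frame", call. = FALSE)
  crop <- image[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  if (is.null(outSize) || identical(as.integer(outSize), dim(crop)[1:2]))
    return(array(as.integer(crop), dim(crop)))
  res <- EBImage::resize(crop / 255, w = outSize[1], h = outSize[2],
                         filter = "bilinear")
  array(as.integer(clip255(roundHalfUp(res * 255))),
        c(as.integer(outSize), 3L))
}

#' Detect, crop and resize all frames of a FrameSet
#'
#' Runs the detector over the frames, drops frames with no detection
#' (recording why), and crops/resizes the rest so downstream stages see a
#' uniform image size. Labels, ids and timestamps are preserved.
#'
#' @param frameSet a \linkS4class{FrameSet}.
#' @param detector a \linkS4class{DetectorBackend}.
#' @param padFrac padding fraction per side (default 0.05).
#' @param outSize integer(2) output (height, width), default 224x224.
#' @return list with \code{frames} (the cropped \linkS4class{FrameSet}),
#'   \code{detections} (full detection table) and \code{dropped} (named
#'   integer vector of drop reasons).
#' @export
cropFrames <- function(frameSet, detector, padFrac = 0.05,
                       outSize = c(224, 224)) {
  det <- detectFrames(detector, frameSet)
  keep <- which(det$detected)
  cropped <- lapply(keep, function(i)
    cropAndResize(frameImages(frameSet)[[i]],
                  unlist(det[i, c("xMin", "yMin", "xMax", "yMax")]),
                  padFrac = padFrac, outSize = outSize))
  meta <- frameMeta(frameSet)[keep, , drop = FALSE]
  rownames(meta) <- NULL
  list(frames = new("FrameSet", frames = cropped, meta = meta),
       detections = det,
       dropped = c(no_detection = sum(!det$detected)))
}
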