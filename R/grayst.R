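#' @include AllClasses.R AllGenerics.R
NULL

#' Convert an RGB image to 8-bit grayscale
#'
#' ITU-R BT.601 luma: \eqn{Y = 0.299R + 0.587G + 0.114B}, rounded half-up
#' and clipped to 0..255. Grayscale-content images (equal channels) pass
#' through unchanged.
#'
#' @param image HxWx3 array of 8-bit intensities.
#' @return HxW integer matrix.
#' @examples
#' rgbToGray(array(c(255, 0, 0), c(1, 1, 3)))  # 76
#' @export
rgbToGray <- function(image) {
  assertFrameArray(image)
  y <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  matrix(as.integer(clip255(roundHalfUp(y))), dim(image)[1], dim(image)[2])
}

#' Grayscale Short-Term Stacking
#'
#' Replaces the three colour channels with grayscale frames from three
#' consecutive sampled time steps: channel 1 holds second \eqn{t}, channel 2
#' second \eqn{t+1}, channel 3 second \eqn{t+2} (chronological order). A 2-D
#' classifier downstream thus sees short-term motion as apparent colour,
#' while a subject static over three seconds renders as a pure gray image
#' (all channels equal). Windows slide over each video's sampled sequence
#' with the given stride; windows that would span a dropped frame (a gap in
#' \code{sampleIndex}) are skipped. The stacked image inherits the middle
#' frame's timestamp and sample index as its representative time.
#'
#' @param frameSet a \linkS4class{FrameSet}; frames of each video must share
#'   one size (i.e. be cropped/resized already).
#' @param stride window advance in sampled steps; 1 = overlapping windows
#'   (default), 3 = disjoint triplets.
#' @return a \linkS4class{FrameSet} of stacked images whose meta gains
#'   t0/t1/t2 source timestamps. For a gap-free video of N frames the output
#'   has \code{floor((N - 3) / stride) + 1} images (0 if N < 3).
#' @export
stackGrayST <- function(frameSet, stride = 1L) {
  stopifnot(is(frameSet, "FrameSet"), stride >= 1)
  stride <- as.integer(stride)
  meta <- frameMeta(frameSet)
  outF <- list(); outM <- list()
  for (vid in unique(meta$videoId)) {
    sel <- which(meta$videoId == vid)
    sel <- sel[order(meta$sampleIndex[sel])]
    n <- length(sel)
    if (n < 3) next
    dims <- lapply(frameImages(frameSet)[sel], dim)
    if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
      stop(sprintf("shape error: mixed frame sizes in video '%s'", vid),
           call. = FALSE)
    idx <- meta$sampleIndex[sel]
    for (s in seq(1L, n - 2L, by = stride)) {
      if (idx[s + 1L] != idx[s] + 1L || idx[s + 2L] != idx[s] + 2L) next
      tri <- sel[s:(s + 2L)]
      chans <- lapply(frameImages(frameSet)[tri], rgbToGray)
      img <- array(as.integer(c(chans[[1]], chans[[2]], chans[[3]])),
                   c(dim(chans[[1]]), 3L))
      m <- meta[tri[2L], , drop = FALSE]
      m$t0 <- meta$timestampS[tri[1L]]
      m$t1 <- meta$timestampS[tri[2L]]
      m$t2 <- meta$timestampS[tri[3L]]
      outF[[length(outF) + 1L]] <- img
      outM[[length(outM) + 1L]] <- m
    }
  }
  meta2 <- if (length(outM)) do.call(rbind, outM) else
    cbind(sampleMeta(character(), character(), character(), numeric(),
                     integer()),
          data.frame(t0 = numeric(), t1 = numeric(), t2 = numeric()))
  rownames(meta2) <- NULL
  new("FrameSet", frames = outF, meta = meta2)
}
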