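#' @include AllClasses.R AllGenerics.R
NULL

#' Load a fixture manifest into video handles
#'
#' Reads a \code{manifest.json} (as written by \code{\link{writeFixture}})
#' and returns one lazy \linkS4class{VideoHandle} per entry. Labels are
#' case-folded (spaces/hyphens become underscores) and validated against
#' \{pain, no_pain\}; \code{"unlabeled"} is passed through for inference-only
#' inputs.
#'
#' @param path the manifest file or the fixture directory containing it.
#' @return list of \linkS4class{VideoHandle}.
#' @examples
#' \dontrun{handles <- loadManifest("fixture_dir")}
#' @export
loadManifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  if (!file.exists(path))
    stop(sprintf("I/O error: manifest '%s' not found", path), call. = FALSE)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  vm <- man$videos
  if (is.null(vm) || !nrow(vm)) return(list())
  base <- dirname(path)
  lapply(seq_len(nrow(vm)), function(k) {
    lab <- normalizeLabel(vm$label[k])
    if (!lab %in% c("pain", "no_pain", "unlabeled"))
      stop(sprintf("format error in manifest entry '%s': unknown label '%s'",
                   vm$video_id[k], vm$label[k]), call. = FALSE)
    new("VideoHandle", source = file.path(base, vm$path[k]),
        nativeFps = as.numeric(vm$fps[k]),
        frameCount = as.integer(vm$n_frames[k]),
        subjectId = as.character(vm$subject_id[k]),
        videoId = as.character(vm$video_id[k]), label = lab)
  })
}

#' Read specific frames of an on-disk video
#'
#' @param handle a \linkS4class{VideoHandle}.
#' @param indices 1-based frame indices (default: all frames).
#' @return list of HxWx3 integer arrays.
#' @export
readVideoFrames <- function(handle, indices = seq_len(handle@frameCount)) {
  stopifnot(is(handle, "VideoHandle"))
  files <- file.path(handle@source, sprintf("frame_%05d.png", indices))
  missing <- !file.exists(files)
  if (any(missing))
    stop(sprintf("I/O error: cannot decode frame(s) %s of video '%s'",
                 paste(indices[missing], collapse = ","), handle@videoId),
         call. = FALSE)
  lapply(files, function(f) {
    a <- png::readPNG(f)
    if (length(dim(a)) == 2) a <- array(rep(a, 3L), c(dim(a), 3L))
    array(as.integer(roundHalfUp(a[, , 1:3, drop = FALSE] * 255)),
          dim = c(dim(a)[1:2], 3L))
  })
}

# shared sampling arithmetic: which native frame index represents second t?
# Convention: the first frame of each second, index floor(t * fps) + 1.
sampledIndices <- function(frameCount, fps, intervalS, maxDurationS) {
  if (intervalS <= 0) stop("'intervalS' must be > 0", call. = FALSE)
  if (frameCount <= 0) return(list(t = numeric(), idx = integer()))
  # whole seconds available, truncated at the trim point
  tEnd <- min(floor(frameCount / fps + 1e-9), maxDurationS)
  n <- max(0L, as.integer(ceiling(tEnd / intervalS - 1e-12)))
  t <- seq(0, by = intervalS, length.out = n)
  t <- t[t < tEnd - 1e-12]
  idx <- floor(t * fps + 1e-9) + 1L
  keep <- idx <= frameCount
  list(t = t[keep], idx = as.integer(idx[keep]))
}

sampleMeta <- function(subjectId, videoId, label, t, idx) {
  n <- length(t)
  data.frame(subjectId = rep(as.character(subjectId), length.out = n),
             videoId = rep(as.character(videoId), length.out = n),
             label = rep(as.character(label), length.out = n),
             timestampS = t, sampleIndex = seq_len(n) - 1L,
             frameIndex = idx, stringsAsFactors = FALSE)
}

#' @describeIn sampleFrames lazily reads only the sampled frames from disk.
#' @export
setMethod("sampleFrames", "VideoHandle",
  function(video, intervalS = 1, maxDurationS = 120) {
    s <- sampledIndices(video@frameCount, video@nativeFps, intervalS,
                        maxDurationS)
    frames <- if (length(s$idx)) readVideoFrames(video, s$idx) else list()
    new("FrameSet", frames = frames,
        meta = sampleMeta(video@subjectId, video@videoId, video@label,
                          s$t, s$idx))
  })

#' @describeIn sampleFrames samples an in-memory video, e.g. one element of
#'   \code{datasetVideos(x)}.
#' @export
setMethod("sampleFrames", "list",
  function(video, intervalS = 1, maxDurationS = 120) {
    need <- c("frames", "fps", "subjectId", "videoId", "label")
    miss <- setdiff(need, names(video))
    if (length(miss))
      stop("in-memory video lacks element(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    s <- sampledIndices(length(video$frames), video$fps, intervalS,
                        maxDurationS)
    new("FrameSet", frames = video$frames[s$idx],
        meta = sampleMeta(video$subjectId, video$videoId, video$label,
                          s$t, s$idx))
  })

# concatenate FrameSets (same meta columns)
bindFrameSets <- function(sets) {
  sets <- Filter(function(s) nFrames(s) > 0, sets)
  if (!length(sets))
    return(new("FrameSet", frames = list(),
               meta = sampleMeta(character(), character(), character(),
                                 numeric(), integer())))
  new("FrameSet", frames = do.call(c, lapply(sets, frameImages)),
      meta = do.call(rbind, lapply(sets, frameMeta)))
}

# subset a FrameSet by row indices, keeping frames and meta aligned
subsetFrameSet <- function(fs, i) {
  m <- fs@meta[i, , drop = FALSE]
  rownames(m) <- NULL
  new("FrameSet", frames = fs@frames[i], meta = m)
}
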