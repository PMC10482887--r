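#' @include AllClasses.R AllGenerics.R
NULL

#' Build a synthetic-video generator configuration
#'
#' Defaults mirror the emulated study design: 24 subjects, each recorded at
#' 60 fps for 120 s, once before surgery (no pain) and once after (pain).
#' The class signal is behavioural: the pain subject's random-walk step is
#' smaller (reduced movement). Noise sources emulate in-the-wild footage:
#' fixed vertical cage bars occluding the subject, per-frame motion blur, and
#' frames with the subject absent/off-camera. \code{appearanceShift} adds an
#' optional static intensity offset to the pain subject so appearance-only
#' class signals can be constructed (motion amplitudes equal); with
#' \code{appearanceShift = 0} motion is the only class signal.
#'
#' @param nSubjects number of subjects (>= 2); two videos each.
#' @param fps native frame rate, frames/second.
#' @param durationS video duration, seconds.
#' @param frameSize integer(2) frame height and width, pixels.
#' @param motionAmplitudeNoPain random-walk step SD, px/frame, no-pain video.
#' @param motionAmplitudePain step SD, px/frame, pain video; must be strictly
#'   smaller than the no-pain amplitude.
#' @param occlusionBarCount number of vertical cage bars.
#' @param occlusionBarWidth bar width, pixels.
#' @param blurProb per-frame probability of directional motion blur.
#' @param absentFrameProb per-frame probability the subject is absent.
#' @param appearanceShift class-conditional texture intensity offset in [0,1].
#' @param seed integer RNG seed; same config + seed gives byte-identical data.
#' @return a validated \linkS4class{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nSubjects = 2, fps = 4, durationS = 8,
#'                        frameSize = c(48, 64), seed = 1)
#' @export
syntheticConfig <- function(nSubjects = 24, fps = 60, durationS = 120,
                            frameSize = c(96, 128),
                            motionAmplitudeNoPain = 1.5,
                            motionAmplitudePain = 0.15,
                            occlusionBarCount = 16, occlusionBarWidth = 1,
                            blurProb = 0.1, absentFrameProb = 0.1,
                            appearanceShift = 0, seed = 1) {
  bad <- function(field, why) stop(sprintf("invalid '%s': %s", field, why),
                                   call. = FALSE)
  asInt <- function(x, field) {
    if (!is.numeric(x) || anyNA(x)) bad(field, "must be numeric and non-missing")
    as.integer(round(x))
  }
  cfg <- try(new("SyntheticConfig",
      nSubjects = asInt(nSubjects, "nSubjects"), fps = as.numeric(fps),
      durationS = as.numeric(durationS), frameSize = asInt(frameSize, "frameSize"),
      motionAmplitudeNoPain = as.numeric(motionAmplitudeNoPain),
      motionAmplitudePain = as.numeric(motionAmplitudePain),
      occlusionBarCount = asInt(occlusionBarCount, "occlusionBarCount"),
      occlusionBarWidth = asInt(occlusionBarWidth, "occlusionBarWidth"),
      blurProb = as.numeric(blurProb), absentFrameProb = as.numeric(absentFrameProb),
      appearanceShift = as.numeric(appearanceShift), seed = asInt(seed, "seed")),
    silent = TRUE)
  if (inherits(cfg, "try-error"))
    stop("configuration error: ", attr(cfg, "condition")$message, call. = FALSE)
  cfg
}

# smooth a uniform-noise matrix with `passes` rounds of a (2r+1)-point box
# blur along both axes (edge-clamped); controls texture correlation length
smoothNoise <- function(h, w, r = 2, passes = 2) {
  m <- matrix(stats::runif(h * w), h, w)
  for (p in seq_len(passes)) {
    m <- shiftSumRows(m, r) / (2 * r + 1)
    m <- t(shiftSumRows(t(m), r) / (2 * r + 1))
  }
  m
}

# sum of row-shifted copies m[i-r..i+r, ] with edge clamping
shiftSumRows <- function(m, r) {
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (s in -r:r) {
    idx <- pmin(pmax(seq_len(n) + s, 1L), n)
    out <- out + m[idx, , drop = FALSE]
  }
  out
}

# 1-D box blur of length 2r+1 along rows (axis=1) or columns (axis=2)
boxBlur1D <- function(m, r, axis) {
  if (axis == 1L) shiftSumRows(m, r) / (2 * r + 1)
  else t(shiftSumRows(t(m), r) / (2 * r + 1))
}

# Render one grayscale scene (returned as an HxW matrix of 0..255 integers)
# and its ground-truth box. Bars are composited last so they occlude; every
# frame gets multiplicative illumination flicker and additive sensor noise,
# so no pixel statistic is ever exactly constant across frames (as on a real
# camera).
renderScene <- function(bg, tex, cx, cy, rx, ry, absent, blurFlag, dx, dy,
                        barCols, X, Y) {
  img <- bg
  box <- c(NA_real_, NA_real_, NA_real_, NA_real_)
  if (!absent) {
    mask <- ((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1
    idx <- which(mask)
    if (length(idx)) {
      tr <- pmin(pmax(Y[idx] - round(cy) + ry + 1L, 1L), nrow(tex))
      tc <- pmin(pmax(X[idx] - round(cx) + rx + 1L, 1L), ncol(tex))
      img[idx] <- tex[cbind(tr, tc)]
      box <- c(min(X[idx]) - 1, min(Y[idx]) - 1, max(X[idx]), max(Y[idx]))
    } else absent <- TRUE
  }
  if (blurFlag)
    img <- boxBlur1D(img, 2L, if (abs(dx) >= abs(dy)) 2L else 1L)
  if (length(barCols)) img[, barCols] <- 120
  img <- img * stats::rnorm(1, 1, 0.05) +
    matrix(stats::rnorm(length(img), 0, 2), nrow(img))
  list(img = clip255(roundHalfUp(img)), box = box, absent = absent)
}

#' Generate a seeded synthetic video dataset
#'
#' Produces two videos per subject (one per class) in which a textured
#' elliptical subject performs a seeded random walk over a static textured
#' background, behind fixed cage bars, with per-frame motion blur and
#' absent-subject frames. The pain video of every subject uses the smaller
#' motion amplitude, so for ordered amplitudes the pain video's mean
#' inter-frame centroid displacement is strictly below the no-pain video's.
#' Every frame carries either a ground-truth bounding box (0-based, half-open
#' pixel coordinates) or an explicit absent marker.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return a \linkS4class{SyntheticVideoSet}.
#' @examples
#' ds <- generateDataset(syntheticConfig(nSubjects = 2, fps = 2, durationS = 4,
#'                                       frameSize = c(48, 64), seed = 7))
#' videoManifest(ds)
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  h <- config@frameSize[1]; w <- config@frameSize[2]
  nFramesVid <- as.integer(round(config@fps * config@durationS))
  X <- matrix(rep(seq_len(w), each = h), h, w)
  Y <- matrix(rep(seq_len(h), times = w), h, w)
  period <- if (config@occlusionBarCount > 0L)
    max(config@occlusionBarWidth + 1L, w %/% config@occlusionBarCount) else 0L
  barCols <- if (period > 0L)
    which(((seq_len(w) - 1L) %% period) < config@occlusionBarWidth) else integer()

  withSeed(config@seed, {
    videos <- vector("list", 2L * config@nSubjects)
    rows <- vector("list", 2L * config@nSubjects)
    # one cage/camera and one species appearance for the whole dataset:
    # the low-contrast background is shared, subjects share a base texture
    # with small individual jitter, so individual identity is a weak cue and
    # leave-one-subject-out generalization is meaningful
    bg <- 100 + 15 * smoothNoise(h, w, r = 2, passes = 2)
    rx0 <- max(3L, as.integer(round(0.12 * w)))
    ry0 <- max(3L, as.integer(round(0.14 * h)))
    texShared <- 140 + 120 * smoothNoise(2L * ry0 + 8L, 2L * rx0 + 8L,
                                         r = 1, passes = 1)
    k <- 0L
    for (i in seq_len(config@nSubjects)) {
      subjectId <- sprintf("s%02d", i)
      rx <- max(3L, as.integer(round(rx0 * stats::runif(1, 0.9, 1.1))))
      ry <- max(3L, as.integer(round(ry0 * stats::runif(1, 0.9, 1.1))))
      texBase <- texShared[seq_len(2L * ry + 1L), seq_len(2L * rx + 1L)] +
        12 * (smoothNoise(2L * ry + 1L, 2L * rx + 1L, r = 1, passes = 1) - 0.5)
      start <- c(stats::runif(1, rx + 1, w - rx), stats::runif(1, ry + 1, h - ry))
      for (label in c("no_pain", "pain")) {
        amp <- if (label == "pain") config@motionAmplitudePain else
          config@motionAmplitudeNoPain
        tex <- texBase + if (label == "pain") 60 * config@appearanceShift else 0
        # centroid random walk, clipped to keep the subject inside the frame
        steps <- matrix(stats::rnorm(2L * nFramesVid, 0, max(amp, 0)),
                        nFramesVid, 2)
        cx <- numeric(nFramesVid); cy <- numeric(nFramesVid)
        px <- start[1]; py <- start[2]
        for (t in seq_len(nFramesVid)) {
          px <- min(max(px + steps[t, 1], rx + 1), w - rx)
          py <- min(max(py + steps[t, 2], ry + 1), h - ry)
          cx[t] <- px; cy[t] <- py
        }
        absent <- stats::runif(nFramesVid) < config@absentFrameProb
        blurred <- stats::runif(nFramesVid) < config@blurProb
        frames <- vector("list", nFramesVid)
        boxes <- data.frame(frameIndex = seq_len(nFramesVid),
                            xMin = NA_real_, yMin = NA_real_,
                            xMax = NA_real_, yMax = NA_real_,
                            absent = absent, cx = cx, cy = cy)
        for (t in seq_len(nFramesVid)) {
          dx <- if (t > 1) cx[t] - cx[t - 1] else 1
          dy <- if (t > 1) cy[t] - cy[t - 1] else 0
          sc <- renderScene(bg, tex, cx[t], cy[t], rx, ry, absent[t],
                            blurred[t], dx, dy, barCols, X, Y)
          g <- sc$img
          frames[[t]] <- array(as.integer(g), c(h, w, 3L))
          boxes[t, c("xMin", "yMin", "xMax", "yMax")] <- sc$box
          boxes$absent[t] <- sc$absent
        }
        k <- k + 1L
        videoId <- sprintf("%s_%s", subjectId, label)
        videos[[k]] <- list(subjectId = subjectId, videoId = videoId,
                            label = label, fps = config@fps,
                            frames = frames, boxes = boxes)
        rows[[k]] <- data.frame(subjectId = subjectId, videoId = videoId,
                                label = label, fps = config@fps,
                                nFrames = nFramesVid)
      }
    }
    new("SyntheticVideoSet", videos = videos,
        manifest = do.call(rbind, rows), config = config)
  })
}

#' Mean inter-frame centroid displacement per video
#'
#' Ground-truth movement summary from the generator's continuous centroid
#' track (the walk continues through absent frames). For ordered motion
#' amplitudes, each subject's pain video displaces strictly less than its
#' no-pain video.
#'
#' @param dataset a \linkS4class{SyntheticVideoSet}.
#' @return data.frame with subjectId, videoId, label, meanDisplacement (px).
#' @export
centroidDisplacement <- function(dataset) {
  stopifnot(is(dataset, "SyntheticVideoSet"))
  rows <- lapply(dataset@videos, function(v) {
    d <- sqrt(diff(v$boxes$cx)^2 + diff(v$boxes$cy)^2)
    data.frame(subjectId = v$subjectId, videoId = v$videoId, label = v$label,
               meanDisplacement = if (length(d)) mean(d) else 0)
  })
  do.call(rbind, rows)
}

#' Write a dataset to a frame-directory fixture
#'
#' Lays out one subdirectory per video holding zero-padded numbered PNG
#' frames plus a \code{boxes.json} ground-truth file (0-based half-open
#' coordinates, explicit absent markers), and a top-level
#' \code{manifest.json} indexing all videos. Pixels round-trip losslessly
#' through \code{\link{readFixture}} and \code{\link{loadManifest}}.
#'
#' @param dataset a \linkS4class{SyntheticVideoSet}.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
writeFixture <- function(dataset, dir) {
  stopifnot(is(dataset, "SyntheticVideoSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir) || file.access(dir, 2L) != 0L)
    stop(sprintf("I/O error: cannot write to '%s'", dir), call. = FALSE)
  entries <- vector("list", length(dataset@videos))
  for (k in seq_along(dataset@videos)) {
    v <- dataset@videos[[k]]
    vdir <- file.path(dir, v$videoId)
    dir.create(vdir, showWarnings = FALSE)
    for (t in seq_along(v$frames))
      png::writePNG(v$frames[[t]] / 255,
                    file.path(vdir, sprintf("frame_%05d.png", t)))
    jsonlite::write_json(v$boxes, file.path(vdir, "boxes.json"),
                         digits = NA, na = "null")
    entries[[k]] <- list(subject_id = v$subjectId, video_id = v$videoId,
                         label = v$label, fps = v$fps,
                         n_frames = length(v$frames), path = v$videoId)
  }
  cfg <- dataset@config
  manifest <- list(
    videos = entries,
    config = lapply(setNames(slotNames(cfg), slotNames(cfg)),
                    function(s) slot(cfg, s)))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a frame-directory fixture back into memory
#'
#' Inverse of \code{\link{writeFixture}}: reconstructs the
#' \linkS4class{SyntheticVideoSet} (frames, ground-truth boxes, config) from
#' a fixture directory.
#'
#' @param dir fixture directory containing \code{manifest.json}.
#' @return a \linkS4class{SyntheticVideoSet}.
#' @export
readFixture <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    stop(sprintf("I/O error: no manifest at '%s'", path), call. = FALSE)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfgl <- man$config
  config <- syntheticConfig(
    nSubjects = cfgl$nSubjects, fps = cfgl$fps, durationS = cfgl$durationS,
    frameSize = cfgl$frameSize,
    motionAmplitudeNoPain = cfgl$motionAmplitudeNoPain,
    motionAmplitudePain = cfgl$motionAmplitudePain,
    occlusionBarCount = cfgl$occlusionBarCount,
    occlusionBarWidth = cfgl$occlusionBarWidth, blurProb = cfgl$blurProb,
    absentFrameProb = cfgl$absentFrameProb,
    appearanceShift = cfgl$appearanceShift, seed = cfgl$seed)
  vm <- man$videos
  videos <- vector("list", nrow(vm))
  rows <- vector("list", nrow(vm))
  for (k in seq_len(nrow(vm))) {
    vdir <- file.path(dir, vm$path[k])
    files <- sort(list.files(vdir, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    frames <- lapply(files, function(f) {
      a <- png::readPNG(f)
      if (length(dim(a)) == 2) a <- array(rep(a, 3L), c(dim(a), 3L))
      array(as.integer(roundHalfUp(a[, , 1:3] * 255)), dim = c(dim(a)[1:2], 3L))
    })
    boxes <- jsonlite::read_json(file.path(vdir, "boxes.json"),
                                 simplifyVector = TRUE)
    videos[[k]] <- list(subjectId = vm$subject_id[k], videoId = vm$video_id[k],
                        label = vm$label[k], fps = vm$fps[k],
                        frames = frames, boxes = as.data.frame(boxes))
    rows[[k]] <- data.frame(subjectId = vm$subject_id[k],
                            videoId = vm$video_id[k], label = vm$label[k],
                            fps = vm$fps[k], nFrames = length(frames))
  }
  new("SyntheticVideoSet", videos = videos, manifest = do.call(rbind, rows),
      config = config)
}
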