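test_that("the oracle detector replays ground truth boxes and absences", {
  ds <- tinyDataset()
  det <- oracleDetector(ds)
  v <- datasetVideos(ds)[[1]]
  fs <- sampleFrames(v)
  d <- detectFrames(det, fs)
  truth <- v$boxes[frameMeta(fs)$frameIndex, ]
  expect_equal(d$detected, !truth$absent)
  ok <- d$detected
  expect_equal(d$xMin[ok], truth$xMin[ok])
  expect_equal(d$yMax[ok], truth$yMax[ok])
})

test_that("background subtraction finds a moving subject accurately", {
  ds <- generateDataset(tinyConfig(seed = 21, blurProb = 0,
                                   absentFrameProb = 0, durationS = 12))
  v <- datasetVideos(ds)[[1]]  # no-pain: high motion
  expect_equal(v$label, "no_pain")
  fs <- sampleFrames(v)
  det <- backgroundDetector(fs)
  d <- detectFrames(det, fs)
  truth <- v$boxes[frameMeta(fs)$frameIndex, ]
  ious <- vapply(which(d$detected), function(i)
    iou(unlist(d[i, 1:4]), unlist(truth[i, c("xMin", "yMin", "xMax", "yMax")])),
    numeric(1))
  expect_gt(sum(d$detected), 0.5 * nFrames(fs))
  expect_gte(mean(ious >= 0.5), 0.9)
})

test_that("a never-moving subject is absorbed into the background model", {
  ds <- generateDataset(tinyConfig(seed = 22, motionAmplitudePain = 0,
                                   blurProb = 0, absentFrameProb = 0))
  pain <- Filter(function(v) v$label == "pain", datasetVideos(ds))[[1]]
  fs <- sampleFrames(pain)
  d <- detectFrames(backgroundDetector(fs), fs)
  expect_true(all(!d$detected))
  # single-frame video: background equals the frame, nothing to detect
  one <- new("FrameSet", frames = frameImages(fs)[1],
             meta = frameMeta(fs)[1, ])
  d1 <- detectFrames(backgroundDetector(one), one)
  expect_false(d1$detected)
})

test_that("detection picks the largest 8-connected changed component", {
  h <- 40; w <- 40
  bgImg <- array(100L, c(h, w, 3L))
  frame <- bgImg
  frame[5:9, 5:14, ] <- 200L          # 50 px blob
  frame[20:29, 15:34, ] <- 220L       # 200 px blob
  # a diagonal tail 8-connected to the large blob must extend its box
  frame[30, 35, ] <- 220L
  fs <- new("FrameSet", frames = list(bgImg, frame),
            meta = data.frame(subjectId = "s", videoId = "v",
                              label = "pain", timestampS = c(0, 1),
                              sampleIndex = 0:1, frameIndex = 1:2))
  det <- new("BackgroundDetector",
             background = matrix(100, h, w), threshold = 25)
  d <- detectFrames(det, fs)
  expect_false(d$detected[1])
  expect_equal(unlist(d[2, c("xMin", "yMin", "xMax", "yMax")]),
               c(xMin = 14, yMin = 19, xMax = 35, yMax = 30))
  expect_equal(d$score[2], 201 / (h * w))
})

test_that("single-frame detection mirrors the per-set path", {
  ds <- tinyDataset()
  det <- oracleDetector(ds)
  fs <- sampleFrames(datasetVideos(ds)[[1]])
  all <- detectFrames(det, fs)
  one <- detectSubject(det, fs, 3L)
  expect_equal(one, all[3, ], ignore_attr = TRUE)
  expect_error(detectSubject(det, fs, 99L), "detector error")
})

test_that("crop and resize honours identity, shape and clipping contracts", {
  img <- array(as.integer(sample(0:255, 30 * 40 * 3, TRUE)), c(30, 40, 3))
  # full-frame box, no padding, same out size: identity
  expect_identical(cropAndResize(img, c(0, 0, 40, 30), padFrac = 0,
                                 outSize = c(30, 40)), img)
  # shape contract
  out <- cropAndResize(img, c(5, 5, 25, 25), padFrac = 0, outSize = c(40, 40))
  expect_equal(dim(out), c(40L, 40L, 3L))
  expect_true(is.integer(out) && all(out >= 0 & out <= 255))
  # corner box with padding clips to the frame instead of erroring
  corner <- cropAndResize(img, c(0, 0, 8, 8), padFrac = 0.1,
                          outSize = c(16, 16))
  expect_equal(dim(corner), c(16L, 16L, 3L))
  # clipping oracle: padded corner box intersected with the frame rectangle
  cropRaw <- cropAndResize(img, c(0, 0, 8, 8), padFrac = 0.1, outSize = NULL)
  expect_identical(cropRaw, img[1:9, 1:9, ])  # ceil(8 + 0.8) = 9
  # degenerate and invalid boxes error
  expect_error(cropAndResize(img, c(10, 10, 10, 20)), "crop error")
  expect_error(cropAndResize(img, c(-30, 0, -20, 10)), "crop error")
})

test_that("cropFrames drops undetected frames and reports the count", {
  ds <- tinyDataset()
  v <- datasetVideos(ds)[[2]]
  fs <- sampleFrames(v)
  cr <- cropFrames(fs, oracleDetector(ds), padFrac = 0.2,
                   outSize = c(32, 32))
  nAbsent <- sum(v$boxes$absent[frameMeta(fs)$frameIndex])
  expect_equal(unname(cr$dropped["no_detection"]), nAbsent)
  expect_equal(nFrames(cr$frames), nFrames(fs) - nAbsent)
  expect_true(all(vapply(frameImages(cr$frames), function(a)
    identical(dim(a), c(32L, 32L, 3L)), logical(1))))
  # labels/ids/timestamps preserved
  expect_true(all(frameMeta(cr$frames)$videoId == v$videoId))
  expect_true(all(frameMeta(cr$frames)$timestampS %in%
                    frameMeta(fs)$timestampS))
})
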