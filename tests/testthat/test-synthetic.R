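test_that("configuration is validated with the offending field named", {
  expect_error(syntheticConfig(nSubjects = 1), "nSubjects")
  expect_error(syntheticConfig(blurProb = 1.5), "blurProb")
  expect_error(syntheticConfig(absentFrameProb = -0.1), "absentFrameProb")
  expect_error(syntheticConfig(motionAmplitudeNoPain = 1,
                               motionAmplitudePain = 2),
               "motionAmplitudePain")
  expect_error(syntheticConfig(fps = 0), "fps")
  expect_s4_class(syntheticConfig(nSubjects = 2), "SyntheticConfig")
})

test_that("a dataset holds two videos per subject, one per class", {
  ds <- generateDataset(syntheticConfig(nSubjects = 24, fps = 1,
                                        durationS = 2, frameSize = c(24, 32),
                                        seed = 1))
  man <- videoManifest(ds)
  expect_equal(nrow(man), 48)
  expect_equal(as.vector(table(man$label)), c(24L, 24L))
  perSubject <- split(man$label, man$subjectId)
  for (labs in perSubject) expect_setequal(labs, c("pain", "no_pain"))
})

test_that("generation is byte-identical for identical config and seed", {
  cfg <- tinyConfig(seed = 7)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  expect_identical(datasetVideos(a), datasetVideos(b))
  expect_identical(videoManifest(a), videoManifest(b))
  c <- generateDataset(tinyConfig(seed = 8))
  expect_false(identical(datasetVideos(a)[[1]]$frames,
                         datasetVideos(c)[[1]]$frames))
})

test_that("pain videos displace strictly less than no-pain videos", {
  disp <- centroidDisplacement(tinyDataset())
  wide <- split(disp, disp$subjectId)
  for (d in wide)
    expect_lt(d$meanDisplacement[d$label == "pain"],
              d$meanDisplacement[d$label == "no_pain"])
})

test_that("a zero motion amplitude yields a perfectly static subject", {
  ds <- generateDataset(tinyConfig(motionAmplitudePain = 0))
  disp <- centroidDisplacement(ds)
  expect_true(all(disp$meanDisplacement[disp$label == "pain"] == 0))
  expect_true(all(disp$meanDisplacement[disp$label == "no_pain"] > 0))
})

test_that("every frame carries a box or an explicit absent marker", {
  for (v in datasetVideos(tinyDataset())) {
    b <- v$boxes
    expect_equal(nrow(b), length(v$frames))
    hasBox <- !is.na(b$xMin)
    expect_true(all(hasBox == !b$absent))
    expect_true(all(b$xMin[hasBox] < b$xMax[hasBox]))
    expect_true(all(b$xMin[hasBox] >= 0 & b$yMin[hasBox] >= 0))
    expect_true(all(b$xMax[hasBox] <= 64 & b$yMax[hasBox] <= 48))
  }
})

test_that("class-signal knobs act independently (motion vs appearance)", {
  subjectMean <- function(v) {
    vals <- unlist(lapply(seq_along(v$frames), function(t) {
      b <- v$boxes[t, ]
      if (b$absent) return(NULL)
      g <- v$frames[[t]][, , 1]
      g[(b$yMin + 1):b$yMax, (b$xMin + 1):b$xMax]
    }))
    mean(vals)
  }
  # appearanceShift = 0: the two videos of one subject differ only in motion;
  # subject-region intensity matches to within sensor noise/flicker
  ds0 <- generateDataset(tinyConfig(appearanceShift = 0, blurProb = 0,
                                    absentFrameProb = 0))
  v <- datasetVideos(ds0)
  expect_lt(abs(subjectMean(v[[1]]) - subjectMean(v[[2]])), 6)
  # appearanceShift > 0: pain subject clearly brighter
  ds1 <- generateDataset(tinyConfig(appearanceShift = 0.5, blurProb = 0,
                                    absentFrameProb = 0))
  v1 <- datasetVideos(ds1)
  pain <- if (v1[[1]]$label == "pain") v1[[1]] else v1[[2]]
  noPain <- if (v1[[1]]$label == "pain") v1[[2]] else v1[[1]]
  expect_gt(subjectMean(pain) - subjectMean(noPain), 15)
})

test_that("fixtures round-trip losslessly through disk", {
  ds <- tinyDataset()
  dir <- withr::local_tempdir()
  manifest <- writeFixture(ds, dir)
  expect_true(file.exists(manifest))
  # frame counts: fps x duration PNGs per video directory
  for (v in datasetVideos(ds))
    expect_length(list.files(file.path(dir, v$videoId), pattern = "\\.png$"),
                  3 * 6)
  back <- readFixture(dir)
  for (k in seq_along(datasetVideos(ds))) {
    expect_identical(datasetVideos(back)[[k]]$frames,
                     datasetVideos(ds)[[k]]$frames)
    expect_equal(datasetVideos(back)[[k]]$boxes$absent,
                 datasetVideos(ds)[[k]]$boxes$absent)
  }
  expect_equal(videoManifest(back), videoManifest(ds))
})

test_that("an empty dataset writes a manifest with zero entries", {
  empty <- new("SyntheticVideoSet", videos = list(),
               manifest = data.frame(subjectId = character(),
                                     videoId = character(),
                                     label = character(), fps = numeric(),
                                     nFrames = integer()),
               config = tinyConfig())
  dir <- withr::local_tempdir()
  manifest <- writeFixture(empty, dir)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_length(man$videos, 0)
  expect_length(list.files(dir, pattern = "\\.png$", recursive = TRUE), 0)
})
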