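test_that("top-frame selection keeps N per subject and class, ranked", {
  se <- separableSe(framesPerVideo = 25)
  m1 <- trainModel1(se)
  top <- selectTopFrames(m1, se, n = 20)
  tab <- selectionTable(top)
  cells <- table(tab$subjectId, tab$class)
  expect_true(all(cells == 20))
  for (cell in split(tab, paste(tab$subjectId, tab$class)))
    expect_true(!is.unsorted(rev(cell$confidence)))
  # monotone selection: kept confidences dominate every excluded frame
  probs <- gnbPredictProba(m1, se)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  conf <- confidenceOf(probs, cd$label)
  for (cell in split(seq_len(ncol(se)), paste(cd$subjectId, cd$label))) {
    keyAll <- paste(cd$videoId[cell], cd$sampleIndex[cell])
    kept <- keyAll %in% paste(tab$videoId, tab$sampleIndex)
    expect_gte(min(conf[cell][kept]), max(conf[cell][!kept]))
  }
})

test_that("undersized cells keep everything available", {
  se <- separableSe(framesPerVideo = 5)
  top <- selectTopFrames(trainModel1(se), se, n = 20)
  expect_true(all(table(selectionTable(top)$subjectId,
                        selectionTable(top)$class) == 5))
})

test_that("ties at the cut match a brute-force stable sort oracle", {
  # identical embeddings -> identical confidences -> timestamp decides
  X <- matrix(rep(c(0, 0, 0, 3, 3, 3), 2), ncol = 1)
  meta <- data.frame(
    subjectId = "s1",
    videoId = rep(c("s1_no_pain", "s1_pain"), each = 3, times = 2),
    label = rep(c("no_pain", "pain"), each = 3, times = 2),
    timestampS = c(0, 1, 2, 0, 1, 2, 3, 4, 5, 3, 4, 5),
    sampleIndex = as.integer(c(0, 1, 2, 0, 1, 2, 3, 4, 5, 3, 4, 5)),
    frameIndex = 1:12)
  se <- seFromMatrix(X, meta)
  m <- trainModel1(se)
  top <- selectTopFrames(m, se, n = 2)
  tab <- selectionTable(top)
  # brute-force oracle: stable order by (-confidence, timestamp, videoId)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  conf <- confidenceOf(gnbPredictProba(m, se), cd$label)
  for (cell in split(seq_len(nrow(cd)), paste(cd$subjectId, cd$label))) {
    o <- cell[order(-conf[cell], cd$timestampS[cell], cd$videoId[cell])]
    want <- cd$sampleIndex[o][1:2]
    got <- tab$sampleIndex[tab$class == cd$label[cell[1]]]
    expect_equal(sort(got), sort(want))
    expect_equal(got, want)
  }
  # earliest timestamps win on full ties
  expect_setequal(tab$sampleIndex[tab$class == "pain"], c(0L, 1L))
})

test_that("a subject missing one class yields a warning and empty cell", {
  se <- separableSe()
  cd <- SummarizedExperiment::colData(se)
  keep <- !(cd$subjectId == "s2" & cd$label == "pain")
  expect_warning(top <- selectTopFrames(trainModel1(se[, keep]), se[, keep]),
                 "s2 pain")
  expect_equal(nrow(subset(selectionTable(top),
                           subjectId == "s2" & class == "pain")), 0)
})

test_that("training on duplicated samples leaves the model unchanged", {
  se <- separableSe()
  X <- t(SummarizedExperiment::assay(se))
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  m <- gnbFit(X, cd$label)
  mDup <- gnbFit(rbind(X, X), c(cd$label, cd$label))
  expect_equal(classMeans(m), classMeans(mDup))
  expect_equal(classVariances(m), classVariances(mDup))
  expect_equal(classPriors(m), classPriors(mDup))
})

test_that("selecting all frames makes stage two equal stage one", {
  se <- separableSe(framesPerVideo = 10)
  m1 <- trainModel1(se)
  top <- selectTopFrames(m1, se, n = 10)
  m2 <- trainModel2(top, se)
  expect_equal(classMeans(m1), classMeans(m2))
  expect_equal(classVariances(m1), classVariances(m2))
})

test_that("separable training data is fit almost perfectly; shuffled labels at chance", {
  se <- separableSe(framesPerVideo = 30)
  cd <- as.data.frame(SummarizedExperiment::colData(se))
  m <- trainModel1(se)
  acc <- mean(gnbPredict(m, se) == cd$label)
  expect_gt(acc, 0.9)
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    y <- sample(cd$label)
    mean(gnbPredict(gnbFit(se, labels = y), se) == y)
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("an all-empty pain cell cannot train stage two", {
  se <- separableSe()
  cd <- SummarizedExperiment::colData(se)
  keep <- cd$label == "no_pain"
  top <- new("TopFrameSet",
             selection = subset(data.frame(
               subjectId = cd$subjectId, class = cd$label,
               videoId = cd$videoId, sampleIndex = cd$sampleIndex,
               timestampS = cd$timestampS, confidence = 1), class == "no_pain"),
             n = 50L)
  expect_error(trainModel2(top, se), "fitting error")
})
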