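test_that("pixel-statistics embeddings meet the shape and determinism contract", {
  be <- pixelStatsBackend(grid = 4, histBins = 8)
  expect_equal(embedDim(be), 16 + 24)
  img <- array(as.integer(sample(0:255, 32 * 32 * 3, TRUE)), c(32, 32, 3))
  fs <- new("FrameSet", frames = list(img, img),
            meta = data.frame(subjectId = "s", videoId = "v", label = "pain",
                              timestampS = 0:1, sampleIndex = 0:1,
                              frameIndex = 1:2))
  se <- embedFrames(fs, be)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(40L, 2L))
  # same image twice -> identical vectors
  expect_identical(SummarizedExperiment::assay(se)[, 1],
                   SummarizedExperiment::assay(se)[, 2])
  # one-pixel difference is visible to the backend
  img2 <- img
  img2[1, 1, 1] <- (img2[1, 1, 1] + 128L) %% 256L
  fs2 <- new("FrameSet", frames = list(img2), meta = frameMeta(fs)[1, ])
  expect_false(identical(SummarizedExperiment::assay(embedFrames(fs2, be))[, 1],
                         SummarizedExperiment::assay(se)[, 1]))
  expect_error(embedFrames(fs, structure(list(), class = "lm")),
               "capability error")
})

test_that("the fitted moments match hand-computed values", {
  m <- gnbFit(matrix(c(0, 1, 2, 3)), c("a", "a", "b", "b"))
  expect_equal(unname(classMeans(m)[, 1]), c(0.5, 2.5))
  expect_equal(unname(classVariances(m)[, 1]), c(0.25, 0.25) + m@eps)
  expect_equal(unname(classPriors(m)), c(0.5, 0.5))
  # priors count samples
  m2 <- gnbFit(matrix(c(0, 1, 2, 9)), c("a", "a", "a", "b"))
  expect_equal(unname(classPriors(m2)), c(0.75, 0.25))
  # identical samples in a class floor at the smoothing eps, densities finite
  m3 <- gnbFit(matrix(c(5, 5, 5, 0, 1, 2), ncol = 1),
               rep(c("a", "b"), each = 3))
  expect_equal(unname(classVariances(m3)["a", 1]), m3@eps)
  p <- gnbPredictProba(m3, 5)
  expect_true(all(is.finite(p)))
  # single class or empty class is a fitting error
  expect_error(gnbFit(matrix(1:3), rep("a", 3)), "fitting error")
  expect_error(gnbFit(matrix(1:3), c("a", "a", "b"), classes = c("a", "b", "c")),
               "fitting error")
})

test_that("posteriors agree with the brute-force linear-space oracle", {
  m <- gnbFit(matrix(c(0, 1, 2, 3)), c("a", "a", "b", "b"))
  expect_equal(unname(gnbPredictProba(m, 1.5)[1, ]), c(0.5, 0.5))  # midpoint
  expect_gt(gnbPredictProba(m, 0.5)[1, "a"], 0.99)
  oracle <- bruteForceGnbProba(classPriors(m), classMeans(m),
                               classVariances(m), 0.5)
  expect_equal(unname(gnbPredictProba(m, 0.5)[1, ]), unname(oracle),
               tolerance = 1e-12)
  # random small instances
  set.seed(42)
  for (i in 1:25) {
    n <- sample(6:20, 1); d <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    y <- sample(c("a", "b"), n, TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c("a", "b")
    mod <- gnbFit(X, y)
    x <- rnorm(d)
    expect_equal(unname(gnbPredictProba(mod, x)[1, ]),
                 unname(bruteForceGnbProba(classPriors(mod), classMeans(mod),
                                           classVariances(mod), x)),
                 tolerance = 1e-9)
  }
})

test_that("equal class-conditional densities reduce posteriors to the priors", {
  # both classes see the same sample values; only counts differ
  X <- matrix(rep(c(0, 1), 4), ncol = 1)
  y <- c("a", "a", "a", "a", "a", "a", "b", "b")
  m <- gnbFit(X, y)
  expect_equal(unname(gnbPredictProba(m, 0.3)[1, ]), c(0.75, 0.25))
})

test_that("relabelling classes swaps posterior columns exactly", {
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2)
  y <- sample(c("a", "b"), 20, TRUE); y[1:2] <- c("a", "b")
  yFlip <- ifelse(y == "a", "b", "a")
  p <- gnbPredictProba(gnbFit(X, y), c(0.2, -0.4))
  pFlip <- gnbPredictProba(gnbFit(X, yFlip), c(0.2, -0.4))
  expect_equal(unname(p[1, "a"]), unname(pFlip[1, "b"]))
  expect_equal(unname(p[1, "b"]), unname(pFlip[1, "a"]))
})

test_that("fitting recovers known Gaussian parameters at n = 10000", {
  set.seed(11)
  n <- 10000
  X <- rbind(matrix(rnorm(n * 2, 1, 2), n, 2),
             matrix(rnorm(n * 2, -1, 0.5), n, 2))
  y <- rep(c("a", "b"), each = n)
  m <- gnbFit(X, y)
  seA <- 2 / sqrt(n); seB <- 0.5 / sqrt(n)
  expect_true(all(abs(classMeans(m)["a", ] - 1) < 3 * seA))
  expect_true(all(abs(classMeans(m)["b", ] + 1) < 3 * seB))
  expect_equal(unname(classVariances(m)["a", ]), c(4, 4), tolerance = 0.1)
})

test_that("feature scaling leaves posteriors unchanged", {
  set.seed(13)
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(c("a", "b"), 15)
  x <- c(0.5, -0.2)
  p1 <- gnbPredictProba(gnbFit(X, y), x)
  p2 <- gnbPredictProba(gnbFit(X * 1000, y), x * 1000)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("variances match an independent naive Bayes fit (e1071)", {
  skip_if_not_installed("e1071")
  set.seed(3)
  X <- matrix(rnorm(100), 50, 2); colnames(X) <- c("f1", "f2")
  y <- factor(rep(c("a", "b"), 25))
  mine <- gnbFit(X, as.character(y), varSmoothing = 1e-300)
  ref <- e1071::naiveBayes(X, y)
  for (cl in c("a", "b")) {
    nc <- sum(y == cl)
    expect_equal(unname(classMeans(mine)[cl, ]),
                 unname(vapply(ref$tables, function(t) t[cl, 1], numeric(1))))
    # e1071 stores sd with the n-1 denominator; ours is population variance
    expect_equal(unname(classVariances(mine)[cl, ]),
                 unname(vapply(ref$tables, function(t) t[cl, 2]^2, numeric(1))) *
                   (nc - 1) / nc,
                 tolerance = 1e-12)
  }
})

test_that("confidence reads the probability of the requested class", {
  probs <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  colnames(probs) <- c("no_pain", "pain")
  expect_equal(confidenceOf(probs, "pain"), c(0.1, 0.5))
  expect_equal(confidenceOf(probs, "no_pain"), c(0.9, 0.5))
  expect_equal(confidenceOf(probs, c("pain", "no_pain")), c(0.1, 0.5))
  expect_error(confidenceOf(probs, "sleepy"), "unknown class")
})

test_that("models survive a JSON round trip", {
  set.seed(5)
  m <- gnbFit(matrix(rnorm(40), 20, 2), rep(c("no_pain", "pain"), 10))
  path <- withr::local_tempfile(fileext = ".json")
  writeGnbModel(m, path)
  back <- readGnbModel(path)
  expect_equal(modelClasses(back), modelClasses(m))
  expect_equal(classMeans(back), classMeans(m), tolerance = 1e-15,
               ignore_attr = TRUE)
  x <- rnorm(2)
  expect_equal(gnbPredictProba(back, x), gnbPredictProba(m, x))
})
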