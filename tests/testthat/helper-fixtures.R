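# Shared tiny fixtures, memoized so expensive generation runs once per suite.

.fixtureCache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# 2-subject, 3 fps x 6 s, 48x64 dataset with moderate noise
tinyConfig <- function(seed = 7, ...) {
  args <- list(nSubjects = 2, fps = 3, durationS = 6, frameSize = c(48, 64),
               motionAmplitudeNoPain = 4, motionAmplitudePain = 0.5,
               blurProb = 0.1, absentFrameProb = 0.1, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(syntheticConfig, args)
}

tinyDataset <- function() memoize("tinyDataset", generateDataset(tinyConfig()))

# 6-subject noise-free dataset for pipeline-level tests
pipelineDataset <- function() memoize("pipelineDataset",
  generateDataset(tinyConfig(seed = 5, nSubjects = 6, durationS = 16,
                             blurProb = 0, absentFrameProb = 0,
                             motionAmplitudeNoPain = 8,
                             motionAmplitudePain = 0.3,
                             appearanceShift = 0.5)))

tinyRunConfig <- function(...) {
  runConfig(crop = list(padFrac = 0.35, outSize = c(48L, 48L)),
            evaluation = list(nVal = 1L, seed = 1L),
            selection = list(n = 8L), ...)
}

pipelineEmbeddings <- function() memoize("pipelineEmbeddings",
  prepareEmbeddings(pipelineDataset(), tinyRunConfig()))

# build an embedding-like SummarizedExperiment directly from a matrix
seFromMatrix <- function(X, meta) {
  SummarizedExperiment::SummarizedExperiment(
    assays = list(embedding = t(X)),
    colData = S4Vectors::DataFrame(meta))
}

# two well-separated 1-D classes for n frames per video
separableSe <- function(framesPerVideo = 25, subjects = c("s1", "s2"),
                        seed = 1, jitterSd = 0.1) {
  set.seed(seed)
  rows <- list(); xs <- numeric()
  for (s in subjects) for (lab in c("no_pain", "pain")) {
    mu <- if (lab == "pain") 3 else 0
    xs <- c(xs, rnorm(framesPerVideo, mu, jitterSd))
    rows[[length(rows) + 1]] <- data.frame(
      subjectId = s, videoId = paste0(s, "_", lab), label = lab,
      timestampS = seq_len(framesPerVideo) - 1,
      sampleIndex = seq_len(framesPerVideo) - 1L,
      frameIndex = seq_len(framesPerVideo))
  }
  seFromMatrix(matrix(xs, ncol = 1), do.call(rbind, rows))
}

# in-memory synthetic video: n gray frames of constant intensity = frame index
flatVideo <- function(nFrames, fps, h = 20, w = 20, label = "pain",
                      subjectId = "sX", videoId = "vX") {
  list(frames = lapply(seq_len(nFrames), function(i)
         array(as.integer(min(i, 255L)), c(h, w, 3L))),
       fps = fps, subjectId = subjectId, videoId = videoId, label = label)
}

# brute-force Gaussian naive Bayes posterior in linear space (independent
# oracle: explicit per-feature normal densities multiplied together)
bruteForceGnbProba <- function(priors, means, vars, x) {
  k <- length(priors)
  joint <- vapply(seq_len(k), function(ci) {
    priors[ci] * prod(stats::dnorm(x, means[ci, ], sqrt(vars[ci, ])))
  }, numeric(1))
  joint / sum(joint)
}

iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}
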