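#' @include AllClasses.R AllGenerics.R
NULL

#' Deterministic pixel-statistics embedding backend
#'
#' Training-free image embedder for the tested pipeline core: each channel is
#' block-mean downsampled to a \code{grid} x \code{grid} raster and
#' flattened; by default a fourth block holds the downsampled per-pixel
#' cross-channel range (max - min over channels), which makes the apparent
#' colour of a short-term stack — i.e. motion — a first-order feature that a
#' naive Bayes head can read from feature marginals. Optional per-channel
#' intensity histograms can be appended. Intensities are scaled to [0, 1].
#' Heavier pretrained encoders (e.g. a 512-d contrastive vision-language
#' embedding) plug in behind the same contract via \code{\link{embedFrames}}.
#'
#' @param grid raster side length g (default 8).
#' @param histBins per-channel histogram bins (default 16; 0 disables).
#' @param channelRange include the cross-channel range block (default TRUE).
#' @param channelGrid include the raw per-channel g x g block means (default
#'   FALSE: they are strongly position-sensitive, which under
#'   leave-one-subject-out evaluation feeds subject-identity nuisance into
#'   the naive Bayes head; histograms carry the appearance signal
#'   position-invariantly instead).
#' @return an object of class \code{PixelStatsEmbedder}.
#' @export
pixelStatsBackend <- function(grid = 8L, histBins = 16L, channelRange = TRUE,
                              channelGrid = FALSE) {
  stopifnot(grid >= 1, histBins >= 0)
  if (!isTRUE(channelRange) && !isTRUE(channelGrid) && histBins < 1)
    stop("capability error: backend with no feature blocks", call. = FALSE)
  structure(list(grid = as.integer(grid), histBins = as.integer(histBins),
                 channelRange = isTRUE(channelRange),
                 channelGrid = isTRUE(channelGrid)),
            class = c("PixelStatsEmbedder", "EmbedderBackend"))
}

#' Embedding dimension of a backend
#' @param backend an embedder backend.
#' @return integer vector length d of the produced embeddings.
#' @export
embedDim <- function(backend) {
  UseMethod("embedDim")
}

#' @export
embedDim.PixelStatsEmbedder <- function(backend) {
  backend$grid^2 * (3L * backend$channelGrid + backend$channelRange) +
    3L * backend$histBins
}

embedOne <- function(img, backend) {
  assertFrameArray(img)
  g <- backend$grid
  feats <- numeric(0)
  if (backend$channelGrid)
    feats <- c(vapply(1:3, function(k) as.numeric(blockMean(img[, , k], g)),
                      numeric(g * g)))
  if (backend$channelRange) {
    # gain-normalize channels before comparing them, so global illumination
    # flicker between the three time steps cancels and only local change
    # (motion) contributes to the cross-channel range
    mu <- vapply(1:3, function(k) mean(img[, , k]), numeric(1))
    gbar <- mean(mu)
    ch <- lapply(1:3, function(k) img[, , k] * (gbar / max(mu[k], 1)))
    rng <- pmax(ch[[1]], ch[[2]], ch[[3]]) - pmin(ch[[1]], ch[[2]], ch[[3]])
    feats <- c(feats, as.numeric(blockMean(rng, g)))
  }
  if (backend$histBins > 0) {
    br <- seq(0, 255, length.out = backend$histBins + 1L)
    feats <- c(feats, vapply(1:3, function(k) {
      h <- hist(pmin(img[, , k], 255), breaks = br, plot = FALSE)$counts
      h / sum(h)
    }, numeric(backend$histBins)))
  }
  feats / 255
}

#' Embed frames into a SummarizedExperiment
#'
#' One d-dimensional vector per frame, deterministic given backend and
#' pixels. The result carries the d x n embedding matrix as the
#' \code{"embedding"} assay with the frame metadata as column data, so
#' classifier stages can subset by subject/video without reindexing.
#'
#' @param frameSet a \linkS4class{FrameSet} (uniform frame size).
#' @param backend an embedder backend, e.g. \code{\link{pixelStatsBackend}}.
#' @return a \code{SummarizedExperiment}.
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @export
embedFrames <- function(frameSet, backend) {
  stopifnot(is(frameSet, "FrameSet"))
  if (!inherits(backend, "EmbedderBackend"))
    stop("capability error: not an initialized embedder backend", call. = FALSE)
  n <- nFrames(frameSet)
  d <- embedDim(backend)
  mat <- matrix(NA_real_, d, n)
  for (i in seq_len(n)) mat[, i] <- embedOne(frameImages(frameSet)[[i]], backend)
  if (n && !all(is.finite(mat)))
    stop("embedding produced non-finite entries", call. = FALSE)
  rownames(mat) <- sprintf("f%04d", seq_len(d))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(embedding = mat),
    colData = S4Vectors::DataFrame(frameMeta(frameSet)))
}

# n x d sample matrix from an embedding SummarizedExperiment or a matrix
sampleMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) t(SummarizedExperiment::assay(x, "embedding"))
  else as.matrix(x)
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Estimates per-class feature means, per-class population variances
#' (divide-by-n) with additive smoothing, and log priors from class counts.
#' The smoothing floor is \code{varSmoothing} times the largest overall
#' feature variance (or \code{varSmoothing} itself when all features are
#' constant), added to every class variance.
#'
#' @param x n x d numeric matrix of embeddings, or a
#'   \code{SummarizedExperiment} from \code{\link{embedFrames}}.
#' @param labels class label per row; defaults to the \code{label} column of
#'   the SummarizedExperiment's column data.
#' @param varSmoothing relative smoothing strength (default 1e-9).
#' @param classes class order for prediction columns; defaults to the sorted
#'   unique labels (\code{no_pain} before \code{pain}).
#' @return a \linkS4class{GnbModel}.
#' @examples
#' m <- gnbFit(matrix(c(0, 1, 2, 3)), c("a", "a", "b", "b"))
#' classMeans(m)  # 0.5 and 2.5
#' @export
gnbFit <- function(x, labels = NULL, varSmoothing = 1e-9, classes = NULL) {
  if (is.null(labels) && is(x, "SummarizedExperiment"))
    labels <- SummarizedExperiment::colData(x)$label
  X <- sampleMatrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(X))
    stop("one label per sample required", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(labels))
  if (length(classes) < 2 || !all(labels %in% classes))
    stop("fitting error: need samples from at least two known classes",
         call. = FALSE)
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  if (any(counts == 0))
    stop(sprintf("fitting error: class '%s' has no samples",
                 classes[which(counts == 0)[1]]), call. = FALSE)
  d <- ncol(X)
  mu <- matrix(NA_real_, length(classes), d,
               dimnames = list(classes, colnames(X)))
  va <- mu
  for (cl in classes) {
    Xc <- X[labels == cl, , drop = FALSE]
    m <- colMeans(Xc)
    mu[cl, ] <- m
    va[cl, ] <- colMeans(Xc^2) - m^2           # population variance
  }
  va <- pmax(va, 0)                            # guard fp cancellation
  gm <- colMeans(X)
  globalVar <- colMeans(X^2) - gm^2
  eps <- varSmoothing * max(globalVar, 0)
  if (eps <= 0) eps <- varSmoothing
  new("GnbModel", classes = classes,
      logPriors = setNames(log(counts) - log(sum(counts)), classes),
      means = mu, variances = va + eps, eps = eps)
}

# per-class joint log density log P(c) + sum_j log N(x_j; mu_cj, var_cj)
gnbJointLogLik <- function(model, X) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, length(model@classes),
                dimnames = list(NULL, model@classes))
  for (k in seq_along(model@classes)) {
    v <- model@variances[k, ]
    m <- model@means[k, ]
    const <- -0.5 * sum(log(2 * pi * v))
    quad <- -0.5 * colSums((t(X) - m)^2 / v)
    out[, k] <- model@logPriors[k] + const + quad
  }
  out
}

#' Posterior class probabilities from a Gaussian naive Bayes model
#'
#' Underflow-safe softmax over the per-class joint log densities
#' (log prior + summed Gaussian feature log densities); rows sum to 1.
#'
#' @param model a fitted \linkS4class{GnbModel}.
#' @param x n x d matrix, a single length-d vector, or a
#'   \code{SummarizedExperiment}.
#' @return n x classes matrix of posterior probabilities.
#' @export
gnbPredictProba <- function(model, x) {
  stopifnot(is(model, "GnbModel"))
  X <- if (is.numeric(x) && is.null(dim(x))) matrix(x, nrow = 1)
       else sampleMatrix(x)
  if (ncol(X) != ncol(model@means))
    stop(sprintf("shape error: model has %d features, input has %d",
                 ncol(model@means), ncol(X)), call. = FALSE)
  ll <- gnbJointLogLik(model, X)
  mx <- apply(ll, 1, max)
  p <- exp(ll - mx)
  p / rowSums(p)
}

#' Predicted class labels
#' @param model a fitted \linkS4class{GnbModel}.
#' @param x samples as in \code{\link{gnbPredictProba}}.
#' @return character vector of class labels (ties resolve to the earlier
#'   class in the model's class order).
#' @export
gnbPredict <- function(model, x) {
  p <- gnbPredictProba(model, x)
  model@classes[apply(p, 1, which.max)]
}

#' Confidence in a target class
#'
#' The confidence of a frame for a class is simply the posterior probability
#' assigned to that class.
#'
#' @param probs probability matrix (columns named by class) or a named
#'   probability vector.
#' @param targetClass class name, or a vector with one class per row.
#' @return numeric confidence(s) in [0, 1].
#' @export
confidenceOf <- function(probs, targetClass) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(NULL, names(probs)))
  bad <- setdiff(unique(targetClass), colnames(probs))
  if (length(bad))
    stop(sprintf("unknown class '%s'", bad[1]), call. = FALSE)
  if (length(targetClass) == 1L) unname(probs[, targetClass])
  else probs[cbind(seq_len(nrow(probs)), match(targetClass, colnames(probs)))]
}

#' Serialize / restore a Gaussian naive Bayes model as JSON
#'
#' @param model a \linkS4class{GnbModel}.
#' @param path file path.
#' @return \code{writeGnbModel}: the path, invisibly; \code{readGnbModel}:
#'   the restored \linkS4class{GnbModel}.
#' @export
writeGnbModel <- function(model, path) {
  stopifnot(is(model, "GnbModel"))
  jsonlite::write_json(list(
    classes = model@classes, log_priors = unname(model@logPriors),
    means = unname(model@means), variances = unname(model@variances),
    eps = model@eps), path, digits = NA)
  invisible(path)
}

#' @rdname writeGnbModel
#' @export
readGnbModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("GnbModel", classes = j$classes,
      logPriors = setNames(j$log_priors, j$classes),
      means = matrix(j$means, nrow = length(j$classes),
                     dimnames = list(j$classes, NULL)),
      variances = matrix(j$variances, nrow = length(j$classes),
                         dimnames = list(j$classes, NULL)),
      eps = j$eps)
}
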