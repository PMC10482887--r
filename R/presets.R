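#' @include AllClasses.R AllGenerics.R
NULL

#' Benchmark scenario presets
#'
#' Canonical synthetic scenarios used throughout the package's tests,
#' examples and the reproduction script, at a desk-scale problem size
#' (12 subjects, 4 fps x 48 s, 48x64 px frames):
#' \describe{
#'   \item{\code{noisy_motion_only}}{the headline scenario: the only class
#'     signal is motion (pain subjects step 0.5 px/frame vs 4 px/frame;
#'     no appearance shift) and roughly 30\% of frames are corrupted
#'     (15\% subject-absent + 15\% motion-blurred), emulating in-the-wild
#'     cage footage.}
#'   \item{\code{clean_separable}}{a noise-free ceiling scenario with both a
#'     strong motion contrast (8 vs 0.3 px/frame) and an appearance shift of
#'     0.5, on which the full pipeline should classify every video
#'     correctly.}
#' }
#'
#' @param name preset name, see above.
#' @param seed integer RNG seed for the generator.
#' @return a \linkS4class{SyntheticConfig}.
#' @seealso \code{\link{presetRunConfig}} for the matching pipeline settings.
#' @export
presetConfig <- function(name = c("noisy_motion_only", "clean_separable"),
                         seed = 1L) {
  name <- match.arg(name)
  base <- list(nSubjects = 12, fps = 4, durationS = 48, frameSize = c(48, 64),
               occlusionBarCount = 16, occlusionBarWidth = 1, seed = seed)
  extra <- switch(name,
    noisy_motion_only = list(motionAmplitudeNoPain = 4,
                             motionAmplitudePain = 0.5, blurProb = 0.15,
                             absentFrameProb = 0.15, appearanceShift = 0),
    clean_separable = list(motionAmplitudeNoPain = 8,
                           motionAmplitudePain = 0.3, blurProb = 0,
                           absentFrameProb = 0, appearanceShift = 0.5))
  do.call(syntheticConfig, c(base, extra))
}

#' Pipeline settings matching the benchmark presets
#'
#' The study-default pipeline scaled to the preset frame size: 64x64 crops
#' instead of 224x224 (the synthetic subject carries no fine detail worth
#' the larger raster) and, for the 12-subject presets, 4 validation subjects
#' per fold as in the full design. All other settings are the
#' \code{\link{runConfig}} defaults.
#'
#' @param ... overrides forwarded to \code{\link{runConfig}}.
#' @return nested configuration list.
#' @export
presetRunConfig <- function(...) {
  runConfig(crop = list(padFrac = 0.35, outSize = c(64L, 64L)),
            evaluation = list(nVal = 4L, seed = 1L),
            selection = list(n = 20L), ...)
}
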