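---
title: "Two-stage video pain recognition with Grayscale Short-Term Stacking"
author: "painstack maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage video pain recognition with Grayscale Short-Term Stacking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painstack)
```

## The problem

Behavioural pain assessment in laboratory animals (the motivating case is
acute postoperative pain in rabbits housed in barred cages) is usually done
by trained human scorers using grimace or behaviour scales. Automating it
from cage video runs into two obstacles. First, almost all affordable
classifiers are *static*: they look at single frames and lose the temporal
information that matters most, since reduced movement is itself a
behavioural indicator of pain. Second, in-the-wild cage footage is noisy —
cage bars occlude the animal, the animal turns away from the camera or
leaves the field of view, and movement causes motion blur — so many frames
are uninformative or misleading.

`painstack` implements a two-stage pipeline that addresses both problems
with cheap, frame-level machinery:

1. **Sampling.** Each video is trimmed to 2 minutes and sampled at one
   frame per second (a 7200-frame, 60 fps video becomes 120 frames). The
   first frame of each second is taken; the phase within the second is a
   convention, not a claim.
2. **Detection and cropping.** A detector localizes the subject in each
   sampled frame; the box is padded, cropped and resized. Frames with no
   detection are dropped and counted.
3. **Grayscale Short-Term Stacking (GrayST).** The three colour channels of
   a working image are replaced by the grayscale frames of three
   consecutive sampled seconds (chronological order: t → R, t+1 → G,
   t+2 → B). A plain 2-D classifier then sees short-term motion as apparent
   colour; an animal static for three seconds renders as a pure gray image.
4. **Embedding + Gaussian naive Bayes.** Images are embedded by a pluggable
   backend and classified by a from-scratch Gaussian naive Bayes (GNB)
   head: per-class feature means, smoothed per-class population variances,
   log priors from class counts, and an underflow-safe log-sum-exp
   posterior.
5. **Confidence-ranked Top-N selection.** A first model ("Model 1") is
   trained on all stacked frames of the training subjects. For every
   training subject and class, the frames of the video carrying that class
   label are ranked by Model 1's confidence *in the video's known label*
   and the top N = 20 are kept. Ranking by the known label is what makes
   the result a labelled training set; ties break to the earlier timestamp,
   then the lower video id.
6. **Retraining and evaluation.** "Model 2" is retrained on the Top-N set
   only. Both models are evaluated on *all* frames of held-out videos;
   frame probabilities are averaged per video (average pooling) and the
   class with the highest mean wins, with exact ties resolved to `no_pain`
   (never flag pain without an evidence margin).

Evaluation is leave-one-subject-out (LOSO): with 24 subjects and the
default of 4 validation subjects, every fold trains on 19 subjects,
validates on 4 and tests on the held-out one, so no individual's data can
leak across the split. Model 1, the selection, and Model 2 are all computed
per fold from training subjects only. Validation subjects pass through
untouched unless the user tunes hyperparameters on them; the GNB head has
no checkpoints to select.

## The synthetic benchmark

The original footage of this kind of study is typically not redistributable,
so the package ships a seeded generator whose class signal matches the
behavioural premise: a textured elliptical subject performs a random walk on
a static textured cage background, and the *pain* video of every subject
uses a strictly smaller step size than its *no-pain* video. Noise sources
mirror the field's complaints: fixed vertical cage bars composited over the
subject, per-frame directional motion blur, and frames where the subject is
absent. Every frame carries a ground-truth box or an explicit absent
marker, which also powers an oracle detector for tests that should not
depend on detector quality.

Design choices worth knowing about, all fixed before the acceptance suite
was frozen:

* **One cage, one species.** The background and the subjects' base texture
  are generated once per dataset and shared, with only small per-subject
  jitter. If each subject had its own texture, subject identity would be a
  dominant image feature and LOSO generalization would be structurally
  impossible for a naive Bayes head — which would test the generator, not
  the pipeline.
* **Camera noise.** Every frame gets 5% multiplicative illumination flicker
  and additive sensor noise (SD 2 intensity units). Without them a static
  subject produces *exactly* constant features, class variances collapse to
  the smoothing floor, and GNB log-odds explode on held-out subjects; no
  real camera produces identical frames.
* **Dense thin bars.** Default occlusion is 16 bars of 1 px rather than a
  few wide ones: at the embedder's grid resolution the phase of wide bars
  relative to the crop is a subject fingerprint with near-zero within-class
  variance, the same degenerate geometry as above.
* **Blur along the motion direction** on a per-frame coin flip, emulating
  movement blur; it both corrupts the apparent-colour motion cue of pain
  frames (they acquire spurious saturation) and smears the texture of
  no-pain frames.
* **Class-signal knobs.** With `appearanceShift = 0` motion is the only
  class signal; with (nearly) equal amplitudes an intensity offset on the
  pain subject is the only signal. The two knobs are independent by
  construction.

What the generator does **not** model: posture or facial expression (the
subject is a rigid ellipse), analgesia or 24-hour time points, multiple
animals, camera motion, and any species-specific appearance. Passing tests
on this benchmark therefore demonstrate that the pipeline's machinery is
sound and that its qualitative claims (GrayST ordering, two-stage gain)
hold when the class signal is motion — they say nothing about accuracy on
real animals.

## The embedding backend

The tested core uses a deterministic, training-free pixel-statistics
backend (`pixelStatsBackend()`); pretrained encoders (e.g. a 512-d
contrastive vision–language embedding) can be plugged in behind the same
`embedFrames()` contract but are deliberately outside the test surface.
The backend computes, per image:

* a **cross-channel-range grid** (default 8×8): each channel is first
  gain-normalized to the stack's mean intensity — which cancels
  illumination flicker between the three time steps exactly — then the
  per-pixel range (max − min across channels) is block-mean downsampled.
  For a GrayST stack this is precisely the "apparent colour saturation"
  motion cue, exposed as first-order features a naive Bayes head can use.
* **per-channel histograms** (default 16 bins): position-invariant
  appearance features.

The raw per-channel block-mean grid is implemented
(`channelGrid = TRUE`) but off by default: its features are strongly
position-sensitive, and under LOSO they inject subject-identity nuisance
(which background patch, which bar phase) whose between-subject variance
dwarfs its within-class variance — empirically this halves video accuracy
on clean data. This is an instance of a general caveat: naive Bayes has no
way to discount a feature whose nuisance variation is between-subject.

## Numerical and procedural choices

* **Luma.** RGB→gray uses ITU-R BT.601 (0.299, 0.587, 0.114), rounded
  half-up and clipped to 0–255.
* **GNB.** Population variances (divide by *n*); additive smoothing
  `varSmoothing × max` overall feature variance (default 1e-9), with
  `varSmoothing` itself as the floor if all features are constant. All
  densities in log space; posteriors via log-sum-exp.
* **Windows.** GrayST windows slide with stride 1 (configurable) over each
  video's sampled sequence and never span a gap left by a dropped frame;
  the stack inherits the middle frame's timestamp.
* **Crop padding 0.35.** The detector's box is tight around the subject and
  crops are subject-centred, so all motion evidence lives in the background
  margin of the crop; at the conventional 5% padding that margin is a
  couple of pixels and the motion cue disappears. 35% padding per side
  keeps a meaningful margin while the subject still fills most of the crop.
* **Degenerate inputs.** Zero-length videos sample to an empty set (not an
  error); videos shorter than the trim point are used in full; a video
  whose frames are all dropped raises an aggregation error naming the
  video; empty precision/recall denominators yield 0 with a warning.
* **Background detector.** Per-pixel median background over the video's
  sampled grayscale frames; |frame − background| > 25 (configurable);
  morphological closing with a 3×3 box (thin bars slice silhouettes);
  largest 8-connected component wins (EBImage's 4-connected labels are
  merged across diagonal adjacencies). A subject that never moves is
  absorbed into the background and undetectable *by construction* — use
  the oracle detector, or a real external detector, for such footage.

## Problem sizes used by tests and the reproduction script

The package's benchmark presets (`presetConfig()`) use 12 subjects, 4 fps ×
48 s videos at 48×64 px with 64×64 crops, rather than the full study-scale
defaults (24 subjects, 60 fps × 120 s) that `syntheticConfig()` documents.
These sizes keep a 10-seed, 2×12-fold LOSO experiment comfortable on a
single CPU while preserving the quantities that matter: ~46 sampled stacks
per video, so the Top-20 selection still has enough clean frames (under
30% corruption) to purify the stage-2 training set — if videos are much
shorter than that, selection *cannot* discard the corrupted frames and the
two-stage gain disappears, which is a property of the method, not a bug.

## Known limitations

* The pixel-statistics backend is intentionally simple; it measures the
  pipeline, not the state of the art. Appearance signals subtler than an
  intensity shift (posture, facial action units) are invisible to it.
* Selection ranks by the video's known label; applying the pipeline to
  unlabeled new videos uses only the trained Model 2.
* With a static subject the baseline background detector fails by design;
  real deployments should plug in a trained detector via the oracle/external
  adapter contract.
* Confidence is the posterior class probability of an uncalibrated GNB; it
  ranks frames well but is not a calibrated probability.
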