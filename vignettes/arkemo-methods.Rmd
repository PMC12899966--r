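---
title: "Prototype-based emotion recognition from blend shape streams: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prototype-based emotion recognition from blend shape streams: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arkemo)
```

## The problem

Modern face-tracking frameworks (ARKit on iOS, MediaPipe elsewhere) stream,
at video rate, a vector of 52 *blend shape coefficients*: continuous
activations in [0, 1] of semantically named facial movements such as
`jawOpen` or `browInnerUp`. Because these coefficients map onto FACS action
units (AUs), they support an interpretable, training-free route to facial
emotion recognition: define, per basic emotion, the set of blend shapes whose
AUs characterize it under EMFACS; build a *prototype* vector per emotion; and
classify new frames by cosine similarity to the prototypes. `arkemo`
implements that pipeline end to end — data model, preprocessing,
classification, evaluation — plus a seeded synthetic cohort generator that
emulates a posed-expression recording protocol, so the whole pipeline is
testable without human recordings.

## Data model

A **recording** is an ordered sequence of frames (times `t` in seconds, one
row of 52 coefficients per frame) with subject ID, target-expression label
and nominal frame rate (30 or 60 FPS). Raw coefficients must lie in [0, 1];
out-of-range values are rejected, not clamped, since silent clamping would
mask capture faults. A **cohort** is a set of uniquely identified recordings
with an optional human-rater label table. CSVs use one `t` column plus the 52
registry-named columns, written at full precision (timestamps coarser than a
millisecond are a known capture defect this format avoids); the canonical
column order follows the ARKit documentation, since capture apps do not agree
on one. The seven facial regions (jaw, eye, mouth, cheek, brow, nose, tongue)
are assigned by name prefix, which partitions the 52 names exactly.

## The EMFACS mapping

`emfacs_table()` encodes the emotion → blend shape table used throughout:
7 emotions, 25 distinct mapped blend shapes, 27 never used. Two deliberate
quirks are kept as printed in the underlying AU guide rather than "fixed":

* anger and fear both include `eyeSquint*` (AU7) *and* `eyeWide*` (AU5),
  although these are near-opposites;
* contempt is unilateral — either `mouthDimpleLeft` + `mouthSmileLeft` or the
  right-side mirror pair, never both.

At classification time the baseline scores contempt as the **maximum of the
two variant means**: this preserves the unilateral definition without
assuming a side. Users can override any emotion's set from a YAML/JSON config
(`load_mapping()`); overrides are validated against the registry. Exploratory
re-mappings are supported only through that config — data-driven re-derivation
of the mapping is out of scope, since it has not been shown to help.

## Preprocessing

1. **FPS harmonization.** 60 FPS recordings are downsampled to 30 by
   dropping every second frame, keeping even 0-based indices. No
   interpolation: frame dropping cannot create artifacts. The phase (start at
   frame 0) is a convention; the alternative phase differs by one frame and
   nothing downstream is sensitive to it.
2. **Subject-wise z-scoring.** `z = (x - mean) / sd` per subject per blend
   shape, with statistics fit over *all* of that subject's frames (all
   recordings pooled — the normalization is subject-specific, not
   recording-specific; a per-recording scope exists for sensitivity
   analysis). We use the population standard deviation (`ddof = 0`, switchable):
   the purpose is standardization, not inference. A blend shape with zero
   variance for a subject standardizes to 0, not NaN — a never-moving
   coefficient carries no directional signal and then contributes nothing to
   cosine similarity. No separate baseline-frame subtraction is applied:
   z-scoring already centers each subject at their own resting level, and the
   scale-free classifier uses only the direction of the standardized vector.
3. **Sustained-phase selection.** Frames before `neutral_cut_s` (default
   1.0 s — the protocol's approximate neutral hold; the exact boundary is a
   convention and configurable) are discarded, keeping ramp, apex and
   release.

The pipeline applies these in the order harmonize → z-score → phase-select,
so the statistics are fit on all harmonized frames including the neutral
segment; this matches fitting "over all of a subject's frames" and makes the
neutral level part of what standardization removes.

## Classification

The **prototype** for emotion *i* is the elementwise mean standardized
vector over all sustained-phase frames of all recordings labeled *i*. A frame
*v* is scored by `cosine(v, p_i) = v·p_i / (||v|| ||p_i||)` and assigned the
argmax. Choices that needed making:

* **Evaluation unit.** Frames are classified individually, but accuracy is
  reported per recording. Recording-level aggregation defaults to the argmax
  of the per-emotion *mean frame similarity* (`mean_score`); a majority
  `frame_vote` is provided. Both units are exposed since per-frame and
  per-expression reporting answer different questions.
* **Prototype fitting.** Default is leave-one-subject-out: the evaluated
  subject's frames are excluded from every prototype, so reported accuracy is
  an honest transfer estimate. `in_sample` mode (all recordings pooled) is
  provided to mirror the simplest construction, which does not state a
  held-out design; at desk scale the two differ noticeably, and we consider
  LOSO the defensible default.
* **Ties and zero vectors.** A zero standardized frame has no direction;
  its similarity is defined as 0 to every prototype, and any resulting tie is
  broken by the fixed canonical emotion order (anger, contempt, disgust,
  fear, joy, sadness, surprise) with an `ambiguous` flag. Determinism is
  preferred over arbitrary hash order.
* **Baseline.** The comparison method scores each emotion by the mean
  activation of its EMFACS-relevant blend shapes (mean over frames and over
  shapes), contempt by the variant maximum. It runs on the same standardized
  frames as the cosine method by default, with a raw-value mode, since mean
  activation is meaningful on either scale; the raw mode is what makes the
  baseline sensitive to global scale distortion, the property the cosine
  metric is chosen to avoid.

## Evaluation

Accuracy is exact counting, overall and conditioned on the true label.
Confusion matrices are reported row-normalized (rows = true labels). ROC/AUC
is one-vs-rest per emotion, with the recording-level mean cosine similarity
as the decision statistic (frame-level scores are available); AUC uses the
rank/Mann–Whitney formula with midrank tie handling. Inter-rater agreement is
Krippendorff's α at the nominal level over the coincidence matrix, tolerating
missing ratings; rater accuracy is computed against the instructed label,
which is the objective ground truth in this design. All four quantities are
verified in the test suite against independent brute-force implementations
(pairwise comparisons for AUC, explicit pair enumeration for α).

## The synthetic cohort generator

The generator emulates the posed-expression protocol: 5-second recordings at
30 or 60 FPS (subjects draw 60 FPS with probability 0.8067, the mixture the
protocol produced), a ~1 s neutral phase, a linear ramp to apex by 2 s, an
apex hold to 4 s, and a release to the end. Per emotion recording, the
signature blend shapes of the emotion activate with per-shape apex
amplitudes; contempt draws a side and activates only that unilateral variant.

The default parameters are fixed choices, not dials:

| parameter | default | what it emulates |
|---|---|---|
| `apex_amplitudes` | 0.8; near-1 for wide-range shapes (cheekPuff, blinks, tongueOut, upward gaze); ~0.5 for narrow ones; 0.45 for jawLeft | the qualitative per-shape activation ranges a TrueDepth capture shows |
| `amplitude_jitter` | 0.25 | attempt-to-attempt intensity variation |
| `expressiveness_sd` | 0.2 (log-normal) | global subject expressiveness |
| `style_sd` | 0.5 (log-normal, per subject × shape) | idiosyncratic expression style: subjects emphasize different components of the same expression |
| `dropout_p` | 0.25 | incomplete posed expressions: a signature shape simply not produced in an attempt |
| `baseline_scale` | 0.04 | small positive resting activations, removed by z-scoring by construction |
| `sigma_obs` | 0.05 | per-frame sensor noise |
| `bleed` | 0.25 | fear produced with attenuated fear-specific components, drifting toward surprise |
| `contempt_p_left` | 0.5 | no side preference |

Two structural rules shape the output. **Opposite-pair exclusivity**: for
each of the 12 opposite pairs, whenever both members are positive in a frame
the smaller is forced to 0 — except the `eyeWide`/`eyeSquint` pairs, which are
near- rather than strictly opposite and are allowed to co-activate
(`squint_wide_exception`). **Fear/surprise bleed**: the surprise signature is
a strict subset of fear's, so attenuating fear-specific shapes by `1 - bleed`
moves fear recordings toward surprise's direction; this is what reproduces,
qualitatively, fear's dominant confusion with surprise.

Amplitudes are not calibrated to any real dataset — the real recordings are
not publicly deposited — so absolute accuracies on synthetic cohorts are not
comparable to accuracies on human data. What the generator supports is
*property-level* validation: perfect separation when all stochastic
mechanisms are disabled, graceful degradation with noise, scale invariance,
confusion structure following signature overlap, and exact protocol counts
(31 subjects × 7 emotions = 217 recordings; 43 per subject with movements).
What it does **not** model: tracking cross-talk between unrelated
coefficients, head pose and occlusion effects, asymmetric non-contempt
expressions, temporal micro-dynamics within a phase, or mixed/ambiguous
affect. Passing tests on synthetic cohorts therefore demonstrate correctness
of the machinery, not field performance.

Randomness is governed by a single integer seed in the configuration;
cohorts are bit-reproducible. The seed is set once at cohort level and all
draws come from R's default generator stream in a fixed order.

## Numerical choices and degenerate inputs

* Cosine of a zero vector: 0 by definition (flagged ambiguous downstream).
* `sd = 0` blend shapes: standardized to 0.
* AUC for a class with no positives or no negatives: `NA`, reported missing.
* Spearman correlations for a constant region series: `NA`, reported
  missing; p-values use the asymptotic approximation.
* Activation in the overlap statistic means strictly `> 0` (an `eps`
  threshold exists for noisy captures, default 0); the denominator counts
  *all* frames, not only frames where either member is active.
* Out-of-range raw values and unknown blend shape names are hard errors
  naming the offending row or column.

## Problem sizes

The test suite and the reproduction script run cohorts of 31 subjects × 7
emotions (217 recordings, 150 sustained-phase-trimmed frames each after
harmonization), the scale of the emulated protocol; oracle-equivalence checks
use 1,000 randomized small instances per metric. These sizes keep full runs
in the tens of seconds on a laptop while leaving no component untested at
protocol scale.

## Known limitations

* The generator's emotion model is a single-envelope, signature-indicator
  model; it cannot produce compound or sequential expressions.
* LOSO prototypes for a cohort with very few subjects per emotion are noisy;
  at least ~4 subjects are advisable before accuracy numbers mean much.
* Krippendorff's α is implemented at nominal level only (labels are
  categorical); ordinal/interval metrics are out of scope.
* The mean-activation baseline's raw mode ignores FPS-dependent exposure
  differences; it is a comparison method, not a recommended classifier.
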