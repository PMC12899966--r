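# arkemo

Interpretable, training-free facial emotion recognition from ARKit-style
blend shape streams.

Face-tracking frameworks on commodity phones stream 52 *blend shape
coefficients* per frame — continuous activations in [0, 1] of named facial
movements (`jawOpen`, `browInnerUp`, `mouthSmileLeft`, ...) that map onto
FACS action units. `arkemo` is for researchers and app developers who want
to turn those per-frame vectors into discrete emotion labels without any
trained model: the classifier is a nearest-prototype rule under cosine
similarity, cheap enough for real time on-device and fully traceable to the
contributing blend shapes.

## The method

For subject *s*, every coefficient is standardized with that subject's own
statistics,

    z = (x − x̄_s) / σ_s ,

recordings are harmonized to 30 FPS (60 FPS streams drop every second
frame), and the initial ~1 s neutral segment is discarded. The prototype
**p**ᵢ of emotion *i* is the mean standardized vector over all
sustained-phase frames of all recordings of that emotion — guided by the
EMFACS mapping from action units to the seven basic emotions (anger,
contempt, disgust, fear, joy, sadness, surprise). A frame **v** is scored by

    cosine(v, pᵢ) = v · pᵢ / (‖v‖ ‖pᵢ‖)

and a recording takes the emotion with the highest mean frame similarity.
Prototypes are fit leave-one-subject-out by default, so no subject is scored
against prototypes containing their own frames. A mean-activation baseline
(average of each emotion's EMFACS-relevant blend shapes; contempt as the max
of its two unilateral variants) is included for comparison, along with
accuracy / row-normalized confusion / one-vs-rest ROC-AUC evaluation and
Krippendorff's α for human-rater tables.

Because no real blend shape corpus ships with the package, a seeded
synthetic cohort generator emulates the posed-expression protocol
(5 s recordings: neutral → ramp → apex hold → release; per-emotion signature
activation; subject-specific baseline, expressiveness and style; opposite-pair
exclusivity; observation noise), providing ground truth for every pipeline
stage. See `vignette("arkemo-methods")` for the model and all design choices.

## Worked example

```r
library(arkemo)

# a synthetic cohort at the emulated protocol's scale:
# 31 subjects x 7 emotions = 217 recordings
sim <- generate_cohort(generator_config(n_subjects = 31, seed = 42))

# harmonize -> z-score -> sustained phase -> LOSO prototypes -> classify
res <- run_pipeline(sim$cohort, method = "cosine")
res$report
#> <evaluation_report> cosine_mean_score, n=217
#>   overall accuracy: 98.16%
#>   per-emotion accuracy:
#>     anger     100.00%   AUC 0.997
#>     contempt   96.77%   AUC 0.989
#>     disgust   100.00%   AUC 0.999
#>     fear       93.55%   AUC 0.997
#>     joy        96.77%   AUC 0.999
#>     sadness   100.00%   AUC 0.992
#>     surprise  100.00%   AUC 0.986

round(res$report$confusion["fear", ], 3)
#>    anger contempt  disgust     fear      joy  sadness surprise
#>    0.000    0.000    0.000    0.935    0.000    0.000    0.065
```

The report prints recording-level accuracy per emotion and the one-vs-rest
AUC using each emotion's mean cosine similarity as the decision statistic.
The fear row of the confusion matrix shows the characteristic error
structure: the surprise signature is a strict subset of fear's, so fear's
misclassifications land on surprise. On the same cohort the mean-activation
baseline reaches 89.86% — below the cosine classifier, whose scale-free
similarity is what copes with subject-specific expressiveness.

On real captures, replace the generator with `read_cohort("manifest.csv")`
pointing at per-recording CSVs (a `t` column plus the 52 blend shape
columns). A command-line interface covers the same flow:

```sh
Rscript inst/cli/arkemo simulate --out cohort/ --seed 7
Rscript inst/cli/arkemo run --manifest cohort/manifest.csv --out results/
Rscript inst/cli/arkemo describe --manifest cohort/manifest.csv --out tables/
```

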