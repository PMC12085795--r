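---
title: "Bone age assessment via entropy-selected regions of interest: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone age assessment via entropy-selected regions of interest: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(skelage)
```

## The problem

Bone age ("skeletal age") expresses a child's skeletal maturity as the
chronological age at which reference children reach the same radiographic
maturation of the hand and wrist. Discrepancies between bone age and
chronological age inform the diagnosis of growth and endocrine disorders.
Visual atlas matching (Greulich–Pyle) is the clinical standard but is slow
and reader-dependent, which motivates automated estimation from left-hand
radiographs.

`skelage` implements a *region-of-interest* (ROI) approach rather than a
whole-image convolutional model. The premise is that a hand radiograph of
more than 240,000 pixels carries its age-relevant information — ossification
centres, epiphyseal gaps, trabecular texture — in a handful of small,
detail-rich patches. Restricting learning to those patches makes the
downstream regressor tiny and the pipeline interpretable: the selected
patches can be displayed and audited.

## Pipeline

1. **ROI selection.** Per image, `k = 13` square patches ("clicks") of
   40×40 pixels (defaults; both configurable) are placed where the *local
   Shannon entropy* is maximal. For a patch with 256-bin gray-level
   histogram frequencies $p_i$,
   $$H = -\sum_{i=0}^{255} p_i \log_2 p_i \in [0, 8]\ \text{bits},$$
   with $0 \log 0 = 0$. High-entropy patches are the textured,
   informative parts of the radiograph; the dark background scores near 0.
   Placement is a joint optimization over all $k$ patches by a genetic
   algorithm (`ga_select_rois()`), validated against an exhaustive greedy
   reference (`brute_force_rois()`).
2. **Feature extraction.** A fixed bank of 7 small kernels (horizontal and
   vertical first differences, 4-neighbour Laplacian, four Sobel-type
   orientation-selective edge kernels at 0°/45°/90°/135°) is applied to
   each patch; each response is summarized by mean absolute value,
   standard deviation and energy (mean square). With the patch mean gray
   level and patch entropy appended, every ROI becomes one 23-dimensional
   "detail vector" labelled with the source subject's reference age and
   sex.
3. **Regression.** Subjects are split 70/15/15 into train/test/validation,
   stratified by sex and 3-year age band. One two-layer perceptron
   (one hidden layer) per sex regresses age from ROI-level detail vectors;
   a subject's bone age is the mean (optionally median) of its $k$
   ROI-level estimates, clipped to the cohort support [1, 18] years.
4. **Evaluation.** Per sex, on the validation partition: MSE and RMSE,
   MAE, Pearson $r$ with its $t$-based $p$-value, the intraclass
   correlation coefficient, Bland–Altman 95% limits of agreement, and the
   raw error range, all at subject level with differences oriented
   predicted − reference.

## ROI selection in detail

`entropy_map()` computes the entropy of every candidate patch position
with a sliding 256-bin histogram (compiled code; cost roughly linear in
pixel count rather than quadratic in patch size).

The greedy reference repeatedly takes the highest-entropy position whose
Euclidean center distance to all already-selected patches is at least
`min_separation` (default `patch_size / 2`), breaking exact ties by (row,
col). It is deterministic and, while not a certificate of the joint
optimum (which is combinatorially out of reach for $k = 13$), it is a
strong upper reference in practice: with many near-equally textured
positions, the GA rarely matches and never exceeded it in our property
tests.

The GA encodes a candidate solution as the concatenation of $k$ (row,
col) top-left corners. Fitness is the sum of the $k$ entropies minus a
penalty of twice the map maximum per violated separation pair, so any
infeasible set ranks below comparable feasible ones. Defaults: population
60, 80 generations, tournament selection of size 3, one-point crossover
with probability 0.8, per-coordinate mutation with probability 0.1 and
uniform jitter of up to ±10 px, elitism 2. One deterministic, evenly
spaced individual is injected into the initial population so a feasible
candidate exists from generation 0; the best feasible individual ever
seen is returned. All randomness flows from `ga_params()$seed`.

A minimum separation is enforced because $k$ coincident patches carry no
more information than one; half a patch side forces the set to spread
over distinct structures while still allowing partial overlap.
Coordinates are 1-based (row, col) top-left corners throughout — the
natural indexing for R matrices — and patches span
`[r, r + s - 1] × [c, c + s - 1]`.

## The filter bank

The bank is deliberately *fixed* (no learning) and versioned
(`skelage-bank-v1`): detail vectors must be comparable across cohorts and
reruns. The choice of kernels is a standard texture/edge descriptor set;
alternatives can be swapped in programmatically since every function
takes the bank as an argument. Convolution inside a patch uses
edge-replicating padding — for the 3×3 and 2×1 kernels used here this
avoids the spurious border responses zero-padding would create in a
40×40 patch. Responses are summarized kernel-major, stat-minor, giving a
fixed 23-long vector; features are stored raw, and all standardization
happens inside the model stage with training-partition statistics only,
so no information leaks from test or validation data into the features.

## The regressor

"Two-layer perceptron" is read as two weight layers: input → hidden
(32 tanh units by default) → linear output. Per sex, features and target
are z-scored with train-partition statistics, and training minimizes the
ROI-level squared error by plain mini-batch gradient descent (batch 32,
learning rate 5·10⁻³, at most 1000 epochs). The earlier defaults of
learning rate 10⁻³ and 500 epochs demonstrably underfit this
architecture — training error was still falling when the budget ran
out — so the shipped defaults are the smallest settings at which plain
gradient descent reliably converges on cohorts of a few hundred
subjects. Early stopping monitors the loss on the *test* partition
(patience 60, best-weights restore); the *validation* partition is
reserved exclusively for final reporting. Weight initialization, batch
shuffling and hence the trained weights are bit-reproducible given the
`mlp_spec()$seed`.

Splitting is *subject-level*: all $k$ rows of one subject share one
partition. Row-level splitting would place rows of the same subject
(which share a label and an image) on both sides of the train/validation
boundary and overstate performance. Partition quotas per sex follow the
largest-remainder rule (so a 20-subject stratum yields exactly 14/3/3),
and subjects are spread over partitions proportionally within each age
band.

Predictions are clipped to [1, 18] years, the support of the cohort
definition; the mean aggregator is the default since ROI-level errors at
zero noise are approximately symmetric, with the median available for
robustness against an occasional off-structure ROI.

## Agreement metrics

ICC defaults to the two-way random-effects, absolute-agreement,
single-measure form ICC(2,1), computed from the two-way ANOVA mean
squares of the $n × 2$ (reference, predicted) table:
$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + MS_E + \tfrac{2}{n}(MS_C - MS_E)}.$$
Absolute agreement is the appropriate notion when the question is
whether predictions can *replace* the reference reading — a constant
bias should (and does) lower it, unlike Pearson $r$. The consistency
form ICC(3,1) is available as an option.

Limits of agreement use the fixed normal multiplier 1.96 (configurable)
rather than a $t$ quantile, with the $n-1$ standard deviation. Both MSE
(years²) and RMSE (years) are reported: a single "MSE in years" figure
is ambiguous between the two conventions, so the report always carries
both explicitly.

Degenerate partitions do not abort a report: metrics whose preconditions
fail (e.g. $r$ and ICC need $n \ge 3$) are reported as `NA` with a note,
while the remaining metrics are computed.

## The synthetic cohort generator

No public dataset exists for this pipeline's input modality, so
`generate_cohort()` emulates it. Each image is built from an *effective
maturity* $m = \mathrm{age} - \mathrm{lag} \cdot [\mathrm{sex = male}]$,
with the male maturation lag defaulting to 1.25 years (midpoint of the
12–18 month developmental lag reported for boys). Three texture channels
are monotone in $m$:

* **blob count** — $3 + \lfloor 0.8 m \rfloor$ bright elliptical
  "ossification centres" on a dark, nearly flat background;
* **edge sharpness** — the logistic edge width of each blob shrinks
  gently with $m$;
* **texture amplitude** — inside blobs, a blend of a per-image uniform
  speckle field (60%) and per-blob sinusoidal gratings (40%) scaled by
  $6 + 2.2 m$ gray levels. The uniform component is what makes the
  quantized patch entropy grow smoothly (approximately logarithmically)
  in $m$; a pure sinusoid's bimodal histogram does not.

The interior brightness $90 + 6.5 m$ adds a mean-gray cue. All random
draws (blob geometry, speckle, phases, pixel noise) have sizes
independent of $m$ and flow from one per-image seed, so images with
equal $(m, \mathrm{seed})$ are pixel-identical — in particular a boy and
a girl whose ages differ by exactly the lag. `noise_level` $\in [0,1]$
adds Gaussian pixel noise (sd $25 \cdot$ `noise_level` gray levels) and,
more importantly, a maturity *rendering jitter* (sd $1.5 \cdot$
`noise_level` years) that decouples the texture from the recorded label
the way biological variation decouples skeletal from chronological
maturation. The effective maturity is not floored at zero: lagged young
boys render at slightly negative $m$ (the mapping stays valid to
$m = -2$), because flooring would make all boys below age
$1 + \mathrm{lag}$ pixel-indistinguishable and hence unlearnable.

Ages are sampled either uniformly on [1, 18] or, by default, from the
per-sex age-band table of the emulated cohort (`age_band_weights()`),
with uniform sampling inside each band clipped to [1, 18]. Default
cohort structure is 220 boys and 335 girls; default images are 512×512
(262,144 pixels).

**What passing tests do and do not show.** The generator provides a
ground truth with a known, monotone, low-dimensional maturity-to-texture
mapping. Recovery of that mapping demonstrates that ROI selection finds
the informative regions, that the detail vectors carry the signal, and
that the per-sex regressors and the metric battery are implemented
correctly end-to-end. It does not demonstrate clinical accuracy: real
radiographs encode maturity in anatomically structured, high-dimensional
ways (carpal ossification sequences, physeal fusion) that no blob model
reproduces, and real reference readings carry inter-reader noise.
Performance numbers on synthetic cohorts are therefore statements about
the software, not about bone age assessment in children.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on
64×64-pixel images with 8×8 patches (minimum separation 4 px), k = 13
ROIs, and cohorts of up to 300 subjects per sex — sizes chosen so a
complete run takes minutes on one CPU while every stage still operates
far from degeneracy (3,249 candidate positions per image, thousands of
detail vectors per sex). The emulated-cohort structure check uses the
full 555 subjects. Entropy ties in greedy selection are broken by (row,
col) order; GA fitness penalties are scaled to twice the entropy-map
maximum; feature standardization guards zero-variance columns (scale 1);
constant training targets short-circuit to y-scale 1 so the regressor
returns the constant. Model files are JSON with a magic tag and format
version, written at full precision so a save/load round trip changes
predictions by less than 10⁻⁹ years.

## Configuration and reproducibility

The pipeline reads a single YAML file with blocks `data`, `roi`,
`features`, `model`, `eval` plus a global `seed` and `out_dir`; unknown
keys are rejected by name. Per-stage seeds are derived from the global
seed by fixed offsets, and each run records the config's MD5 hash and
the package version. Two runs with one seed produce byte-identical
manifests, images, ROI tables, feature tables, model files and reports.

## Known limitations

* The blob generator makes no attempt at anatomical realism (no carpal
  layout, no physes, no pathology); see above for what that implies.
* The greedy ROI reference is not a global joint optimizer; GA quality
  is assessed relative to it, not to the true optimum.
* The regressor is intentionally small; no hyperparameter search or
  deep architectures are provided.
* Only 8-bit single-channel PNG/TIFF input is supported — no DICOM.
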