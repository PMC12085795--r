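# skelage

Automated bone age (skeletal age) assessment from 8-bit grayscale
hand-radiograph-like images, for researchers building or auditing
region-of-interest pipelines for pediatric skeletal maturity.

Instead of feeding whole radiographs to a convolutional network, the
pipeline selects, per image, the k small square patches ("clicks") with
maximal **local Shannon entropy**

> H = −Σᵢ pᵢ log₂ pᵢ,  i = 0…255,

where pᵢ are the patch's gray-level histogram frequencies — these are the
detail-rich regions (ossification centres, physes) that carry the age
signal. Patch placement is a joint optimization by a **genetic algorithm**
(with an exhaustive greedy reference implementation for verification). A
fixed bank of edge/texture filters turns each patch into a 23-dimensional
detail vector; one small **two-layer perceptron per sex** regresses bone
age in years from the vectors (70/15/15 subject-level split, early
stopping on the test partition); a subject's estimate is the mean of its
k ROI-level predictions. Agreement with the reference standard is
quantified per sex by MSE/RMSE, MAE, Pearson r, the intraclass
correlation coefficient **ICC(2,1)**, Bland–Altman **95% limits of
agreement**, and the error range.

Because no public dataset exists for this modality, the package ships a
synthetic radiograph generator whose texture (blob count, edge
sharpness, texture amplitude) monotonically encodes a known bone age,
with a sex-dependent maturation lag and the emulated cohort's
demographic structure (220 boys / 335 girls, ages 1–18). Every stage is
testable against that ground truth; see `vignettes/skelage-methods.Rmd`
for what such tests do and do not demonstrate.

## Worked example

```r
library(skelage)

cfg <- default_config()
cfg$seed <- 42L
cfg$out_dir <- file.path(tempdir(), "demo")
cfg$data <- modifyList(cfg$data, list(n_male = 40L, n_female = 40L,
  image_height = 64L, image_width = 64L, noise_level = 0.2))
cfg$roi <- modifyList(cfg$roi, list(patch_size = 8L, k = 13L,
  min_separation = 4))

report <- run_pipeline(cfg)
#> [skelage] simulate     done in 1.3 s
#> [skelage] select-rois  done in 63.1 s
#> [skelage] featurize    done in 2.7 s
#> [skelage] train        done in 3.7 s
#> [skelage] evaluate     done in 0.3 s
print(report)
#> eval_report on 'validation' partition (icc2_1)
#>   M (n=6): MSE 0.451  RMSE 0.672  MAE 0.650  r 0.993  ICC 0.992  LoA [-1.16, 1.58]  range [-0.76, 0.81]
#>   F (n=6): MSE 0.348  RMSE 0.590  MAE 0.504  r 0.991  ICC 0.988  LoA [-1.17, 1.34]  range [-1.06, 0.71]
```

This simulates an 80-subject cohort of 64×64 px images at moderate
noise, places 13 ROIs per image with the genetic algorithm, extracts
detail vectors, trains one perceptron per sex, and evaluates on the
held-out validation subjects. The printed rows are the per-sex agreement
battery: errors in years (MSE in years²), correlation and ICC
dimensionless, and the 95% limits of agreement bracketing the mean
difference between predicted and reference age. On such a small
validation split (n = 6 per sex) the numbers fluctuate; the test suite
uses 300 subjects per sex.

Intermediate artifacts land in `cfg$out_dir`: `manifest.csv`, `images/`,
`rois.csv`, `features.csv`, `split.csv`, `model_M.json`,
`model_F.json`, and `report/` (JSON, CSV, scatter and paired-bars PNGs).
Each stage can be rerun individually (`stage_simulate()`,
`stage_select_rois()`, …) from the previous stage's files, and
`inst/cli/skelage.R` exposes the same stages as shell subcommands
(`simulate`, `select-rois`, `featurize`, `train`, `evaluate`, `predict`,
`run-all`).

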