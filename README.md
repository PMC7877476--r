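# decodelight

Searchlight decoding of fMRI beta series with expertise correlation mapping.

## The problem this package addresses

Domain expertise reshapes how the brain represents domain stimuli. A direct
way to localize that reshaping is to ask, at every brain location, two
questions: *can a stimulus distinction be decoded from the local multivoxel
pattern?* and *does that decodability track how good the person is at the
task?* Regions that answer yes to the first but no to the second (early
visual cortex, which sees the same pixels in everyone) dissociate from
regions that answer yes to both — candidate neural substrates of expertise.
The motivating study scanned programmers of widely varying skill while they
categorized source-code snippets, and found exactly this dissociation.

`decodelight` implements the complete analysis chain in R, for
methodologists and instructors who want a tested, desk-scale, fully
reproducible version of this workflow:

- **trial-wise GLM** (least-squares-all): one HRF-convolved regressor per
  trial plus motion, discrete-cosine drift (128 s cutoff) and constant
  columns; OLS per voxel yields a 216-volume beta series per subject;
- **searchlight decoding**: a sphere (radius 4 = 251 voxels; strict-radius
  convention) scans the mask; at each center a linear-kernel SVM is evaluated
  by leave-one-run-out cross-validation with train-only z-scaling, [−3, 3]
  outlier clipping, nested cost selection over {0.1, 1, 10}, and
  inverse-frequency class weights for imbalanced labels; chance is
  frequency-proportional guessing, `Σ pᵢ²` (25% for 4 balanced categories,
  9.72% for the 11-subcategory distribution);
- **group inference**: 6 mm FWHM smoothing, then accuracy > chance at
  voxel-level FWE 0.05 (sign-flip max-statistic permutation), accuracy ×
  behavior Pearson correlation at cluster-forming p < 0.001 with
  cluster-level FWE 0.05 (score-permutation max extent, 18-connectivity),
  and the conjunction of the two significance maps;
- **synthetic cohort generator** with planted ground truth (regions that are
  informative and expertise-coupled, informative but uncoupled, or null), so
  the whole pipeline is validated by parameter recovery and error-control
  simulations.

## Worked example

```r
library(decodelight)

scheme   <- category_scheme()            # 4 categories x 18; 11 subcategories
stimuli  <- build_stimulus_set(scheme)   # 72 stimuli
schedule <- make_schedule(stimuli, seed = 7)   # 6 runs x 36 trials, balanced
run_duration_seconds(schedule)
#> [1] 592

geometry <- volume_geometry()            # 20 x 24 x 20 grid, 2 mm voxels
regions  <- default_regions(geometry)    # frontal/temporal/visual/null truth
bank     <- build_pattern_bank(geometry, regions, scheme, seed = 3)
betas    <- render_beta_series(0.8, schedule, bank, geometry, regions,
                               seed = 11)  # expert-level subject
nrow(betas$data)
#> [1] 216

feat <- extract_features(betas, regions$frontal_like$voxels[14, ],
                         sphere_offsets(2))
cv_accuracy(feat, betas$trials$category, betas$trials$run,
            decoding_config())
#> Leave-one-run-out decoding: accuracy 0.468 (chance 0.250, 216 trials, 6 folds)
```

The decoding accuracy (0.468 against a 0.25 chance) is what the searchlight
writes into this subject's map at that center; across subjects, these values
are smoothed, tested against chance, and correlated with behavioral
performance. For a subject with low expertise (0.45) the same frontal-like
center gives 0.380 — the coupled region carries more pattern information as
expertise grows — while the visual-like region decodes equally well in
everyone and the null region stays at chance.

The `analysis/` directory holds the full narrative workflow as numbered
scripts (design/behavior → GLM → searchlight demo → 12-subject group
inference → figures); each writes its tables under `results/`.

## Package layout

- `R/design.R` — stimulus hierarchy, balanced scheduling, events TSV
- `R/cohort.R` — geometry, regions, expertise sampling, behavior, pattern
  bank, beta/BOLD renderers
- `R/glm.R` — HRF, DCT drift basis, design matrices, per-run OLS
- `R/searchlight.R`, `R/decoding.R` — sphere geometry, feature extraction,
  scaling/clipping, nested-CV SVM, whole-brain maps
- `R/group.R` — smoothing, t/r maps, permutation FWE, clusters, conjunction
- `R/behavior.R` — performance scoring, exact correlation tests
- `R/recovery.R`, `R/pipeline.R` — recovery harness and end-to-end runner
- `vignettes/searchlight-expertise-decoding.Rmd` — models, assumptions,
  parameter choices, limitations
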