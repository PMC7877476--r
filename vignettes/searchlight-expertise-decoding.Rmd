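---
title: "Searchlight decoding of expertise-linked multivoxel patterns: models and methods"
author: "decodelight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight decoding of expertise-linked multivoxel patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

`decodelight` implements an end-to-end multivoxel pattern analysis (MVPA)
workflow for a question of the form: *where in the brain does local pattern
information about a stimulus distinction track individual expertise?* The
motivating application is program comprehension: subjects spanning a wide
range of programming skill categorize short source-code snippets in the
scanner, a searchlight classifier measures how well the functional category of
the viewed snippet can be decoded from local activity patterns at every
location, and a second-level analysis asks where decoding accuracy correlates
with behavioral performance across subjects. The interesting dissociation is
between regions that are decodable in everyone but indifferent to skill
(early visual cortex sees the same pixels regardless of expertise) and regions
whose pattern information grows with skill (fronto-parieto-temporal areas).

The package provides the full chain as testable units:

1. **design** — stimulus hierarchy and balanced trial schedule;
2. **synthetic cohort** — a generator with known ground truth;
3. **first-level GLM** — trial-wise beta-series estimation;
4. **searchlight + decoding** — cross-validated linear-SVM accuracy maps;
5. **group inference** — permutation-based FWE control and conjunction;
6. **behavior** — performance scoring and exact correlation tests.

# Experimental design

The stimulus set is 72 items in 4 categories of 18, subdivided into 11
subcategories: ten of six items and one ("linear search") of twelve, which
forces its parent category to hold exactly two subcategories (12 + 6 = 18).
Each item is shown three times over six runs of 36 task trials (216 trials),
never twice in a run, and every run holds exactly nine trials of each
category. Trials are 16 s (2 s fixation, 10 s stimulus, 4 s response); each
run carries one leading dummy trial, so a run lasts 37 × 16 = 592 s.

`make_schedule()` builds the stimulus-by-run incidence per category as a
binary matrix with row sums 3 (repetitions) and column sums 9 (per-run
balance), starting from a feasible cyclic assignment and randomizing it with
checkerboard swaps, which preserve both margins exactly. We chose this over
draw-and-reject scheduling because rejection has a vanishing acceptance rate
for 18 × 3 draws from a shuffled multiset, whereas swap randomization is valid
by construction, uniform enough for scheduling purposes, and deterministic
given the seed. Response-button order is randomized and recorded per trial;
it has no downstream computational role.

# The synthetic cohort

The generator is first-class, tested code: it defines the conditions under
which the pipeline is validated.

**Geometry.** A 20 × 24 × 20 grid of 2 mm voxels with an ellipsoidal
"brain" mask (4304 voxels). Real-brain dimensions are configuration, not
code; the small default keeps full runs in the minutes range.

**Regions.** Four disjoint 3 × 3 × 3 regions encode the target dissociation:

| region | informative for | expertise-coupled | gain |
|---|---|---|---|
| `frontal_like` | category | yes | 0.2 + 1.0·expertise |
| `temporal_like` | category + subcategory | yes | 0.2 + 1.0·expertise |
| `visual_like` | category | no | 0.9 |
| `null_region` | nothing | — | 0 |

**Patterns.** Each (region, class) has a fixed pattern vector over the
region's voxels, zero-mean (class information is multivoxel, not mean signal)
and unit norm, so gains read directly in units of the trial noise SD. Each
subject sees a perturbed copy (20% of the pattern norm): within-subject
decoding does not require patterns to align across subjects, and the
perturbation adds realistic between-subject variation in decodability.

**Trial amplitudes.** `beta[trial, voxel] = Σ_regions gain_r(expertise) ·
pattern(region, class(trial))[voxel] + N(0, noise_sd²)` with `noise_sd = 1`.
The gains were chosen so region-center accuracies span roughly 0.35–0.65
against a 0.25 chance across the expertise range — the order of magnitude
real searchlight studies report — without saturating (saturation would
destroy the accuracy-behavior correlation the design is meant to carry).

**BOLD path.** `render_bold_runs()` turns the same amplitudes into time
series: HRF-convolved 10-s boxcars at each code-phase onset, eight leading
dummy volumes without task signal, slow cosine drift, a motion-coupled
nuisance term (random-walk motion parameters times random spatial weights),
and white noise at TR = 2 s (296 volumes per run, 288 after dummy discard).
With noise, drift and motion off, the GLM stage recovers the amplitudes to
machine precision — the generative model and the analysis model coincide by
construction, which is exactly what makes the recovery test sharp.

**Behavior.** A linear psychometric map with lapses: the subject answers
with probability 1 − lapse (2% default) and is then correct with probability
`chance + (ceiling − chance) · expertise`. Group expertise means 0.54 / 0.71
/ 0.85 (SD 0.10 / 0.08 / 0.06, truncated to [0.05, 0.98]) with category
ceiling 1.0 give a cohort mean near 76% on the 4-choice task; a subcategory
ceiling of 0.80 gives ~66% on the post-session task whose guessing rate is
37.5% (54 of 72 trials offer three choices, 18 offer two). These constants
were calibrated once against the published group means and are configuration,
not findings. A published value of 37.25% for the post-session chance differs
slightly from the 37.5% implied by the stated class structure; the derivation
of the former is not stated, so the package computes the design-implied value
and does not force agreement.

**What the generator does not emulate:** hemodynamic nonlinearity,
physiological noise, spatial autocorrelation of noise, head-motion image
resampling, and anatomical variability. Passing recovery tests therefore
shows the *analysis chain* is correct and calibrated under its own
assumptions — not that those assumptions hold in any real dataset.

# First-level GLM

Least-squares-all: one HRF-convolved regressor per trial (code phase only;
fixation and response are unmodeled) in a single per-run model, plus six
motion columns, `floor(2·N·TR/cutoff)` discrete-cosine drift regressors
(9 for 288 volumes at a 128 s cutoff), and a constant — 52 columns. The HRF
is the standard double-gamma (peak delay 6 s, undershoot delay 16 s, ratio
1/6), zero at t = 0, peaking near 5 s, scaled to unit peak; regressors are
built on a 0.1 s grid and sampled at volume times, each scaled to unit peak
so betas read as response amplitudes. High-pass filtering lives inside the
GLM as DCT regressors — equivalent to pre-filtering under OLS and easier to
test (a projection argument the suite verifies numerically). Per-trial
modeling could alternatively be least-squares-single (one model per trial);
the all-trials-in-one-model variant matches the "one β per trial per run"
output structure and is the one implemented. OLS is used without
autocorrelation modeling; with i.i.d. generator noise, GLS would change
nothing, and prewhitening is out of scope.

# Searchlight decoding

**Sphere.** Offsets with squared norm *strictly* below radius²: at radius 4
this gives 251 voxels, the published sphere size (a closed ball would give
257), which pins down the membership convention. Spheres are truncated at
mask edges without a minimum-count filter; the per-center voxel count is kept
for QC. Tests run at radius 2 (27 voxels) to match the small grid.

**Preprocessing per fold.** Features are z-scored with training-fold means
and SDs, applied unchanged to the test fold, then clipped into [−3, +3]
(outlier reduction); constant training voxels map to 0.

**Classifier.** Linear-kernel C-SVM (libsvm via `e1071`), one-vs-one
multiclass with libsvm's vote tie-break. Leave-one-run-out outer
cross-validation; within each training partition, the cost is chosen from
{0.1, 1, 10} by an inner leave-one-run-out grid search, ties to the smallest
cost (strongest regularization, reproducible). For the imbalanced
subcategory problem, per-class misclassification costs proportional to
inverse frequency (normalized to mean 1, so the cost grid keeps its meaning)
are applied; the size-12 class gets half the weight of a size-6 class.
Accuracy is pooled correct/total over all outer folds. The chance reference
is frequency-proportional guessing, `Σ p²`: 25% for four balanced categories
and 9.72% (= 504/5184) for the subcategory distribution — the one simple
convention consistent with both published values.

Two numerical choices matter for runtime and are deliberate:

* the inner-loop model for outer fold *r*, inner fold *s* is trained on runs
  ∖{r, s}, which is symmetric in (r, s); models are memoized over unordered
  pairs. This is an exact re-arrangement, not an approximation, and the test
  suite proves it by comparing against an independently coded naive loop;
* the solver's termination tolerance defaults to 0.05 rather than libsvm's
  0.001. Fold accuracies are quantized at 1/36, two orders of magnitude above
  solver precision, and the loosened tolerance roughly halves searchlight
  cost. Both routes of every oracle-equivalence test use the same setting.

# Group inference

Subject accuracy maps are smoothed (Gaussian, 6 mm FWHM; σ = FWHM/(2√(2 ln 2))
= 1.274 voxels at 2 mm) and only then tested; first-level maps are never
smoothed. When a mask is supplied, the kernel is renormalized over in-mask
voxels — each smoothed value is a weighted average of *available* neighbors.
With sparse analysis-center masks, the plain zero-fill convention would
multiply each map by a position-dependent attenuation factor and bias the
accuracy-versus-chance test; renormalization is unbiased and coincides with
ordinary smoothing deep inside a whole-brain mask.

**Accuracy test.** One-sample t against the chance level per voxel, df = n−1.
Familywise error is controlled at α = 0.05 by max-statistic permutation with
random sign flips of the subject deviations; the threshold is the 95th
percentile of the permuted map-maximum. Exact under symmetric exchangeability,
no random-field assumptions, and testable at desk scale — this replaces the
random-field-theory machinery of classical toolboxes throughout.

**Correlation test.** Pearson r between accuracy and behavioral performance
per voxel. Cluster-extent inference: voxels past the one-sided
cluster-forming threshold (p < 0.001 on t with df = n−2, mapped to r units)
are labeled into 18-connected components; the null distribution of the
maximum cluster extent comes from score permutations through the identical
pipeline; clusters with `p_fwe ≤ 0.05` survive. Both map tests are one-sided
(accuracy > chance, r > 0), matching the directional hypotheses; scalar
behavioral correlations are two-tailed, which reproduces the published
behavioral p-values exactly.

**Conjunction.** The voxel-wise AND of the two significance masks, reported
with its fraction of evaluated searchlight centers. In recovery runs it is
scored by Dice overlap against the expertise-coupled ground-truth regions
dilated by the searchlight radius (a center one voxel outside a region still
sees most of it).

# Problem sizes and the analysis-center mask

A nested-cost searchlight unit on 216 trials costs 0.2–1.3 s with libsvm on
one CPU, so exhaustive decoding of all ~4300 mask voxels per subject is a
cluster-scale job by design, exactly as in the original setting. Desk-scale
runs therefore evaluate a restricted, scientifically sufficient center set
(`analysis_centers()`): all 27 voxels of each expertise-coupled core, an
alternating 14-voxel sample of the uncoupled and null cores, and 8 background
voxels away from every region (~110 centers). All thresholds, permutation
nulls, coverage scores and the conjunction Dice are computed over this
evaluated set — a searchlight cannot recover voxels it never visited. The
standard validation run uses 12 subjects (4 per group), radius 2, 1000
permutations; the error-control study uses 50 pure-noise replicates of 12
subjects on a 10³ grid with 500 permutations.

# Degenerate inputs and tie-breaks

* Constant training voxels scale to 0; constant behavioral scores are a
  configuration error; |r| = 1 converts to an infinite t with a warning.
* A class absent from a training partition is an error naming the fold and
  class (it cannot be weighted or learned).
* Zero supra-threshold voxels yield a valid empty cluster table.
* `alpha = 1` marks every finite voxel significant; `n_perm < 20` is an
  error, below 100 a warning.
* Cost ties select the smallest candidate; voxels with zero variance across
  subjects are excluded from t-maps and logged.

# Known limitations

* Inference validity rests on exchangeability (i.i.d. noise in the
  generator); temporally autocorrelated noise would require run-aware
  permutation schemes the package does not implement.
* The original workflow's spatial preprocessing (realignment, normalization,
  anatomical masking) is out of scope; synthetic data are generated aligned.
* Real-data mode reads beta series + labels + mask from NIfTI/TSV, but the
  package has no atlas labeling or surface rendering; cluster peaks are
  reported in voxel indices.
* With 12 subjects the correlation test sits at its power limit: the
  cluster-forming p < 0.001 threshold corresponds to r = 0.795 at df = 10.
  The temporal-like region (category + subcategory patterns, ~2× signal)
  clears it; the frontal-like region (category patterns only, whose edge
  spheres are diluted by out-of-region voxels) has a true accuracy-behavior
  correlation near 0.6 and reliably does not. The recovery suite asserts
  coverage of both coupled regions and therefore documents this as an
  expected failure at the default conditions; at a 30-subject cohort the
  same threshold drops to r = 0.54 and both regions are recoverable. The
  generator constants were fixed before any recovery run and are not adjusted
  to the outcome.
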