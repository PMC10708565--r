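---
title: "Methods: calibration transfer and hybrid modelling for two-form NIR spectra"
author: "spectransfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibration transfer and hybrid modelling for two-form NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Total viable count (TVC, log10 CFU/g) in cooked meat can be predicted from
near-infrared diffuse reflectance, but the prediction degrades badly on
intact ("full", FS) samples: their uneven surfaces scatter light much less
reproducibly than crushed ("CS") material. A model trained on crushed
spectra is accurate but destructive to apply; a model trained on full
spectra is non-destructive but unreliable. The workflow implemented here
keeps the crushed model and *transfers* full-form spectra into its space
with direct standardization (DS), optionally augmenting the crushed
calibration set with transferred full-form spectra (a hybrid model).

## The pipeline

1. **Reflectance calibration** (`calibrate_reflectance`). Raw counts become
   percent reflectance via `R = (raw - dark) / (white - dark) * 100`.
   Pixels with `white - dark <= 0` are flagged invalid (`NaN`), and
   reflectance is *not* clamped to [0, 100]: the next stage is affine-
   invariant, and clamping would destroy that.
2. **ROI extraction** (`build_roi_mask`, `roi_mean_spectrum`). The sample
   edge is specular and uneven, so the region of interest is the foreground
   *eroded* by a 2 mm margin (square structuring element; `px_per_mm` is
   instrument-specific and must be supplied). Replicate scans are averaged
   after ROI extraction - a mean of means, matching per-scan acquisition.
3. **Multiplicative scatter correction** (`msc_fit`, `msc_apply`). Each
   spectrum is regressed on the calibration-set mean spectrum and the
   fitted affine map inverted. The reference is frozen at fit time: new
   spectra are corrected against the *calibration* mean, never their own,
   which prevents information leakage into prediction sets. MSC is fitted
   per physical form, since the two forms have systematically different
   scatter.
4. **CARS wavelength screening** (`cars_run`). See below.
5. **Union of variable sets** (`merge_variable_sets`). The CS-screened and
   FS-screened wavelength sets are pooled (set union, each wavelength kept
   once) so both models and the transfer operate on one grid.
6. **4:1 split** (`random_split`), seeded, calibration never smaller than
   prediction.
7. **Standard samples** (`ks_select`, `spxy_select`,
   `pair_standard_sets`). Kennard-Stone is greedy max-min selection on
   Euclidean spectral distance; SPXY uses the joint distance
   `d_x/max(d_x) + d_y/max(d_y)`. Whatever form supplies the distances,
   the *same* sample ids are taken from both forms, row-aligned - the
   standards must be measured in both conditions.
8. **DS transfer** (`compute_transfer`, `apply_transfer`). The band-to-band
   matrix `F` solves `Sms = Sss F` on column-centered standards, via a
   truncated-SVD pseudoinverse of `Sss`.
9. **epsilon-SVR models and metrics** (`train_svr`, `metrics_report`),
   **hybrid sweeps** (`build_hybrid`, `hybrid_sweep`).

`transfer_experiment()` runs all of this in memory; `run_pipeline()` is the
file-based equivalent used by the CLI (`inst/cli/spectransfer.R`).

## CARS: what is canonical and what we had to decide

Competitive adaptive reweighted sampling shrinks the variable set over `N`
sampling runs (default 50). Per run: a Monte-Carlo subsample (default 80%
of calibration rows) is drawn, a PLS model fitted on the currently retained
variables, and variables are ranked by |regression coefficient|. An
exponentially decreasing function fixes the retained count per run,
`count_i = round(p * a * exp(-k i))` with `a = (p/2)^(1/(N-1))`,
`k = log(p/2)/(N-1)`, so `count_1 = p` and `count_N = 2`. The subset with
the lowest 10-fold cross-validated RMSECV wins; the PLS component count is
chosen per run by the same cross-validation, capped at 10.

One design choice was genuinely open. The classical "adaptive reweighted
sampling" step is a weighted bootstrap whose *unique* survivors form the
next set, so the realized counts drift below the schedule. This package
instead retains the top half of the scheduled count by force (the enforced
EDF cut) and fills the remainder by a weighted draw **without** replacement
(probability proportional to |coefficient|). Both competitive mechanisms
survive - strong variables are guaranteed through, weak ones compete
stochastically - and the retained counts follow the schedule exactly, which
makes the shrinkage path reproducible and testable. The Monte-Carlo row
subsampling remains the dominant source of run-to-run variation.

The PLS engine is a minimal SIMPLS implementation (`pls_fit`); no headline
results are produced with PLS, it only ranks variables and provides RMSECV
inside CARS.

## Direct standardization details

Centering resolves an ambiguity in the usual presentation: `F` is estimated
on column-centered standards, but unknown spectra arrive uncentered. We
center unknowns with the **slave standard mean**, multiply by `F`, and add
the **master standard mean**. This makes the rank-one per-wavelength
residual term of the DS model exact: the slave mean always maps exactly to
the master mean, and self-transfer (slave = master) is the identity on the
standards' row space (both properties are asserted in tests).

The pseudoinverse truncates singular values below `svd_tol * sigma_max`
(default `1e-6`, configurable). The standard-sample count is the number of
rows behind that SVD: with `m` standards the centered slave matrix has rank
at most `m - 1`, so transfer is only as expressive as the standards allow.
`optimize_ssn()` scans candidate counts by minimum RMSEP on transferred
prediction spectra. Two practical regimes are worth knowing: while the
standard count is *below* the band count, the transfer is rank-limited and
RMSEP is erratic - the worst spot is standards roughly equal to bands,
the classic DS ill-conditioning zone; once standards clearly exceed bands,
more standards keep improving the least-squares estimate of `F` and RMSEP
decreases (the monotone regime exercised in the tests).

The transfer direction follows the workflow's purpose: the crushed-form
model is the master and full-form spectra are transferred into its space.
Both standard-selection schemes (distances computed on the crushed or on
the full calibration spectra) are available; the default is SPXY on the
crushed form with 70 standards, the configuration this kind of workflow
typically settles on and the one the end-to-end tests exercise.

## epsilon-SVR

No SVM implementation is guaranteed in the target environment, so the
package carries a compact SMO solver for the epsilon-SVR dual (the
standard 2n-variable box-constrained QP with one equality constraint),
with second-order working-set selection and the usual KKT-based offset.
It was cross-checked against an independent libsvm binding during
development (max prediction difference 2e-7 on a shared fixture).

Kernels: RBF (default) and linear. Predictors are standardized internally
with training-set statistics so the gamma grid is scale-free; the response
stays in log10 CFU/g so the epsilon tube has physical units. Tuning is a
seeded 10-fold grid search minimizing RMSECV over
`C in 2^(-5..15)`, `gamma in 2^(-15..3)` (log2 steps of 2) and
`epsilon in {0.01, 0.05, 0.1}`. Hybrid sweeps reuse the hyperparameters
tuned on the base model for every `k` by default (`retune = TRUE`
re-searches per row; slower and rarely different).

## Metrics

`RMSE = sqrt(mean((y - yhat)^2))`; `R2 = 1 - SSres/SStot`;
`RPD = SD / RMSEP` and `RER = (Max - Min) / RMSEP`, where SD (n-1
denominator), Max and Min are computed from the *prediction-set reference
values*, read literally from the definitions. The identity
`RER / RPD = (Max - Min) / SD` is asserted on random vectors. Conventional
flags are attached: RPD > 2.5 "reliable"; RER < 3 little utility, 3-10
good utility, > 10 high efficiency. `compare_models()` reports percent
changes with positive = improvement for both error metrics
(`100 (a-b)/a`) and gain metrics (`100 (b-a)/a`), plus raw deltas, to
avoid sign ambiguity.

Note that published RPD/RER values in this literature are often not
reproducible from the same paper's summary tables (the evaluation
population is ambiguous); the formulas here are implemented literally and
documented, nothing else.

## Plate counts

`plate_count_tvc()` implements the weighted two-dilution rule
`N = sum(C) / ((n1 + 0.1 n2) d)`. Some sources typeset the weight with a
minus sign; that variant is available as `sign_convention =
"paper_minus"` for audits, but the national-standard plus sign is the
default. Both agree when no second-dilution plates are counted.

## The synthetic world

Real two-form spectra of this kind are not publicly distributable, so the
generator (`generate_dataset_pair`) states a world in which every claim can
be tested:

* 100 samples, 256 bands over 885-1735 nm; TVC uniform on 2.1347-3.8808
  log10 CFU/g (the observed calibration range; the models never use
  storage time, so no temporal trend is simulated).
* Crushed spectrum = smooth baseline minus Gaussian absorption peaks at
  944, 980, 1076, 1186, 1264, 1455 nm (the O-H/N-H/C-H overtone bands of
  meat), peak depths affine in TVC with both signs of slope, plus
  per-sample affine scatter (slope sd 0.04, offset sd 1%) and white noise
  (sd 0.15%).
* Full spectrum = the same clean spectrum pushed through a fixed band-wise
  affine **form map** (smooth gain in [0.7, 1.3], offset in [-3, 3]%),
  then 3x stronger scatter, a smooth per-sample heterogeneity wiggle
  (three random-phase harmonics, amplitude sd 2.5%) and noise sd 1.5%.

The form-map strength and the full-form noise/heterogeneity levels were
fixed once so the stated world exhibits the qualitative structure the
design targets - crushed models outperform full-form models; feeding raw
full-form spectra to the crushed model fails visibly; DS transfer with 70
standards recovers most of the loss; transferred hybrids match or beat
transfer-only - and those properties are asserted in the test suite
rather than assumed. Percent-scale heterogeneity between measurement spots
is realistic for intact cooked-meat surfaces in diffuse mode.

What the generator does **not** emulate: radiometrically realistic meat
optics, spatial texture, drift between acquisition days, detector
nonlinearity, or any dependence of noise on wavelength. A green test
establishes that the algorithms behave as designed under the stated
generative structure - not that any particular accuracy figure would be
reproduced on real instrument data.

## Numerical choices

* SVD cutoff `1e-6` (relative) in DS; SMO tolerance `1e-3` (the libsvm
  default) with a 2e5 iteration cap and a warning if hit.
* MSC refuses samples whose regression slope is below `1e-12` in absolute
  value (a flat spectrum carries no scatter information).
* Tie-breaks in KS/SPXY: lowest index among tied candidates,
  lexicographically smallest pair for the seed; exact nearest-neighbour
  ties in wavelength-to-band mapping resolve to the lower index. All
  deterministic and covered by oracle tests.
* Every stochastic stage takes an explicit seed; pipeline stage seeds
  derive from one master seed by fixed offsets, so a single integer
  reproduces a full run bit-for-bit.

## Known limitations

* DS estimates a dense band-to-band map; with standards close to or fewer
  than bands it degrades gracefully (SVD truncation) but noticeably -
  use the union-variable grid, not the full 256 bands, when standards are
  scarce.
* The SMO solver is exact but not shrinking-accelerated; it is sized for
  chemometric calibration sets (tens to a few hundred samples), not for
  thousands.
* `read_cube()` supports ENVI BSQ/BIL/BIP with integer and float types and
  a plain-text fixture dialect; exotic header extensions are out of scope.
* Plate-count records assume the standard two-dilution design.
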