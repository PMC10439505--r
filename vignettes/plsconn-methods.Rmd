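---
title: "Methods: behavioural PLS on ridge partial-correlation connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: behavioural PLS on ridge partial-correlation connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plsconn)
```

## The model

`plsconn` analyses the covariance between two subject-level blocks: an
edge block **X** (subjects × edges, Fisher-z ridge partial correlations
over the upper triangle of a parcellation) and a behaviour block **Y**
(subjects × clinical variables — ordinal symptom items, syndrome scales,
or binary diagnosis indicators). Behavioural PLS correlation forms the
cross-block matrix **R** = corr(**Y**, **X**) and decomposes it,
**R** = **U S Vᵀ**. Each latent variable (LV) ties a unit-norm behaviour
salience **u** to a unit-norm brain salience **v**; subjects receive
scores by projecting their processed data on the saliences, and
100·s²/Σs² is the percent cross-block covariance the LV explains.

The key assumptions are (i) linearity of the brain–behaviour association
after rank transformation, (ii) exchangeability of subjects under the
null (the basis of both permutation schemes), and (iii) that nuisance
structure is adequately captured by linear confound regression.

### Spearman mode

Symptom data are heavily skewed ordinal counts, so the default mode
replaces every column of both blocks by average ranks (ties averaged)
standardized to mean 0, *population*-SD 1, and then applies Pearson
machinery — i.e. **R** holds Spearman rank correlations. This makes all
singular values invariant to strictly monotone transformations of any
variable. Whether the edge block should be ranked as well is genuinely
open; ranking both blocks is the default (`rank_x = TRUE`) because it
makes the two blocks symmetric and robustifies against heavy-tailed edge
estimates, and the Pearson-on-ranks construction is what rank-option PLS
toolboxes compute. `mode = "pearson"` z-scores instead of ranking.

### Rotated vs non-rotated fits

The rotated fit lets the SVD find the behaviour rotation, yielding one LV
per behaviour variable. The non-rotated fit (`nonrotated_pls()`) pins the
behaviour side to prespecified unit-norm contrasts **c** and sets
**v** = **Rᵀc**/‖**Rᵀc**‖ with singular value ‖**Rᵀc**‖. "Controlling
for the other diagnoses" is implemented as `control =
"residualize_target"`: every behaviour column involved in a contrast is
residualized on the block's remaining columns before the cross-block
correlations are formed. This is the most direct reading of
diagnosis-specific testing; `control = "none"` disables it. Exact
contrast matrices are user-supplied (`diagnosis_contrasts()` builds the
one-indicator-per-diagnosis default).

### Sign and ordering conventions

LV signs are mathematically arbitrary; for deterministic output the
largest-|element| entry of each behaviour salience is made positive at
fit time. LVs are ordered by singular value (rotated) or contrast row
(non-rotated). The per-LV `lv_corr` is the Pearson correlation between
the paired brain and behaviour score vectors; published analyses report
a single r per LV without defining it, and this is the interpretation we
document.

## Inference

**Permutation test.** Subject rows of the behaviour block are shuffled
and the decomposition refit; p = (1 + #{s*ₗ ≥ sₗ})/(n_perm + 1). Singular
values are compared slot-to-slot without Procrustes realignment — the
plainest reading of standard toolbox behaviour; `max_stat = TRUE` offers
the stricter variant that compares every observed value against the
permuted *largest* value. Because column ranks and within-block
residualization commute with a joint row permutation, the blocks are
processed once and rows of the processed behaviour block are permuted;
this is exactly equivalent to refitting from raw data. No multiplicity
correction is applied across LVs (raw per-LV p-values are reported).

**Bootstrap stability.** Subjects are resampled with replacement and the
model refit from raw data (ranks are recomputed within each resample —
resampling does not commute with ranking, so no shortcut is taken).
Bootstrap saliences are sign-aligned to the original per LV (flip when
the dot product with the original brain salience is negative), and the
bootstrap ratio is the original salience over the SD of the aligned
bootstrap saliences, i.e. a pseudo-z. Edges with |bsr| *strictly*
greater than 3 (default) form the stable mask. A zero bootstrap SD maps
to ±50 (a documented cap); draws with fewer than 3 distinct subjects are
redrawn.

**Replication.** Weights from sample A are multiplied with sample B's
identically processed data, and the derived scores are correlated with
B's native scores (Pearson), brain and behaviour sides reported
separately; an LV replicates when both directions are significant at α
(default 0.05). The permutation null for each direction breaks B's
brain–behaviour pairing (shuffles B's behaviour rows) and *refits B's
saliences on every draw*. The cheaper alternative — permuting the derived
score vector against fixed native scores — is a conditional test only:
it ignores that two independently estimated salience vectors align by
chance (in a q-dimensional behaviour space the expected chance alignment
scales like 1/√q), and simulation on null cohorts shows it declares
replication far too often. With the refitting null, null cohorts fail to
replicate at the nominal rate, while planted dimensions replicate with
r close to 1 (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`).

## Preprocessing decisions

* Missingness: subjects with more than `max_missing` (default 10%)
  missing items are excluded; the boundary case (exactly 10%) is
  retained, reading "more than" strictly.
* Imputation: k-nearest neighbours with k = 1 (the default of the
  classic routine this mirrors), Euclidean distance over mutually
  observed variables scaled by √(p/p_obs). Imputed values are means of
  observed donor values, so they always lie within the variable's
  observed range, and observed cells are never modified.
* Z-scoring uses the sample SD (n − 1) — the conventional R choice,
  documented so tests can be exact; the rank transform inside Spearman
  mode uses the population SD of ranks, which is the convention under
  which ranks of distinct values have exactly unit variance.
* Confound residualization fits least squares on intercept + age + sex +
  site (dummy-coded) + FD + tSNR and keeps residuals; it is idempotent
  and leaves features exactly orthogonal to the design. The sensitivity
  variant without age/sex adjustment is just `terms = c("site", "fd",
  "tsnr")`. Only edges are residualized by default — published work
  names edge adjustment only — with `residualize_behaviour = TRUE`
  extending it to the behaviour block.
* Behaviour choice: symptom analyses accept items, scales, or both —
  instruments disagree on which the model "should" see, so the pipeline
  keys on a config field (`pls$behaviour`) rather than hard-coding one.

## The synthetic cohort generator

The generator exists so that every downstream stage can be tested against
known truth. It emulates:

* **Edges** on the Fisher-z partial-correlation scale: a network-block
  baseline (the exact partial level that yields a chosen within-network
  *marginal* correlation, default 0.3, in an equicorrelated block), plus
  per-latent contributions `z · effect · w`, plus linear confound
  effects, plus i.i.d. noise with SD `edge_noise_sd` (default 0.06,
  a realistic between-subject spread for Fisher-z partial correlations).
  Effect sizes are *per active edge*: salience rows are rescaled so their
  nonzero entries have RMS 1, making `effect_sizes = 0.8` mean "0.8
  noise-SDs of edge movement per latent SD". True brain saliences are
  block-structured: network pairs are dealt round-robin to the latents
  plus one unloaded share, so some circuits stay null — needed to
  measure false-positive edge stability.
* **Symptoms**: latent-loaded continuous scores cut at their 70%/90%
  quantiles into 0/1/2, reproducing the zero-inflation of checklist
  items; syndrome scales are sums over contiguous item subsets.
* **Diagnoses**: liabilities mixing a shared general factor (weight =
  `comorbidity_load`), a latent-specific term and noise, thresholded at
  1 SD; "no diagnosis" is always derived, never sampled, so the
  invariant *no-diagnosis ⇔ no other indicator* holds by construction.
* **Confounds**: age ~ U(5, 21) years, sex ~ Bernoulli(0.5), four
  scanner sites, FD and tSNR log-normal; injected linearly into both
  blocks with magnitude `confound_strength`.
* **Missingness**: completely at random at `missing_rate` on items only.
  MNAR mechanisms are deliberately out of scope.

One master seed drives documented sub-streams (structure, latents,
edges, behaviour, diagnoses, covariates, missingness, time series), so
cohorts are bitwise reproducible.

### Emulated time series

`gen_timeseries()` realizes each subject's edge vector as a multivariate
Gaussian series: the target partial-correlation matrix is the baseline
plus a shrunken copy (`embed_shrink`, default 0.9) of the subject's
deviation, assembled as a precision matrix Q = I − Π. If Q's smallest
eigenvalue falls below a floor (0.05), the deviation is shrunk further by
bisection on that eigenvalue — the baseline block structure is never
touched, which keeps the null within-network correlation level honest.
Naive alternatives fail: clipping eigenvalues after the fact inflates
within-network marginal correlations, and shrinking via an operator-norm
bound over-attenuates exactly the strong-effect subjects. Two caveats
follow from the construction: recovered edges are a shrunken (but, over
edges, proportionally faithful) copy of the direct ones, and in networks
with many nodes the marginal correlation responds steeply to partial
perturbations, so per-subject within-network levels jitter more when
blocks are large.

### What passing tests do and do not show

The generator's linear-Gaussian edges, MCAR missingness and
site-as-random-category confounds make recovery, type-I error and
replication testable with exact ground truth. They do not emulate
haemodynamics, scanner drift, motion artefact spectra, MNAR missingness,
or item-content structure, so green tests certify the statistical
machinery — not robustness to those real-data pathologies.

## Numerical choices

* Ridge default ρ = 0.1 — the conventional default of regularized
  network-matrix estimation; the reference description names the method
  but no value. ρ = 0 reproduces exact partial correlations and is
  verified against a brute-force matrix inversion to 1e−10.
* arctanh inputs with |r| ≥ 1 are clipped to ±(1 − 1e−7) with a warning.
* Constant columns: z-scoring returns zeros, loadings return 0, cross-
  correlations with them are set to 0 — each with a warning.
* Rank-deficient confound designs drop collinear columns (QR pivoting)
  with a warning; singular (C + ρI) raises an error advising a larger ρ.
* The scree "elbow" utility returns the index maximizing the second
  difference of the covariance-explained sequence; it is advisory — LV
  selection remains the analyst's decision.
* Matched splits use quantile bins (default 4) for numeric strata and
  assign strata too small to split to the larger half with a warning.

## Problem sizes in the test-suite

The suite exercises: salience recovery and bootstrap sensitivity on a
600-subject, 20-node (190-edge), 12-item cohort with effects 0.8/0.5;
type-I error over 200 null cohorts (n = 200, 10 nodes → 45 edges, 6
scales, 500 permutations each); split-half replication power at n = 600
(999 permutations) and the null replication rate over 100 trials (199
permutations each); and time-series fidelity at T = 500 on 10–12-node
parcellations. These sizes give stable Monte-Carlo estimates while the
whole suite stays fast; 45 edges stands in for the nominal "40" because
an upper triangle has P(P−1)/2 entries and no integer P yields 40.

## Known limitations

* Two blocks only; no sparse or regularized PLS, and no CCA.
* The bootstrap ratio uses the SD of aligned bootstrap saliences — a
  pseudo-z, not a jackknife SE or a percentile interval.
* Permutation and bootstrap loops are plain R; at 5000 permutations ×
  thousands of edges they are minutes-scale, not seconds-scale.
* `comorbidity_load` near 1 combined with strong latent loadings can
  make diagnosis indicators nearly collinear; the residualize-target
  control then removes most diagnosis-specific variance, which is the
  statistically honest but power-poor regime diagnosis-specific tests
  face on real data too.
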