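# plsconn

Multivariate analysis linking functional brain connectivity to
psychopathology in developmental clinical cohorts.

Children and adolescents referred for mental-health concerns rarely fit a
single diagnostic box: comorbidity is the rule, and the same connectivity
alterations recur across disorders. Rather than comparing diagnostic groups
one at a time, `plsconn` asks which *dimensions* of symptom burden and
diagnosis covary with which patterns of functional-connectivity edges, and
whether those dimensions survive out-of-sample projection. It is aimed at
researchers working with parcellated resting-state fMRI and parent-report
symptom instruments (CBCL-style 0/1/2 items, syndrome scales, diagnosis
indicators).

## The method

**Connectome.** Each subject's parcel time series (time × P) are
standardized and turned into ridge-regularized partial correlations: with
sample correlation matrix C and Q = (C + ρI)⁻¹,

    partial_ij = −Q_ij / √(Q_ii Q_jj),   ρ = 0.1 by default.

Edges are Fisher z-transformed (arctanh) and the upper triangle is
vectorized in row-major order — P = 100 nodes gives 4950 edges. Subjects
with parcel coverage below 60% on any parcel are excluded.

**Behaviour preparation.** Subjects with more than 10% missing symptom
items are excluded; remaining gaps are filled by k-nearest-neighbour
imputation (partial Euclidean distance, k = 1 default). Edges are
residualized on age, sex, scanner site, mean framewise displacement and
tSNR before modelling.

**Behavioural PLS correlation.** Both blocks are rank-transformed
(Spearman mode), and the cross-block correlation matrix R = corr(Y, X) is
decomposed, R = U S Vᵀ. Each latent variable (LV) pairs a behaviour
salience (column of U) with a brain salience (column of V); subjects score
on an LV by projection, and the LV's strength is its singular value, with
100·s²/Σs² percent cross-block covariance explained. A *non-rotated*
variant pins the behaviour side to user-supplied contrasts (e.g. one
diagnosis vs the rest, controlling the other diagnosis indicators by
residualization) with brain salience Rᵀc/‖Rᵀc‖.

**Inference.** LV significance comes from permutation of the behaviour
block's subject rows (add-one Monte-Carlo p on the singular values);
edge stability from bootstrap ratios ("pseudo-z": original salience over
its bootstrap SD), thresholded at |bsr| > 3. Stable-edge loadings are
summarised to network-pair blocks and nodal strength, and subject scores
are regressed post hoc on diagnosis category and comorbidity count
(adjusted for age, age², sex).

**Replication.** Salience weights fitted in one subsample are multiplied
with the other subsample's (identically processed) data; the derived
scores are correlated with the natively estimated ones, in both
directions, each with a permutation test that refits the target sample's
saliences under broken brain–behaviour pairing. An LV replicates when
both directions are significant.

A synthetic cohort generator (`sim_config()` / `gen_cohort()` /
`gen_timeseries()`) plants known latent dimensions, comorbidity structure,
confound effects and missingness, so every stage above is testable with
full ground truth and no restricted clinical data.

## Worked example

```r
library(plsconn)

cfg <- sim_config(n_subjects = 300, n_parcels = 20, n_networks = 4,
                  n_items = 12, n_scales = 4, seed = 11)
cohort <- gen_cohort(cfg)

keep   <- missing_filter(cohort$symptoms$items, max_missing = 0.1)
cohort <- subset_cohort(cohort, match(keep, rownames(cohort$edges)))
items  <- knn_impute(cohort$symptoms$items, k = 1)
edges  <- residualize_confounds(cohort$edges, cohort$covariates)

model  <- rotated_pls(edges, items, mode = "spearman")
perm   <- permutation_test(edges, items, model, n_perm = 999, seed = 2)
model$perm_p <- perm$p_values
print(model)
```

```
Rotated behavioural PLS (spearman mode), 272 subjects, 12 LVs
 LV singular_value covexp_pct score_r perm_p
  1         5.2113      66.03   0.734  0.001
  2         3.1102      23.52   0.707  0.001
  3         0.7946       1.53   0.642  1.000
  ...
```

The two planted dimensions surface as LV1 and LV2: together they carry
~90% of the cross-block covariance, their brain/behaviour score
correlations are ≈ 0.73 and 0.71, and only they survive permutation
testing (`significant_lvs(perm)` returns `1 2`). Bootstrap stability then
isolates the contributing edges, and the network summary attributes LV1's
stable edges to specific network pairs:

```r
boot   <- bootstrap_stability(edges, items, model, n_boot = 200, seed = 3)
lo     <- pls_loadings(model, edges, items)
blocks <- network_block_summary(lo$brain_loadings[1, ],
                                boot$stable_mask[1, ], cohort$atlas)
round(blocks, 2)
```

```
       net1  net2  net3   net4
net1   0.00 -0.20 14.63 -14.23
net2  -0.20  5.76 -0.11   0.00
net3  14.63 -0.11 -5.44   0.00
net4 -14.23  0.00  0.00   0.00
```

Positive block sums mark network pairs whose connectivity increases with
the symptom dimension, negative sums the reverse. The whole chain —
simulate → preprocess → fit → permute → bootstrap → summarise → replicate
— also runs as one call, `run_pipeline(config, out_dir)`, or from the
shell via `inst/scripts/run_pipeline.R`.

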