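test_that("atlas assignment is contiguous with near-equal block sizes", {
  a <- gen_atlas(100, 7)
  expect_identical(nrow(a), 100L)
  expect_identical(length(unique(a$network)), 7L)
  expect_true(all(table(a$network) >= 1))
  expect_identical(gen_atlas(5, 5)$network, paste0("net", 1:5))
  # manual enumeration for (10, 3): sizes 4, 3, 3 in order
  a3 <- gen_atlas(10, 3)
  expect_identical(a3$network,
                   rep(paste0("net", 1:3), times = c(4, 3, 3)))
  expect_error(gen_atlas(3, 5), "exceeds")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(n_scales = 30, n_items = 20), "n_scales")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(effect_sizes = c(1, 2, 3), n_latent = 2),
               "effect_sizes")
  expect_error(sim_config(n_networks = 30, n_parcels = 10), "n_networks")
})

test_that("generated cohorts match the config and carry unit-norm truth", {
  cfg <- sim_config(n_subjects = 80, n_parcels = 12, n_networks = 3,
                    n_items = 10, n_scales = 5, n_diagnoses = 4, seed = 5)
  co <- gen_cohort(cfg)
  expect_identical(dim(co$edges), c(80L, 66L))
  expect_identical(dim(co$symptoms$items), c(80L, 10L))
  expect_identical(dim(co$symptoms$scales), c(80L, 5L))
  expect_identical(dim(co$diagnoses), c(80L, 5L))   # incl. no_diagnosis
  expect_equal(rowSums(co$truth$brain_saliences_true^2), c(1, 1),
               tolerance = 1e-12)
  expect_equal(rowSums(co$truth$behaviour_saliences_true^2), c(1, 1),
               tolerance = 1e-12)
  # no_diagnosis is 1 exactly when all diagnosis columns are 0
  dx <- co$diagnoses[, 1:4, drop = FALSE]
  expect_identical(unname(co$diagnoses[, "no_diagnosis"]),
                   as.numeric(rowSums(dx) == 0))
  expect_true(all(co$symptoms$items %in% c(0, 1, 2, NA)))
  # bitwise reproducibility
  co2 <- gen_cohort(cfg)
  expect_identical(co$edges, co2$edges)
  expect_identical(co$symptoms$items, co2$symptoms$items)
})

test_that("null cohorts carry no cross-block association", {
  co <- null_cohort(seed = 123, n = 400)
  n <- 400
  r <- cor(co$edges[, c(1, 10, 30)], co$symptoms$scales[, c(1, 4)])
  expect_true(all(abs(r) < 4 / sqrt(n)))
})

test_that("full comorbidity load induces positive association for all pairs", {
  co <- gen_cohort(sim_config(n_subjects = 800, n_parcels = 5, n_networks = 2,
                              n_diagnoses = 4, comorbidity_load = 1, seed = 8))
  dx <- co$diagnoses[, 1:4]
  for (a in 1:3) for (b in (a + 1):4) {
    tab <- table(factor(dx[, a], 0:1), factor(dx[, b], 0:1))
    # positive association: odds ratio above 1
    expect_gt(tab[1, 1] * tab[2, 2], tab[1, 2] * tab[2, 1])
  }
})

test_that("a single strong latent dimension is recoverable from the cross-corr SVD", {
  co <- gen_cohort(sim_config(n_subjects = 600, n_parcels = 10, n_networks = 3,
                              n_latent = 1, effect_sizes = 1,
                              n_items = 8, n_scales = 4,
                              confound_strength = 0, missing_rate = 0,
                              seed = 31))
  R <- cor(rank_z(co$symptoms$items), rank_z(co$edges))
  v <- svd(R)$v[, 1]
  expect_cosine(v, co$truth$brain_saliences_true[1, ], 0.9)
})

test_that("matched splits are disjoint, exhaustive and stratum-preserving", {
  sp <- matched_split(100, 0.8, seed = 1)
  expect_identical(c(length(sp$a), length(sp$b)), c(80L, 20L))
  expect_identical(sort(c(sp$a, sp$b)), 1:100)
  # stratified: 60/40 sex preserved within +/- 1 subject in a 20-subject toy
  df <- data.frame(sex = rep(c(1, 0), times = c(12, 8)))
  sp2 <- matched_split(df, 0.5, strata = "sex", seed = 2)
  expect_identical(sum(df$sex[sp2$a]), 6)
  expect_identical(length(sp2$a), 10L)
  # determinism
  sp3 <- matched_split(df, 0.5, strata = "sex", seed = 2)
  expect_identical(sp2, sp3)
  # cohort interface with age quantile bins
  co <- null_cohort(seed = 12, n = 120)
  sp4 <- suppressWarnings(
    matched_split(co, 0.75, strata = c("site", "sex", "age"), seed = 3))
  expect_identical(sort(c(sp4$a, sp4$b)), 1:120)
  expect_lt(abs(length(sp4$a) - 90), 8)
})

test_that("tiny strata go to the larger split with a warning", {
  df <- data.frame(g = c("a", "a", "a", "a", "b"))
  expect_warning(sp <- matched_split(df, 0.75, strata = "g", seed = 1),
                 "too small")
  expect_true(5 %in% sp$a)
})

test_that("emulated time series realize the planted edge patterns", {
  cfg <- sim_config(n_subjects = 6, n_parcels = 10, n_networks = 3,
                    n_timepoints = 500, seed = 21)
  co <- gen_timeseries(gen_cohort(cfg))
  expect_identical(length(co$timeseries), 6L)
  expect_identical(dim(co$timeseries[[1]]), c(500L, 10L))
  # determinism
  co2 <- gen_timeseries(gen_cohort(cfg))
  expect_identical(co$timeseries, co2$timeseries)
  # end-to-end: recomputed edges correlate with the direct ones per subject
  er <- compute_edges(co$timeseries, rho = 0.1)
  for (s in 1:6)
    expect_gt(cor(er[s, ], co$edges[s, ]), 0.8)
})

test_that("null time series show the target within-network correlation level", {
  cfg <- sim_config(n_subjects = 4, n_parcels = 12, n_networks = 4,
                    n_timepoints = 500, effect_sizes = c(0, 0),
                    confound_strength = 0, seed = 22)
  co <- gen_timeseries(gen_cohort(cfg))
  within <- outer(co$atlas$network, co$atlas$network, "==")
  for (s in 1:4) {
    C <- cor(co$timeseries[[s]])
    expect_gt(mean(C[within & upper.tri(C)]), 0.2)
    expect_lt(mean(C[within & upper.tri(C)]), 0.4)
  }
})

test_that("long series converge to the population correlation matrix", {
  cfg <- sim_config(n_subjects = 1, n_parcels = 10, n_networks = 2,
                    n_timepoints = 10000, effect_sizes = c(0, 0),
                    confound_strength = 0, seed = 30)
  co <- suppressWarnings(gen_timeseries(gen_cohort(cfg)))
  # rebuild the embedded population matrix independently
  mu <- plsconn:::baseline_edges(co$atlas, co$config$within_r)
  Qb <- diag(10) - devectorize_edges(tanh(mu), 10)
  lb <- min(eigen(Qb, symmetric = TRUE, only.values = TRUE)$values)
  fl <- min(0.05, lb / 2)
  D <- devectorize_edges(tanh(pmin(pmax(co$edges[1, ] - mu, -3), 3)), 10)
  s_dev <- 0.9
  if (min(eigen(Qb - s_dev * D, symmetric = TRUE,
                only.values = TRUE)$values) < fl) {
    lo <- 0; hi <- s_dev
    for (it in 1:20) {
      mid <- (lo + hi) / 2
      ok <- min(eigen(Qb - mid * D, symmetric = TRUE,
                      only.values = TRUE)$values) >= fl
      if (ok) lo <- mid else hi <- mid
    }
    s_dev <- lo
  }
  ei <- eigen(Qb - s_dev * D, symmetric = TRUE)
  R_pop <- cov2cor(ei$vectors %*% (t(ei$vectors) / pmax(ei$values, fl)))
  expect_lt(max(abs(cor(co$timeseries[[1]]) - R_pop)), 0.03)
})

test_that("exchangeability under the null: permuting one block leaves singular values stable", {
  co <- null_cohort(seed = 44, n = 300)
  m <- rotated_pls(co$edges, co$symptoms$scales)
  set.seed(9)
  svs <- replicate(30, {
    perm <- sample.int(300)
    rotated_pls(co$edges, co$symptoms$scales[perm, , drop = FALSE]
    )$singular_values[1]
  })
  # observed LV1 singular value sits inside the permuted spread
  expect_gt(m$singular_values[1], min(svs) * 0.8)
  expect_lt(m$singular_values[1], max(svs) * 1.2)
})
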