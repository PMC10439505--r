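test_that("rank_z uses average ranks and population-SD standardization", {
  x <- matrix(c(3, 1, 2), 3, 1)
  z <- rank_z(x)
  expect_equal(drop(z), c(1.2247449, -1.2247449, 0), tolerance = 1e-6)
  # ties share the average rank
  zt <- rank_z(matrix(c(1, 1, 2), 3, 1))
  r <- c(1.5, 1.5, 3)
  expect_equal(drop(zt), (r - mean(r)) / sqrt(mean((r - mean(r))^2)),
               tolerance = 1e-12)
  # strictly monotone transforms leave the output unchanged
  y <- matrix(rnorm(40), 20, 2)
  y2 <- y
  y2[, 1] <- exp(y2[, 1])
  expect_equal(rank_z(y), rank_z(y2), tolerance = 1e-12)
})

test_that("rotated PLS matches an independent SVD of the cross-correlation matrix", {
  set.seed(31)
  X <- matrix(rnorm(6 * 3), 6, 3)
  Y <- matrix(rnorm(6 * 2), 6, 2)
  m <- rotated_pls(X, Y, mode = "spearman")
  # oracle: explicit Spearman cross-correlation matrix, plain svd()
  R <- cor(apply(Y, 2, rank), apply(X, 2, rank))
  expect_equal(m$singular_values, svd(R)$d, tolerance = 1e-10)
  expect_identical(length(m$singular_values), 2L)
  # pearson mode against pearson cross-correlations
  mp <- rotated_pls(X, Y, mode = "pearson")
  expect_equal(mp$singular_values, svd(cor(Y, X))$d, tolerance = 1e-10)
})

test_that("one LV per behaviour variable; perfect association gives r = 1", {
  set.seed(32)
  X <- matrix(rnorm(40 * 10), 40, 10)
  Y8 <- matrix(rnorm(40 * 8), 40, 8)
  expect_identical(length(rotated_pls(X, Y8)$singular_values), 8L)
  Y <- X[, 4, drop = FALSE]
  m <- rotated_pls(X, Y)
  expect_gt(m$lv_corr[1], 0.95)
  expect_identical(which.max(abs(m$brain_saliences[1, ])), 4L)
  # with exactly uncorrelated edges the limit is exact: salience is the
  # indicator of the matching column and the score correlation is 1
  Xo <- qr.Q(qr(scale(X, scale = FALSE)))
  mo <- rotated_pls(Xo, Xo[, 4, drop = FALSE], mode = "pearson")
  expect_equal(mo$lv_corr[1], 1, tolerance = 1e-10)
  expect_equal(unname(abs(mo$brain_saliences[1, ])),
               as.numeric(seq_len(10) == 4), tolerance = 1e-10)
  expect_error(rotated_pls(X[1:2, ], Y[1:2, , drop = FALSE]), "3 subjects")
})

test_that("salience rows are orthonormal and covexp sums to 100", {
  set.seed(33)
  X <- matrix(rnorm(50 * 20), 50, 20)
  Y <- matrix(rnorm(50 * 5), 50, 5)
  m <- rotated_pls(X, Y)
  G_brain <- m$brain_saliences %*% t(m$brain_saliences)
  G_beh <- m$behaviour_saliences %*% t(m$behaviour_saliences)
  expect_lt(max(abs(G_brain - diag(5))), 1e-10)
  expect_lt(max(abs(G_beh - diag(5))), 1e-10)
  expect_lt(abs(sum(m$covexp) - 100), 1e-8)
  # deterministic sign: largest behaviour salience element positive
  for (l in 1:5) {
    u <- m$behaviour_saliences[l, ]
    expect_gt(u[which.max(abs(u))], 0)
  }
})

test_that("spearman mode is invariant under monotone transforms of behaviour", {
  set.seed(34)
  X <- matrix(rnorm(60 * 15), 60, 15)
  Y <- matrix(rnorm(60 * 4), 60, 4)
  m1 <- rotated_pls(X, Y, mode = "spearman")
  Y2 <- Y
  Y2[, 1] <- exp(Y2[, 1])
  Y2[, 3] <- atan(Y2[, 3]) * 10 + 2
  m2 <- rotated_pls(X, Y2, mode = "spearman")
  expect_equal(m1$singular_values, m2$singular_values, tolerance = 1e-10)
  expect_equal(m1$brain_saliences, m2$brain_saliences, tolerance = 1e-10)
})

test_that("two-group contrast PLS matches the group mean-difference oracle", {
  set.seed(35)
  n <- 60
  g <- rep(c(1, 0), each = n / 2)
  X <- matrix(rnorm(n * 25), n, 25) + outer(g, rnorm(25, 0, 0.5))
  Y <- cbind(grpA = g, grpB = 1 - g)
  m <- nonrotated_pls(X, Y, contrasts = matrix(c(1, -1), 1), control = "none")
  Xp <- rank_z(X)
  md <- colMeans(Xp[g == 1, ]) - colMeans(Xp[g == 0, ])
  expect_equal(abs(cor(m$brain_saliences[1, ], md)), 1, tolerance = 1e-10)
  # scaling a contrast changes nothing
  m10 <- nonrotated_pls(X, Y, contrasts = matrix(c(10, -10), 1), control = "none")
  expect_equal(m$brain_saliences, m10$brain_saliences, tolerance = 1e-12)
  expect_equal(m$brain_scores, m10$brain_scores, tolerance = 1e-12)
  expect_error(nonrotated_pls(X, Y, contrasts = matrix(c(0, 0), 1)), "zero")
})

test_that("rotated and non-rotated solutions agree when contrasts equal the saliences", {
  set.seed(36)
  X <- matrix(rnorm(50 * 12), 50, 12)
  Y <- matrix(rnorm(50 * 3), 50, 3)
  mr <- rotated_pls(X, Y)
  mn <- nonrotated_pls(X, Y, contrasts = mr$behaviour_saliences,
                       control = "none")
  expect_equal(mr$singular_values, mn$singular_values, tolerance = 1e-8)
  expect_equal(mr$brain_saliences, mn$brain_saliences, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("residualize_target control removes shared diagnosis variance", {
  set.seed(37)
  co <- gen_cohort(sim_config(n_subjects = 300, n_parcels = 8, n_networks = 2,
                              comorbidity_load = 0.8, seed = 57))
  Y <- co$diagnoses
  m <- nonrotated_pls(co$edges, Y, diagnosis_contrasts(colnames(Y)))
  expect_identical(length(m$singular_values), 6L)
  expect_identical(rownames(m$behaviour_saliences), paste0("dx0", 1:6))
  # behaviour score for dx01 is orthogonal to the other diagnosis columns
  Yp <- rank_z(Y)
  others <- Yp[, setdiff(colnames(Y), "dx01")]
  expect_lt(max(abs(cor(m$behaviour_scores[, "dx01"], others))), 1e-10)
})

test_that("loadings are correlations between scores and original data", {
  set.seed(38)
  X <- matrix(rnorm(5 * 4), 5, 4)
  Y <- matrix(rnorm(5 * 2), 5, 2)
  m <- rotated_pls(X, Y)
  lo <- pls_loadings(m, X, Y)
  for (e in 1:4)
    expect_equal(unname(lo$brain_loadings[1, e]),
                 cor(m$brain_scores[, 1], X[, e]), tolerance = 1e-12)
  expect_true(all(abs(lo$brain_loadings) <= 1 + 1e-12))
  # behaviour column equal to its own score vector loads 1.0
  Y2 <- cbind(m$behaviour_scores[, 1], rnorm(5))
  lo2 <- pls_loadings(m, X, Y2)
  expect_equal(unname(lo2$behaviour_loadings[1, 1]), 1, tolerance = 1e-10)
  # constant feature gets loading 0 with a warning
  Xc <- X
  Xc[, 2] <- 3
  expect_warning(lo3 <- pls_loadings(m, Xc, Y), "constant")
  expect_identical(lo3$brain_loadings[, 2], c(LV1 = 0, LV2 = 0))
})

test_that("covariance-explained table and scree elbow behave as documented", {
  expect_equal(covexp_table(c(2, 1)), c(80, 20))
  expect_equal(covexp_table(5), 100)
  expect_equal(covexp_table(c(3, 3, 3)), rep(100 / 3, 3))
  expect_error(covexp_table(c(0, 0)), "zero")
  # elbow: sharp drop after the first two LVs
  expect_identical(scree_elbow(c(10, 6, 1, 0.9, 0.8)), 3L)
})
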