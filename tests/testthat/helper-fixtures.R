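# Shared fixtures, built once per test run.

# strong-effect cohort at the parameter-recovery scale: n = 600, 20 nodes
# (190 edges), 12 ordinal items, two planted dimensions (0.8 / 0.5)
strong_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_subjects = 600, n_parcels = 20, n_networks = 4,
                        n_items = 12, n_scales = 4, seed = 42)
      cache <<- gen_cohort(cfg)
    }
    cache
  }
})

# the same cohort taken through the standard preprocessing chain
strong_prepped <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- strong_cohort()
      keep <- missing_filter(co$symptoms$items, 0.1)
      co <- subset_cohort(co, match(keep, rownames(co$edges)))
      items <- knn_impute(co$symptoms$items, k = 1)
      edges <- residualize_confounds(co$edges, co$covariates)
      cache <<- list(cohort = co, edges = edges, items = items)
    }
    cache
  }
})

# small null cohort factory (no planted effects, no confounds, complete)
null_cohort <- function(seed, n = 200, scales = 6) {
  gen_cohort(sim_config(n_subjects = n, n_parcels = 10, n_networks = 3,
                        n_items = 2 * scales, n_scales = scales,
                        effect_sizes = c(0, 0), confound_strength = 0,
                        missing_rate = 0, seed = seed))
}

expect_cosine <- function(a, b, at_least) {
  cosine <- abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
  expect_gte(cosine, at_least)
  invisible(cosine)
}
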