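#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the generator. Effect sizes are
#' expressed per latent dimension as the standard deviation of that
#' latent's contribution to each of its active edges (and items), in units
#' of the edge (item) noise SD, so `effect_sizes = 0.8` means the latent
#' moves its edges by 0.8 noise-SDs per latent-SD.
#'
#' @param n_subjects,n_parcels,n_networks,n_timepoints,n_items,n_scales,n_diagnoses,n_latent
#'   counts (all >= 1; `n_scales <= n_items`, `n_networks <= n_parcels`).
#' @param effect_sizes numeric vector of length `n_latent`.
#' @param comorbidity_load in \[0, 1\]: weight of the shared liability
#'   factor generating diagnosis comorbidity.
#' @param confound_strength scalar >= 0 scaling the linear age/sex/site/
#'   motion effects injected into edges and behaviour.
#' @param missing_rate proportion in \[0, 1) of symptom items set missing
#'   completely at random.
#' @param within_r target population correlation within network blocks of
#'   the emulated time series (also fixes the baseline partial-correlation
#'   level of generated edges).
#' @param edge_noise_sd SD of the i.i.d. edge noise on the Fisher-z scale.
#' @param seed integer master seed; all sub-streams derive from it.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_subjects = 600, n_parcels = 20, n_networks = 4,
                       n_timepoints = 250, n_items = 24, n_scales = 8,
                       n_diagnoses = 6, n_latent = 2,
                       effect_sizes = c(0.8, 0.5), comorbidity_load = 0.5,
                       confound_strength = 0.5, missing_rate = 0.05,
                       within_r = 0.3, edge_noise_sd = 0.06, seed = 1) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_parcels = as.integer(n_parcels),
              n_networks = as.integer(n_networks),
              n_timepoints = as.integer(n_timepoints),
              n_items = as.integer(n_items), n_scales = as.integer(n_scales),
              n_diagnoses = as.integer(n_diagnoses),
              n_latent = as.integer(n_latent),
              effect_sizes = as.numeric(effect_sizes),
              comorbidity_load = comorbidity_load,
              confound_strength = confound_strength,
              missing_rate = missing_rate, within_r = within_r,
              edge_noise_sd = edge_noise_sd, seed = as.integer(seed))
  counts <- c("n_subjects", "n_parcels", "n_networks", "n_timepoints",
              "n_items", "n_scales", "n_diagnoses", "n_latent")
  for (nm in counts)
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 1)
      stop("invalid config: ", nm, " must be a count >= 1")
  if (cfg$n_scales > cfg$n_items)
    stop("invalid config: n_scales must not exceed n_items")
  if (cfg$n_networks > cfg$n_parcels)
    stop("invalid config: n_networks must not exceed n_parcels")
  if (length(cfg$effect_sizes) != cfg$n_latent)
    stop("invalid config: effect_sizes must have length n_latent")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("invalid config: missing_rate must lie in [0, 1)")
  if (cfg$comorbidity_load < 0 || cfg$comorbidity_load > 1)
    stop("invalid config: comorbidity_load must lie in [0, 1]")
  if (cfg$confound_strength < 0 || cfg$edge_noise_sd <= 0)
    stop("invalid config: nonnegative confound_strength and positive edge_noise_sd required")
  if (cfg$within_r <= 0 || cfg$within_r >= 1)
    stop("invalid config: within_r must lie in (0, 1)")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic sub-stream seeds derived from the master seed (kept < 2^31)
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 1000003) * 1009 + stream) %% 2147483629L
}

# partial correlation giving marginal correlation r in an equicorrelated
# block of size m (precision with unit diagonal and off-diagonal -pi);
# vectorised over m
partial_for_marginal <- function(r, m) {
  ifelse(m < 2, 0, r / (1 + (m - 2) * r))
}

# split nf features into ng near-equal contiguous groups; returns group index
contiguous_groups <- function(nf, ng) {
  sizes <- rep(nf %/% ng, ng)
  extra <- nf %% ng
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(ng), times = sizes)
}

# baseline Fisher-z partial-correlation edge vector implied by the atlas
# block structure and the target within-network marginal correlation
baseline_edges <- function(atlas, within_r) {
  P <- nrow(atlas)
  idx <- edge_index(P)
  nets <- atlas$network
  sizes <- table(nets)
  mu <- numeric(nrow(idx))
  within <- nets[idx$i] == nets[idx$j]
  if (any(within)) {
    m_of <- as.numeric(sizes[nets[idx$i]])
    mu[within] <- atanh(partial_for_marginal(within_r, m_of[within]))
  }
  mu
}

# unit-norm salience rows with disjoint network-block (resp. item) support
plant_brain_saliences <- function(atlas, n_latent) {
  P <- nrow(atlas)
  idx <- edge_index(P)
  nets <- unique(atlas$network)
  net_of <- match(atlas$network, nets)
  K <- length(nets)
  pairs <- expand.grid(a = seq_len(K), b = seq_len(K))
  pairs <- pairs[pairs$a <= pairs$b, ]
  # deal network-pair blocks round-robin over the latents plus one
  # "unloaded" share, so some circuits stay unrelated to any dimension
  ord <- sample.int(nrow(pairs))
  owner <- integer(nrow(pairs))
  owner[ord] <- rep_len(seq_len(n_latent + 1L), nrow(pairs))
  ea <- pmin(net_of[idx$i], net_of[idx$j])
  eb <- pmax(net_of[idx$i], net_of[idx$j])
  block_of_edge <- match(paste(ea, eb), paste(pairs$a, pairs$b))
  W <- matrix(0, n_latent, nrow(idx))
  for (l in seq_len(n_latent)) {
    blocks <- which(owner == l)
    active <- which(block_of_edge %in% blocks)
    if (length(active) == 0) next
    sgn <- sample(c(-1, 1), length(blocks), replace = TRUE)
    W[l, active] <- abs(stats::rnorm(length(active), 1, 0.3)) *
      sgn[match(block_of_edge[active], blocks)]
    W[l, ] <- W[l, ] / sqrt(sum(W[l, ]^2))
  }
  W
}

plant_behaviour_saliences <- function(n_items, n_latent) {
  B <- matrix(0, n_latent, n_items)
  owner <- rep_len(seq_len(n_latent), n_items)
  for (l in seq_len(n_latent)) {
    active <- which(owner == l)
    B[l, active] <- abs(stats::rnorm(length(active), 1, 0.3))
    B[l, ] <- B[l, ] / sqrt(sum(B[l, ]^2))
  }
  B
}

# rescale unit-norm salience rows so active entries have RMS 1 (effect
# sizes then read as per-active-feature contribution SDs)
active_rms_scale <- function(S) {
  t(apply(S, 1L, function(w) {
    na <- sum(w != 0)
    if (na == 0) w else w * sqrt(na)
  }))
}

#' Generate a synthetic cohort with planted brain-behaviour dimensions
#'
#' Emulates the data structure of a developmental clinical cohort: a
#' subjects x edges connectivity block (Fisher-z ridge-partial-correlation
#' scale) with a network-block baseline plus planted latent dimensions,
#' ordinal 0/1/2 symptom items thresholded from latent-loaded continuous
#' scores (cut at their 70\%/90\% quantiles, giving the zero-inflation
#' typical of symptom checklists), syndrome scales as sums over contiguous
#' item subsets, binary diagnoses thresholded at 1 SD from liabilities
#' sharing a general factor (comorbidity), linear age/sex/site/motion
#' confounds injected into both blocks, and completely-at-random missing
#' symptom entries. The planted structure is returned as ground truth for
#' recovery testing.
#'
#' @param config a [sim_config()].
#' @return a `plsconn_cohort`: list with `edges`, `timeseries` (`NULL`
#'   until [gen_timeseries()]), `symptoms` (`$items` with `NA`s, `$scales`),
#'   `diagnoses` (0/1 matrix including a derived `no_diagnosis` column),
#'   `covariates`, `atlas`, `truth` (`latent_scores`,
#'   `brain_saliences_true`, `behaviour_saliences_true`, `confound_coefs`)
#'   and `config`.
#' @export
gen_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  P <- config$n_parcels
  L <- config$n_latent
  E <- (P * (P - 1L)) %/% 2L
  sig <- config$edge_noise_sd
  ids <- sprintf("sub%04d", seq_len(n))

  atlas <- gen_atlas(P, config$n_networks)
  mu <- baseline_edges(atlas, config$within_r)

  set.seed(sub_seed(config$seed, 1L))
  W <- plant_brain_saliences(atlas, L)
  B <- plant_behaviour_saliences(config$n_items, L)

  set.seed(sub_seed(config$seed, 2L))
  Z <- matrix(stats::rnorm(n * L), n, L)

  set.seed(sub_seed(config$seed, 6L))
  covariates <- data.frame(
    subject_id = ids,
    age = stats::runif(n, 5, 21),
    sex = stats::rbinom(n, 1, 0.5),
    site = factor(paste0("site", sample.int(4, n, replace = TRUE))),
    fd = stats::rlnorm(n, log(0.2), 0.4),
    tsnr = stats::rlnorm(n, log(50), 0.2),
    stringsAsFactors = FALSE
  )
  Dc <- confound_design(covariates,
                        c("age", "sex", "site", "fd", "tsnr"))[, -1, drop = FALSE]
  Dc <- scale(Dc)
  Dc[!is.finite(Dc)] <- 0   # constant covariate at small n carries no signal
  ncov <- ncol(Dc)
  coef_edges <- matrix(stats::rnorm(ncov * E, 0,
                                    config$confound_strength * sig / sqrt(ncov)),
                       ncov, E)
  coef_items <- matrix(stats::rnorm(ncov * config$n_items, 0,
                                    0.5 * config$confound_strength / sqrt(ncov)),
                       ncov, config$n_items)

  set.seed(sub_seed(config$seed, 3L))
  edges <- matrix(mu, n, E, byrow = TRUE) +
    Z %*% (config$effect_sizes * sig * active_rms_scale(W)) +
    Dc %*% coef_edges +
    matrix(stats::rnorm(n * E, 0, sig), n, E)
  dimnames(edges) <- list(ids, edge_names(P))

  set.seed(sub_seed(config$seed, 4L))
  items_cont <- Z %*% (config$effect_sizes * active_rms_scale(B)) +
    Dc %*% coef_items +
    matrix(stats::rnorm(n * config$n_items), n, config$n_items)
  items <- vapply(seq_len(config$n_items), function(j) {
    x <- items_cont[, j]
    q <- stats::quantile(x, c(0.7, 0.9))
    as.numeric((x > q[1]) + (x > q[2]))
  }, numeric(n))
  items <- matrix(items, nrow = n,
                  dimnames = list(ids, sprintf("item%02d", seq_len(config$n_items))))

  scale_of <- contiguous_groups(config$n_items, config$n_scales)
  scales <- vapply(seq_len(config$n_scales), function(s)
    rowSums(items[, scale_of == s, drop = FALSE]), numeric(n))
  scales <- matrix(scales, nrow = n,
                   dimnames = list(ids, sprintf("scale%02d", seq_len(config$n_scales))))

  set.seed(sub_seed(config$seed, 5L))
  g <- stats::rnorm(n)
  dx_latent <- rep_len(seq_len(L), config$n_diagnoses)
  w_z <- 0.4
  w_e <- 0.5
  coef_diag <- matrix(stats::rnorm(ncov * config$n_diagnoses, 0,
                                   0.3 * config$confound_strength / sqrt(ncov)),
                      ncov, config$n_diagnoses)
  conf_d <- Dc %*% coef_diag
  diagnoses <- vapply(seq_len(config$n_diagnoses), function(d) {
    raw <- config$comorbidity_load * g + w_z * Z[, dx_latent[d]] +
      conf_d[, d] + w_e * stats::rnorm(n)
    tot_sd <- sqrt(config$comorbidity_load^2 + w_z^2 + w_e^2 +
                     mean(coef_diag[, d]^2) * ncov)
    as.numeric(raw / tot_sd > 1)
  }, numeric(n))
  diagnoses <- matrix(diagnoses, nrow = n)
  colnames(diagnoses) <- sprintf("dx%02d", seq_len(config$n_diagnoses))
  diagnoses <- cbind(diagnoses,
                     no_diagnosis = as.numeric(rowSums(diagnoses) == 0))
  rownames(diagnoses) <- ids

  if (config$missing_rate > 0) {
    set.seed(sub_seed(config$seed, 7L))
    miss <- matrix(stats::runif(length(items)) < config$missing_rate,
                   nrow(items), ncol(items))
    items[miss] <- NA
  }

  structure(
    list(edges = edges, timeseries = NULL,
         symptoms = list(items = items, scales = scales),
         diagnoses = diagnoses, covariates = covariates, atlas = atlas,
         truth = list(latent_scores = Z, brain_saliences_true = W,
                      behaviour_saliences_true = B,
                      confound_coefs = list(edges = coef_edges,
                                            items = coef_items,
                                            diagnoses = coef_diag),
                      scale_of_item = scale_of, dx_latent = dx_latent),
         config = config),
    class = "plsconn_cohort"
  )
}

#' Emulate parcel time series realizing a cohort's edge patterns
#'
#' For every subject, builds a population covariance whose partial
#' correlations embed that subject's generated edge vector (baseline plus a
#' shrunken copy of the individual deviation, `embed_shrink`, which keeps
#' the implied precision matrix well conditioned) on top of elevated
#' within-network blocks, then draws a multivariate Gaussian series of
#' `n_timepoints` volumes. Re-estimating edges from these series via
#' [compute_edges()] recovers vectors that correlate strongly with the
#' directly generated ones.
#'
#' @param cohort a `plsconn_cohort` with ground truth.
#' @param embed_shrink factor in (0, 1\] applied to each subject's
#'   deviation from the baseline edge pattern before embedding.
#' @return the cohort with a `timeseries` list (one timepoints x parcels
#'   matrix per subject) filled in.
#' @export
gen_timeseries <- function(cohort, embed_shrink = 0.9) {
  stopifnot(inherits(cohort, "plsconn_cohort"))
  config <- cohort$config
  P <- config$n_parcels
  T_ <- config$n_timepoints
  if (T_ < P + 1)
    warning("n_timepoints < n_parcels + 1; ridge estimation remains defined ",
            "but sample matrices are rank deficient")
  mu <- baseline_edges(cohort$atlas, config$within_r)
  set.seed(sub_seed(config$seed, 8L))
  ts_list <- vector("list", nrow(cohort$edges))
  names(ts_list) <- rownames(cohort$edges)
  Q_base <- diag(P) - devectorize_edges(tanh(mu), P)
  lam_base <- min(eigen(Q_base, symmetric = TRUE, only.values = TRUE)$values)
  floor_ <- min(0.05, lam_base / 2)
  eig_min <- function(M) min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
  for (s in seq_len(nrow(cohort$edges))) {
    dev <- tanh(pmin(pmax(cohort$edges[s, ] - mu, -3), 3))
    D <- devectorize_edges(dev, P)
    # shrink the deviation just enough to keep the precision matrix
    # positive definite (bisection on its smallest eigenvalue); the
    # baseline block structure is never touched
    s_dev <- embed_shrink
    if (eig_min(Q_base - s_dev * D) < floor_) {
      lo <- 0
      hi <- s_dev
      for (it in 1:20) {
        mid <- (lo + hi) / 2
        if (eig_min(Q_base - mid * D) >= floor_) lo <- mid else hi <- mid
      }
      s_dev <- lo
    }
    eig <- eigen(Q_base - s_dev * D, symmetric = TRUE)
    Sigma <- eig$vectors %*% (t(eig$vectors) / pmax(eig$values, floor_))
    R <- stats::cov2cor(Sigma)
    ts_list[[s]] <- MASS::mvrnorm(T_, rep(0, P), R)
    colnames(ts_list[[s]]) <- cohort$atlas$label
  }
  cohort$timeseries <- ts_list
  cohort
}

#' Stratified matched split of a cohort
#'
#' Partitions subjects into two disjoint, exhaustive index sets of
#' proportions `fraction` and `1 - fraction`, preserving the requested
#' strata: within every cross-classified stratum (numeric variables such as
#' age are cut into quantile bins) the split proportion deviates from
#' `fraction` by at most one subject. Strata too small to be represented
#' in both splits are assigned entirely to the larger split with a
#' warning.
#'
#' @param x a `plsconn_cohort`, a data frame of stratification variables,
#'   or a single integer (number of subjects, unstratified).
#' @param fraction proportion assigned to the first split (0 < f < 1).
#' @param strata character vector naming covariate and/or diagnosis
#'   columns to match on (ignored when `x` is an integer).
#' @param seed integer seed.
#' @param age_bins number of quantile bins for numeric strata (default 4).
#' @return list with integer index vectors `a` and `b`.
#' @export
matched_split <- function(x, fraction = 0.8, strata = character(), seed = 1,
                          age_bins = 4) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.numeric(x) && length(x) == 1) {
    n <- as.integer(x)
    df <- NULL
  } else if (inherits(x, "plsconn_cohort")) {
    n <- nrow(x$edges)
    pool <- cbind(x$covariates, as.data.frame(x$diagnoses))
    missing_s <- setdiff(strata, names(pool))
    if (length(missing_s) > 0)
      stop("strata column(s) not found: ", paste(missing_s, collapse = ", "))
    df <- pool[, strata, drop = FALSE]
  } else {
    df <- as.data.frame(x)
    missing_s <- setdiff(strata, names(df))
    if (length(missing_s) > 0)
      stop("strata column(s) not found: ", paste(missing_s, collapse = ", "))
    df <- df[, strata, drop = FALSE]
    n <- nrow(df)
  }
  if (is.null(df) || ncol(df) == 0) {
    stratum <- rep(1L, n)
  } else {
    binned <- lapply(df, function(v) {
      if (is.numeric(v) && length(unique(v)) > age_bins) {
        br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = age_bins + 1)))
        cut(v, breaks = br, include.lowest = TRUE)
      } else factor(v)
    })
    stratum <- as.integer(interaction(binned, drop = TRUE))
  }
  set.seed(seed)
  a <- integer(0)
  b <- integer(0)
  for (st in sort(unique(stratum))) {
    members <- which(stratum == st)
    m <- length(members)
    na <- round(fraction * m)
    if (na == 0L || na == m) {
      warning("stratum ", st, " (", m, " subject(s)) too small to split; ",
              "assigned to the larger split")
      if (fraction >= 0.5) a <- c(a, members) else b <- c(b, members)
      next
    }
    ord <- members[sample.int(m)]
    a <- c(a, ord[seq_len(na)])
    b <- c(b, ord[(na + 1L):m])
  }
  list(a = sort(a), b = sort(b))
}

#' Subset a cohort by subject indices
#' @param cohort a `plsconn_cohort`.
#' @param idx integer subject indices.
#' @return the subsetted cohort.
#' @export
subset_cohort <- function(cohort, idx) {
  stopifnot(inherits(cohort, "plsconn_cohort"))
  cohort$edges <- cohort$edges[idx, , drop = FALSE]
  if (!is.null(cohort$timeseries)) cohort$timeseries <- cohort$timeseries[idx]
  cohort$symptoms$items <- cohort$symptoms$items[idx, , drop = FALSE]
  cohort$symptoms$scales <- cohort$symptoms$scales[idx, , drop = FALSE]
  cohort$diagnoses <- cohort$diagnoses[idx, , drop = FALSE]
  cohort$covariates <- cohort$covariates[idx, , drop = FALSE]
  cohort$truth$latent_scores <- cohort$truth$latent_scores[idx, , drop = FALSE]
  cohort
}

#' @export
print.plsconn_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("Synthetic cohort: %d subjects, %d parcels (%d networks, ",
                     "%d edges), %d items / %d scales, %d diagnoses, ",
                     "%d planted latent dimension(s)\n"),
              cfg$n_subjects, cfg$n_parcels, cfg$n_networks,
              ncol(x$edges), cfg$n_items, cfg$n_scales, cfg$n_diagnoses,
              cfg$n_latent))
  cat(sprintf("effect sizes: %s; comorbidity load %.2f; missing rate %.2f%s\n",
              paste(cfg$effect_sizes, collapse = ", "), cfg$comorbidity_load,
              cfg$missing_rate,
              if (is.null(x$timeseries)) "" else "; time series attached"))
  invisible(x)
}
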