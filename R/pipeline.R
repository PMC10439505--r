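#' Default pipeline configuration
#'
#' Returns the full RunConfig list with every option at its default;
#' user configs (YAML/JSON, see [read_run_config()]) are merged over it.
#' Stages: `simulate`, `connectome` (re-derive edges from emulated time
#' series; off by default), `preprocess`, `fit`, `permute`, `bootstrap`,
#' `summarize`, `replicate`.
#'
#' @return nested list of settings.
#' @export
default_run_config <- function() {
  list(
    stages = c("simulate", "preprocess", "fit", "permute", "bootstrap",
               "summarize", "replicate"),
    sim = list(),
    rho = 0.1,
    knn_k = 1,
    max_missing = 0.1,
    residualize_terms = c("age", "sex", "site", "fd", "tsnr"),
    residualize_behaviour = FALSE,
    pls = list(mode = "spearman", rotated = TRUE, rank_x = TRUE,
               behaviour = "scales"),
    n_perm = 500,
    n_boot = 200,
    bsr_threshold = 3,
    alpha = 0.05,
    split = list(fraction = 0.8, strata = c("site", "sex", "age")),
    seed = 1
  )
}

#' Read a RunConfig from YAML or JSON
#' @param path configuration file (`.yaml`/`.yml` or `.json`).
#' @return RunConfig list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  modifyList(default_run_config(), cfg)
}

#' Run the full analysis pipeline
#'
#' Config-driven orchestration: simulate a cohort (or reuse one), derive
#' edges from emulated time series, preprocess behaviour and edges, fit
#' the PLS, assess permutation significance and bootstrap stability,
#' summarise edge results to network blocks / nodal strength and post-hoc
#' regressions, and evaluate split-sample replication. Every artefact is a
#' TSV or JSON file under `out_dir`, together with a `manifest.json`
#' recording settings and seeds; a rerun with the same config reproduces
#' byte-identical payloads.
#'
#' @param config RunConfig list (see [default_run_config()]); missing
#'   entries are filled with defaults.
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory results (`cohort`, `model`,
#'   `perm`, `boot`, `summaries`, `replication`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- modifyList(default_run_config(), config)
  stages <- cfg$stages
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()

  if (!"simulate" %in% stages)
    stop("stage 'simulate' is required: the pipeline runs on generated cohorts")
  sim_args <- cfg$sim
  sim_args$seed <- cfg$seed
  cohort <- do.call(sim_config, sim_args)
  cohort <- gen_cohort(cohort)
  res$cohort <- cohort

  if ("connectome" %in% stages) {
    cohort <- gen_timeseries(cohort)
    cohort$edges_direct <- cohort$edges
    cohort$edges <- compute_edges(cohort$timeseries, rho = cfg$rho)
    res$cohort <- cohort
  }
  write_cohort(cohort, file.path(out_dir, "cohort"))

  prep <- preprocess_cohort(cohort, cfg)
  res$prep <- prep
  write_matrix_tsv(prep$edges, file.path(out_dir, "edges_preprocessed.tsv"))

  if (!"fit" %in% stages) {
    write_manifest(cfg, out_dir)
    return(invisible(res))
  }
  model <- fit_stage(prep, cfg)
  res$model <- model

  if ("permute" %in% stages) {
    if (!is.numeric(cfg$n_perm) || cfg$n_perm < 1)
      stop("inference stage refused: n_perm must be >= 1 (got ",
           deparse(cfg$n_perm), "); set n_perm in the config")
    perm <- permutation_test(prep$edges, prep$behaviour, model,
                             n_perm = cfg$n_perm,
                             seed = sub_seed(cfg$seed, 101L))
    model$perm_p <- perm$p_values
    res$perm <- perm
    jsonlite::write_json(
      list(n_perm = perm$n_perm, observed_s = perm$observed_s,
           p_values = perm$p_values, seed = perm$seed),
      file.path(out_dir, "perm.json"), digits = NA, auto_unbox = TRUE)
    utils::write.table(perm$perm_s, file.path(out_dir, "perm_s.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_pls_model(model, out_dir, "model")

  boot <- NULL
  if ("bootstrap" %in% stages) {
    if (!is.numeric(cfg$n_boot) || cfg$n_boot < 2)
      stop("inference stage refused: n_boot must be >= 2 (got ",
           deparse(cfg$n_boot), "); set n_boot in the config")
    boot <- bootstrap_stability(prep$edges, prep$behaviour, model,
                                n_boot = cfg$n_boot,
                                threshold = cfg$bsr_threshold,
                                seed = sub_seed(cfg$seed, 102L))
    res$boot <- boot
    utils::write.table(
      data.frame(lv = rownames(boot$bsr), boot$bsr, check.names = FALSE),
      file.path(out_dir, "bsr.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }

  if ("summarize" %in% stages)
    res$summaries <- summarize_stage(model, boot, prep, cohort, cfg, out_dir)

  if ("replicate" %in% stages)
    res$replication <- replicate_stage(cohort, cfg, out_dir)

  write_manifest(cfg, out_dir)
  invisible(res)
}

# behaviour selection + missingness filter + imputation + residualization
preprocess_cohort <- function(cohort, cfg) {
  beh_kind <- cfg$pls$behaviour
  behaviour <- switch(beh_kind,
                      scales = cohort$symptoms$scales,
                      items = cohort$symptoms$items,
                      diagnoses = cohort$diagnoses,
                      stop("unknown behaviour block '", beh_kind, "'"))
  keep_ids <- missing_filter(cohort$symptoms$items, cfg$max_missing)
  keep <- match(keep_ids, rownames(cohort$edges))
  cohort <- subset_cohort(cohort, keep)
  behaviour <- behaviour[keep_ids, , drop = FALSE]
  if (beh_kind == "items")
    behaviour <- knn_impute(behaviour, k = cfg$knn_k)
  edges <- residualize_confounds(cohort$edges, cohort$covariates,
                                 cfg$residualize_terms)
  if (isTRUE(cfg$residualize_behaviour) && beh_kind != "diagnoses")
    behaviour <- residualize_confounds(behaviour, cohort$covariates,
                                       cfg$residualize_terms)
  list(edges = edges, behaviour = behaviour, cohort = cohort,
       behaviour_kind = beh_kind)
}

fit_stage <- function(prep, cfg) {
  if (isTRUE(cfg$pls$rotated)) {
    rotated_pls(prep$edges, prep$behaviour, mode = cfg$pls$mode,
                rank_x = isTRUE(cfg$pls$rank_x))
  } else {
    contrasts <- if (!is.null(cfg$pls$contrast_file)) {
      as.matrix(utils::read.delim(cfg$pls$contrast_file, row.names = 1,
                                  check.names = FALSE))
    } else {
      diagnosis_contrasts(colnames(prep$behaviour))
    }
    nonrotated_pls(prep$edges, prep$behaviour, contrasts,
                   mode = cfg$pls$mode, rank_x = isTRUE(cfg$pls$rank_x))
  }
}

summarize_stage <- function(model, boot, prep, cohort, cfg, out_dir) {
  loads <- pls_loadings(model, prep$edges, prep$behaviour)
  sig <- if (!is.null(model$perm_p)) which(model$perm_p < cfg$alpha)
         else seq_along(model$singular_values)
  out <- list(loadings = loads)
  atlas <- cohort$atlas
  blocks <- list()
  strength <- list()
  for (l in sig) {
    mask <- if (!is.null(boot)) boot$stable_mask[l, ] else NULL
    blocks[[l]] <- network_block_summary(loads$brain_loadings[l, ], mask, atlas)
    strength[[l]] <- nodal_strength(loads$brain_loadings[l, ], mask, atlas)
  }
  out$network_blocks <- blocks
  out$nodal_strength <- strength
  for (l in sig) {
    utils::write.table(
      data.frame(network = rownames(blocks[[l]]), blocks[[l]],
                 check.names = FALSE),
      file.path(out_dir, sprintf("network_blocks_LV%d.tsv", l)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (length(strength) > 0 && length(sig) > 0) {
    sm <- do.call(cbind, strength[sig])
    colnames(sm) <- paste0("LV", sig)
    utils::write.table(
      data.frame(node_id = atlas$node_id, label = atlas$label, sm,
                 check.names = FALSE),
      file.path(out_dir, "nodal_strength.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  prep_cohort <- prep$cohort
  n_dx <- rowSums(prep_cohort$diagnoses[, colnames(prep_cohort$diagnoses) !=
                                          "no_diagnosis", drop = FALSE])
  lv1 <- model$brain_scores[, 1]
  out$dx_regression <- score_diagnosis_regression(
    lv1, prep_cohort$diagnoses, prep_cohort$covariates)
  out$comorbidity <- rbind(
    cbind(include_zero = TRUE,
          comorbidity_trend(lv1, n_dx, prep_cohort$covariates, TRUE)),
    cbind(include_zero = FALSE,
          comorbidity_trend(lv1, n_dx, prep_cohort$covariates, FALSE)))
  utils::write.table(out$dx_regression,
                     file.path(out_dir, "diagnosis_regression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$comorbidity,
                     file.path(out_dir, "comorbidity_trend.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

replicate_stage <- function(cohort, cfg, out_dir) {
  split <- matched_split(cohort, fraction = cfg$split$fraction,
                         strata = cfg$split$strata,
                         seed = sub_seed(cfg$seed, 103L))
  fit_half <- function(idx) {
    half <- subset_cohort(cohort, idx)
    prep <- preprocess_cohort(half, cfg)
    list(prep = prep, model = fit_stage(prep, cfg))
  }
  A <- fit_half(split$a)
  B <- fit_half(split$b)
  rep_res <- cross_replicate(A$model, A$prep$edges, A$prep$behaviour,
                             B$model, B$prep$edges, B$prep$behaviour,
                             n_perm = cfg$n_perm, alpha = cfg$alpha,
                             seed = sub_seed(cfg$seed, 104L))
  jsonlite::write_json(
    list(brain = rep_res$brain, behaviour = rep_res$behaviour,
         n_perm = rep_res$n_perm, alpha = rep_res$alpha,
         split_sizes = c(length(split$a), length(split$b))),
    file.path(out_dir, "replication.json"), digits = NA, auto_unbox = TRUE)
  rep_res
}

write_manifest <- function(cfg, out_dir) {
  jsonlite::write_json(
    list(package = "plsconn",
         version = as.character(utils::packageVersion("plsconn")),
         config = cfg,
         sub_seeds = list(permutation = sub_seed(cfg$seed, 101L),
                          bootstrap = sub_seed(cfg$seed, 102L),
                          split = sub_seed(cfg$seed, 103L),
                          replication = sub_seed(cfg$seed, 104L))),
    file.path(out_dir, "manifest.json"), digits = NA, auto_unbox = TRUE)
  invisible(out_dir)
}
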