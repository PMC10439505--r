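#' Read and write subject-keyed TSV matrices
#'
#' All tabular artefacts use tab-separated text with the subject ID in the
#' first column (`subject_id`); missing cells are written as empty strings
#' and read back as `NA`.
#'
#' @param x numeric matrix with subject IDs as row names.
#' @param path file path.
#' @return `read_matrix_tsv()` returns a numeric matrix with row names.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(subject_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Write a generated cohort to a directory of plain-text artefacts
#'
#' Emits `edges.tsv`, `symptoms_items.tsv`, `symptoms_scales.tsv`,
#' `diagnoses.tsv`, `covariates.tsv`, `atlas.tsv` and `truth.json`
#' (the planted ground truth), plus one `timeseries/<subject>.tsv` per
#' subject when time series are attached.
#'
#' @param cohort a `plsconn_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "plsconn_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(cohort$edges, file.path(dir, "edges.tsv"))
  write_matrix_tsv(cohort$symptoms$items, file.path(dir, "symptoms_items.tsv"))
  write_matrix_tsv(cohort$symptoms$scales, file.path(dir, "symptoms_scales.tsv"))
  write_matrix_tsv(cohort$diagnoses, file.path(dir, "diagnoses.tsv"))
  utils::write.table(cohort$covariates, file.path(dir, "covariates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.tsv"))
  jsonlite::write_json(
    list(latent_scores = cohort$truth$latent_scores,
         brain_saliences_true = cohort$truth$brain_saliences_true,
         behaviour_saliences_true = cohort$truth$behaviour_saliences_true,
         config = unclass(cohort$config)),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE
  )
  if (!is.null(cohort$timeseries)) {
    tsdir <- file.path(dir, "timeseries")
    dir.create(tsdir, showWarnings = FALSE)
    for (s in names(cohort$timeseries))
      utils::write.table(cohort$timeseries[[s]],
                         file.path(tsdir, paste0(s, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read per-subject parcel time series from a directory
#'
#' Expects one TSV per subject (columns `n1..nP`, rows timepoints), as
#' written by [write_cohort()].
#'
#' @param dir directory of `<subject>.tsv` files.
#' @return named list of timepoints x parcels matrices.
#' @export
read_timeseries <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.tsv$", full.names = TRUE))
  if (length(files) == 0) stop("no .tsv time-series files in ", dir)
  out <- lapply(files, function(f) {
    m <- as.matrix(utils::read.delim(f, check.names = FALSE))
    storage.mode(m) <- "double"
    if (anyNA(m) || any(!is.finite(m)))
      stop("non-finite values in time series file ", f)
    m
  })
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' Serialize a fitted PLS model
#'
#' Writes `<prefix>.json` (singular values, covariance explained, score
#' correlations, settings and any attached permutation p-values) plus TSVs
#' for saliences (edge columns in canonical order) and subject scores.
#'
#' @param model a `pls_model`.
#' @param dir output directory.
#' @param prefix file name prefix (default `"model"`).
#' @return the directory path, invisibly.
#' @export
write_pls_model <- function(model, dir, prefix = "model") {
  stopifnot(inherits(model, "pls_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(singular_values = model$singular_values,
               lv_corr = model$lv_corr, covexp = model$covexp,
               mode = model$mode, rotated = model$rotated,
               rank_x = model$rank_x, n = model$n)
  if (!is.null(model$perm_p)) meta$perm_p <- model$perm_p
  jsonlite::write_json(meta, file.path(dir, paste0(prefix, ".json")),
                       digits = NA, auto_unbox = TRUE)
  sal_tsv <- function(m, path) {
    df <- data.frame(lv = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sal_tsv(model$brain_saliences,
          file.path(dir, paste0(prefix, "_brain_saliences.tsv")))
  sal_tsv(model$behaviour_saliences,
          file.path(dir, paste0(prefix, "_behaviour_saliences.tsv")))
  write_matrix_tsv(model$brain_scores,
                   file.path(dir, paste0(prefix, "_brain_scores.tsv")))
  write_matrix_tsv(model$behaviour_scores,
                   file.path(dir, paste0(prefix, "_behaviour_scores.tsv")))
  invisible(dir)
}
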