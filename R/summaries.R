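#' Summarise edge values to network-pair blocks
#'
#' Aggregates per-edge values (typically loadings of bootstrap-stable
#' edges) over all edges whose endpoints fall in a given pair of networks;
#' within-network edges land on the diagonal. The default aggregates by
#' signed sum; `stat = "mean"` averages over the masked edges of each block
#' instead.
#'
#' @param edge_values numeric vector in canonical edge order.
#' @param mask logical vector of the same length selecting edges (e.g. the
#'   bootstrap stable-edge mask); `NULL` selects all edges.
#' @param atlas atlas data frame ([gen_atlas()] format) whose node count
#'   matches the edge count.
#' @param stat `"sum"` (default) or `"mean"`.
#' @return symmetric K x K matrix with network labels as dimnames.
#' @export
network_block_summary <- function(edge_values, mask = NULL, atlas,
                                  stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  validate_atlas(atlas)
  P <- nrow(atlas)
  idx <- edge_index(P)
  if (length(edge_values) != nrow(idx))
    stop("edge_values length does not match the atlas node count")
  if (is.null(mask)) mask <- rep(TRUE, length(edge_values))
  stopifnot(length(mask) == length(edge_values))
  nets <- unique(atlas$network)
  K <- length(nets)
  net_of <- match(atlas$network, nets)
  B <- matrix(0, K, K, dimnames = list(nets, nets))
  cnt <- matrix(0L, K, K)
  sel <- which(mask & !is.na(edge_values))
  for (e in sel) {
    a <- net_of[idx$i[e]]
    b <- net_of[idx$j[e]]
    B[a, b] <- B[a, b] + edge_values[e]
    cnt[a, b] <- cnt[a, b] + 1L
    if (a != b) {
      B[b, a] <- B[a, b]
      cnt[b, a] <- cnt[a, b]
    }
  }
  if (stat == "mean") {
    B <- ifelse(cnt > 0, B / cnt, 0)
    dimnames(B) <- list(nets, nets)
  }
  B
}

#' Nodal strength of masked edges
#'
#' Weighted degree of each node over the selected edges. By default the
#' absolute weighted graph is used (`strength(i) = sum of |value|` over
#' masked edges incident to `i`), matching the magnitude convention of
#' connectivity-toolbox strength plots; `signed = TRUE` sums raw values.
#'
#' @inheritParams network_block_summary
#' @param signed sum signed values instead of magnitudes.
#' @return named numeric vector, one nonnegative (or signed) value per node.
#' @export
nodal_strength <- function(edge_values, mask = NULL, atlas, signed = FALSE) {
  validate_atlas(atlas)
  P <- nrow(atlas)
  idx <- edge_index(P)
  if (length(edge_values) != nrow(idx))
    stop("edge_values length does not match the atlas node count")
  if (is.null(mask)) mask <- rep(TRUE, length(edge_values))
  w <- ifelse(mask & !is.na(edge_values), edge_values, 0)
  if (!signed) w <- abs(w)
  strength <- numeric(P)
  for (e in which(w != 0)) {
    strength[idx$i[e]] <- strength[idx$i[e]] + w[e]
    strength[idx$j[e]] <- strength[idx$j[e]] + w[e]
  }
  names(strength) <- atlas$label
  strength
}

#' Post-hoc regression of subject scores on diagnosis category
#'
#' For each diagnosis column, restricts the sample to subjects carrying
#' that diagnosis or the reference ("no diagnosis") group and fits
#' `score ~ diagnosis + age + age^2 + sex` by least squares, returning the
#' diagnosis coefficient, its standard error and two-sided p-value. Set
#' `terms = character(0)` for the unadjusted variant (then the coefficient
#' is exactly the group mean difference).
#'
#' @param scores numeric vector of per-subject LV scores.
#' @param diagnoses subjects x diagnoses 0/1 matrix including the
#'   reference column.
#' @param covariates data frame with `age` and `sex` columns (same order).
#' @param reference reference column name (default `"no_diagnosis"`).
#' @param terms adjustment terms; any of `"age"`, `"age2"`, `"sex"`.
#' @return data frame: `diagnosis`, `estimate`, `se`, `p`, `n_case`,
#'   `n_ref`. Diagnoses with fewer than 3 cases are skipped with a warning.
#' @export
score_diagnosis_regression <- function(scores, diagnoses, covariates,
                                       reference = "no_diagnosis",
                                       terms = c("age", "age2", "sex")) {
  stopifnot(is.matrix(diagnoses), length(scores) == nrow(diagnoses),
            nrow(covariates) == nrow(diagnoses))
  if (!reference %in% colnames(diagnoses))
    stop("reference column '", reference, "' not found in diagnoses")
  ref <- diagnoses[, reference] == 1
  out <- list()
  for (d in setdiff(colnames(diagnoses), reference)) {
    case <- diagnoses[, d] == 1
    if (sum(case) < 3 || sum(ref) < 3) {
      warning("skipping '", d, "': fewer than 3 subjects in a group")
      next
    }
    sel <- case | ref
    df <- data.frame(score = scores[sel], dx = as.numeric(case[sel]))
    rhs <- "dx"
    if ("age" %in% terms) { df$age <- covariates$age[sel]; rhs <- c(rhs, "age") }
    if ("age2" %in% terms) { df$age2 <- covariates$age[sel]^2; rhs <- c(rhs, "age2") }
    if ("sex" %in% terms) { df$sex <- covariates$sex[sel]; rhs <- c(rhs, "sex") }
    fit <- stats::lm(stats::reformulate(rhs, "score"), data = df)
    cf <- summary(fit)$coefficients["dx", ]
    out[[d]] <- data.frame(diagnosis = d, estimate = cf[1], se = cf[2],
                           p = cf[4], n_case = sum(case), n_ref = sum(ref))
  }
  if (length(out) == 0) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Linear trend of subject scores with comorbidity burden
#'
#' Least-squares slope of scores on the per-subject number of diagnoses,
#' adjusted for age, age^2 and sex, interpreting the count as a proxy of
#' cross-diagnostic vulnerability. `include_zero = FALSE` drops subjects
#' with no diagnosis, testing whether the trend also holds among cases.
#'
#' @inheritParams score_diagnosis_regression
#' @param n_diagnoses nonnegative integer vector of diagnosis counts.
#' @param include_zero keep subjects with zero diagnoses (default `TRUE`).
#' @return one-row data frame: `slope`, `se`, `p`, `n`.
#' @export
comorbidity_trend <- function(scores, n_diagnoses, covariates,
                              include_zero = TRUE,
                              terms = c("age", "age2", "sex")) {
  stopifnot(length(scores) == length(n_diagnoses),
            nrow(covariates) == length(scores), all(n_diagnoses >= 0))
  sel <- if (include_zero) rep(TRUE, length(scores)) else n_diagnoses > 0
  if (stats::sd(n_diagnoses[sel]) == 0)
    stop("diagnosis counts are constant; no trend estimable")
  df <- data.frame(score = scores[sel], count = n_diagnoses[sel])
  rhs <- "count"
  if ("age" %in% terms) { df$age <- covariates$age[sel]; rhs <- c(rhs, "age") }
  if ("age2" %in% terms) { df$age2 <- covariates$age[sel]^2; rhs <- c(rhs, "age2") }
  if ("sex" %in% terms) { df$sex <- covariates$sex[sel]; rhs <- c(rhs, "sex") }
  fit <- stats::lm(stats::reformulate(rhs, "score"), data = df)
  cf <- summary(fit)$coefficients["count", ]
  data.frame(slope = cf[1], se = cf[2], p = cf[4], n = sum(sel),
             row.names = NULL)
}
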