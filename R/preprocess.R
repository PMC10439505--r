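#' Exclude subjects with excessive missing behaviour data
#'
#' A subject is retained when the fraction of missing entries in the block
#' is at most `max_missing`; strictly more than the threshold excludes
#' (exactly 10\% missing is retained at the default).
#'
#' @param x subjects x variables matrix with `NA` for missing entries;
#'   subject IDs as row names.
#' @param max_missing maximal tolerated missing proportion (default 0.1).
#' @return character vector of retained subject IDs (indices if unnamed).
#' @export
missing_filter <- function(x, max_missing = 0.1) {
  stopifnot(is.matrix(x), max_missing >= 0)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  frac <- rowMeans(is.na(x))
  ids[frac <= max_missing]
}

#' k-nearest-neighbour imputation of missing entries
#'
#' Each missing cell is replaced by the mean value of that variable among
#' the `k` nearest subjects with the value observed. Distance between two
#' subjects is the Euclidean distance over mutually observed variables,
#' scaled by `sqrt(p / p_obs)` (total over observed variable count), the
#' standard correction for partial distances. Observed cells are never
#' altered.
#'
#' @param x subjects x variables numeric matrix with `NA` for missing.
#' @param k number of neighbours (default 1, the referenced routine's
#'   default).
#' @return completed matrix of the same shape and dimnames.
#' @export
knn_impute <- function(x, k = 1L) {
  stopifnot(is.matrix(x), k >= 1)
  if (!anyNA(x)) return(x)
  p <- ncol(x)
  if (any(colSums(!is.na(x)) == 0)) {
    v <- colnames(x)[colSums(!is.na(x)) == 0]
    if (is.null(v)) v <- which(colSums(!is.na(x)) == 0)
    stop("variable(s) missing for all subjects, cannot impute: ",
         paste(v, collapse = ", "))
  }
  obs <- !is.na(x)
  x0 <- x
  x0[!obs] <- 0
  # pairwise squared partial distances via masked cross-products
  sq <- x0^2
  d2 <- tcrossprod(sq, obs) + tcrossprod(obs, sq) - 2 * tcrossprod(x0)
  n_obs <- tcrossprod(obs * 1)           # mutually observed variable counts
  d2 <- pmax(d2, 0) * p / pmax(n_obs, 1)
  d2[n_obs == 0] <- Inf
  diag(d2) <- Inf
  out <- x
  for (s in which(rowSums(!obs) > 0)) {
    miss <- which(!obs[s, ])
    ord <- order(d2[s, ])
    for (v in miss) {
      donors <- ord[obs[ord, v]]
      if (length(donors) < 1) stop("no donor subject for variable ", v)
      use <- donors[seq_len(min(k, length(donors)))]
      out[s, v] <- mean(x[use, v])
    }
  }
  out
}

#' Z-score each column of a matrix
#'
#' Centers to mean 0 and scales to unit sample standard deviation
#' (denominator `n - 1`). Constant columns are set to zero with a warning.
#'
#' @param x numeric matrix.
#' @return matrix of standardized columns, same dimnames.
#' @export
zscore_columns <- function(x) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("zscore_columns requires a complete matrix")
  mu <- colMeans(x)
  sd <- apply(x, 2L, stats::sd)
  const <- sd < .Machine$double.eps^0.5
  if (any(const)) {
    warning(sum(const), " constant column(s) set to zero")
    sd[const] <- 1
  }
  z <- sweep(sweep(x, 2L, mu, "-"), 2L, sd, "/")
  z[, const] <- 0
  z
}

#' Build a confound design matrix from a covariate table
#'
#' Intercept always included; categorical columns (factor/character, e.g.
#' scanner site) are dummy-coded against their first level; numeric columns
#' enter linearly.
#'
#' @keywords internal
confound_design <- function(covariates, terms) {
  stopifnot(is.data.frame(covariates))
  missing_terms <- setdiff(terms, names(covariates))
  if (length(missing_terms) > 0)
    stop("covariate column(s) not found: ", paste(missing_terms, collapse = ", "))
  single <- vapply(terms, function(tm) {
    v <- covariates[[tm]]
    (is.factor(v) || is.character(v)) && length(unique(v)) < 2
  }, logical(1))
  terms <- terms[!single]
  if (length(terms) == 0)
    return(matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)")))
  f <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  stats::model.matrix(f, data = covariates)
}

#' Residualize features on nuisance covariates
#'
#' Replaces every feature column by its least-squares residual on a design
#' of the requested covariate terms plus an intercept. Residuals are exactly
#' orthogonal to every design column; the operation is idempotent. A
#' rank-deficient design has its collinear columns dropped with a warning.
#' `terms = character(0)` mean-centers only.
#'
#' @param x subjects x features numeric matrix.
#' @param covariates data frame with one row per subject (same order).
#' @param terms character vector of covariate column names (e.g.
#'   `c("age", "sex", "site", "fd", "tsnr")`); a sensitivity variant
#'   without age/sex adjustment is obtained by dropping those names.
#' @return residualized matrix, same shape and dimnames.
#' @export
residualize_confounds <- function(x, covariates,
                                  terms = c("age", "sex", "site", "fd", "tsnr")) {
  stopifnot(is.matrix(x), nrow(x) == nrow(covariates))
  if (anyNA(covariates[terms])) stop("covariates must be complete")
  D <- confound_design(covariates, terms)
  qr_d <- qr(D)
  if (qr_d$rank < ncol(D)) {
    dropped <- colnames(D)[qr_d$pivot[-seq_len(qr_d$rank)]]
    warning("rank-deficient confound design; dropping: ",
            paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qr_d, x)
  dimnames(res) <- dimnames(x)
  res
}
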