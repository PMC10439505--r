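#' Ridge-regularized partial correlation matrix
#'
#' Estimates direct connectivity between nodes as partial correlations
#' derived from an L2-regularized inverse of the sample correlation matrix:
#' columns are standardized, `C = cor(ts)`, `Q = (C + rho I)^-1`, and the
#' partial correlation is `-Q_ij / sqrt(Q_ii Q_jj)` off the diagonal. The
#' diagonal of the result is set to 0. With `rho = 0` this is the exact
#' partial correlation (when `C` is invertible); positive `rho` shrinks
#' estimates towards zero and keeps the inverse well defined when the number
#' of timepoints is small relative to the number of nodes.
#'
#' @param ts numeric matrix, timepoints x parcels.
#' @param rho nonnegative ridge penalty (default 0.1, the conventional
#'   default of ridge-regularized network-matrix estimation).
#' @return symmetric `P x P` matrix of partial correlations, zero diagonal.
#' @export
ridge_partial_cor <- function(ts, rho = 0.1) {
  stopifnot(is.matrix(ts), rho >= 0)
  if (nrow(ts) < 3) stop("at least 3 timepoints are required")
  C <- stats::cor(ts)
  if (anyNA(C)) stop("correlation matrix contains NA (constant column?)")
  P <- ncol(C)
  Q <- tryCatch(
    solve(C + diag(rho, P)),
    error = function(e) stop("(C + rho*I) is numerically singular; raise rho (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  d <- sqrt(diag(Q))
  m <- -Q / tcrossprod(d)
  diag(m) <- 0
  (m + t(m)) / 2
}

#' Exclude subjects with insufficient parcel coverage
#'
#' A subject is retained only when the proportion of source voxels present
#' is at least `min_coverage` for every parcel; the rule excludes strictly
#' below the threshold, so a parcel at exactly the threshold is kept.
#'
#' @param coverage subjects x parcels matrix of proportions in \[0,1\], with
#'   subject IDs as row names, or a named list of per-parcel coverage
#'   vectors. `NULL` coverage for a subject is treated as full coverage
#'   with a warning.
#' @param min_coverage retention threshold (default 0.6).
#' @return character vector of retained subject IDs (or integer indices
#'   when the input is unnamed).
#' @export
coverage_filter <- function(coverage, min_coverage = 0.6) {
  if (is.list(coverage)) {
    ids <- names(coverage)
    if (is.null(ids)) ids <- as.character(seq_along(coverage))
    keep <- vapply(seq_along(coverage), function(s) {
      cv <- coverage[[s]]
      if (is.null(cv)) {
        warning("missing coverage for subject ", ids[s], "; assuming 1.0")
        return(TRUE)
      }
      all(cv >= min_coverage)
    }, logical(1))
    return(ids[keep])
  }
  stopifnot(is.matrix(coverage))
  ids <- rownames(coverage)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(coverage)))
  keep <- apply(coverage, 1L, function(cv) all(cv >= min_coverage))
  ids[keep]
}

#' Compute a subjects-by-edges matrix from parcel time series
#'
#' Applies [ridge_partial_cor()] then [fisher_z()] per subject and stacks
#' the canonical upper-triangle edge vectors.
#'
#' @param ts_list named list of timepoints x parcels matrices, one per
#'   subject.
#' @param rho ridge penalty passed to [ridge_partial_cor()].
#' @return subjects x edges matrix; rows named by subject, columns by
#'   [edge_names()].
#' @export
compute_edges <- function(ts_list, rho = 0.1) {
  stopifnot(is.list(ts_list), length(ts_list) >= 1)
  P <- ncol(ts_list[[1]])
  E <- vapply(ts_list, function(ts) {
    if (ncol(ts) != P) stop("all subjects must have the same parcel count")
    vectorize_edges(fisher_z(ridge_partial_cor(ts, rho)))
  }, numeric(P * (P - 1L) / 2))
  E <- t(E)
  colnames(E) <- edge_names(P)
  rownames(E) <- names(ts_list)
  E
}
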