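#' Canonical edge indexing for an upper-triangle connectome
#'
#' Edges of a `P`-node connectome are stored as a vector over the upper
#' triangle of the node-by-node matrix in row-major order:
#' (1,2), (1,3), ..., (1,P), (2,3), ..., (P-1,P). A 100-node parcellation
#' therefore yields `choose(100, 2) = 4950` edges.
#'
#' @param i,j 1-based node indices with `i < j` (vectorised).
#' @param P number of nodes.
#' @return `edge_id()` returns the 1-based position of edge (i,j) in the
#'   canonical vector; `edge_index()` returns a data frame with columns
#'   `i`, `j` enumerating all `P(P-1)/2` edges in canonical order.
#' @examples
#' edge_id(1, 2, 100)   # 1
#' edge_id(99, 100, 100) # 4950
#' @export
edge_id <- function(i, j, P) {
  if (any(i < 1L) || any(j > P)) stop("node indices must lie in 1..P")
  if (any(i >= j)) stop("edge indices require i < j")
  as.integer((i - 1L) * P - i * (i - 1L) / 2 + (j - i))
}

#' @rdname edge_id
#' @export
edge_index <- function(P) {
  stopifnot(P >= 2)
  i <- rep.int(seq_len(P - 1L), times = (P - 1L):1L)
  j <- unlist(lapply(seq_len(P - 1L), function(a) (a + 1L):P), use.names = FALSE)
  data.frame(i = i, j = as.integer(j))
}

#' Edge column names in canonical order ("e_i_j")
#' @param P number of nodes.
#' @return character vector of length `P(P-1)/2`.
#' @export
edge_names <- function(P) {
  idx <- edge_index(P)
  paste0("e_", idx$i, "_", idx$j)
}

#' Vectorize and devectorize symmetric edge matrices
#'
#' `vectorize_edges()` extracts the upper triangle of a symmetric matrix in
#' canonical row-major order; `devectorize_edges()` is its exact inverse,
#' rebuilding a symmetric matrix with zero diagonal.
#'
#' @param m symmetric `P x P` matrix.
#' @param v edge vector of length `P(P-1)/2`.
#' @param P number of nodes (inferred from `length(v)` when missing).
#' @return a numeric vector, resp. a symmetric matrix with zero diagonal.
#' @export
vectorize_edges <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  # row-major upper triangle == column-major lower triangle of the transpose;
  # for symmetric input the lower triangle itself suffices
  m[lower.tri(m)]
}

#' @rdname vectorize_edges
#' @export
devectorize_edges <- function(v, P = NULL) {
  if (is.null(P)) {
    P <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (P != round(P)) stop("length(v) is not P(P-1)/2 for integer P")
    P <- as.integer(P)
  }
  if (length(v) != P * (P - 1L) / 2) stop("length(v) does not match P")
  m <- matrix(0, P, P)
  m[lower.tri(m)] <- v
  m + t(m)
}

#' Fisher z-transformation of correlations
#'
#' `atanh(r)`, the variance-stabilizing transform applied to every edge
#' before multivariate analysis. Values with `|r| >= 1` are clipped to
#' `+/-(1 - 1e-7)` with a warning.
#'
#' @param r correlation value, vector or matrix; entries in (-1, 1).
#' @return transformed values with the same shape.
#' @export
fisher_z <- function(r) {
  bad <- is.finite(r) & abs(r) >= 1
  if (any(bad)) {
    warning(sum(bad), " correlation(s) with |r| >= 1 clipped before atanh")
    r[bad] <- sign(r[bad]) * (1 - 1e-7)
  }
  atanh(r)
}
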