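#' Project data through fitted salience weights
#'
#' Derives subject scores for a new sample by multiplying its data —
#' processed with the same rank/z pipeline used at fitting time — with
#' salience weights estimated elsewhere. Projecting a sample onto its own
#' fitted saliences reproduces its native scores exactly.
#'
#' @param weights features x n_LV matrix (a transposed salience block), or
#'   a numeric vector for a single LV.
#' @param data subjects x features matrix in the same canonical feature
#'   order as the weights.
#' @param mode,do_rank processing settings matching the source model.
#' @return subjects x n_LV score matrix.
#' @export
project_scores <- function(weights, data, mode = "spearman", do_rank = TRUE) {
  if (!is.matrix(weights)) weights <- matrix(weights, ncol = 1)
  if (ncol(data) != nrow(weights))
    stop("feature mismatch: data has ", ncol(data), " columns but weights have ",
         nrow(weights), " rows")
  pls_process(data, mode, do_rank) %*% weights
}

# one direction: project A's saliences into B's data, correlate with B's
# native scores per LV (Pearson). The permutation null breaks B's
# brain-behaviour pairing (shuffling B's behaviour rows) and refits B's
# saliences each time, so chance alignment between independently estimated
# salience vectors is part of the null; p is two-sided on |r|, add-one.
replicate_direction <- function(model_a, X_b, Y_b, model_b, n_perm, seed) {
  L <- min(length(model_a$singular_values), length(model_b$singular_values))
  if (length(model_a$singular_values) != length(model_b$singular_values))
    warning("LV counts differ; comparing the first ", L, " LVs")
  Xp <- pls_process(X_b, model_b$mode, model_b$rank_x)
  Yp <- pls_process(Y_b, model_b$mode, TRUE)
  proj_brain <- Xp %*% t(model_a$brain_saliences[seq_len(L), , drop = FALSE])
  proj_behav <- Yp %*% t(model_a$behaviour_saliences[seq_len(L), , drop = FALSE])
  nat_brain <- model_b$brain_scores[, seq_len(L), drop = FALSE]
  nat_behav <- model_b$behaviour_scores[, seq_len(L), drop = FALSE]
  r_brain <- vapply(seq_len(L), function(l)
    stats::cor(proj_brain[, l], nat_brain[, l]), numeric(1))
  r_behav <- vapply(seq_len(L), function(l)
    stats::cor(proj_behav[, l], nat_behav[, l]), numeric(1))
  n <- nrow(X_b)
  exceed_brain <- exceed_behav <- rep(0L, L)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    vec <- pls_vectors(Xp, Yp[sample.int(n), , drop = FALSE], model_b)
    nb <- Xp %*% vec$v[, seq_len(L), drop = FALSE]
    ny <- Yp %*% vec$u[, seq_len(L), drop = FALSE]
    for (l in seq_len(L)) {
      if (abs(stats::cor(proj_brain[, l], nb[, l])) >= abs(r_brain[l]))
        exceed_brain[l] <- exceed_brain[l] + 1L
      if (abs(stats::cor(proj_behav[, l], ny[, l])) >= abs(r_behav[l]))
        exceed_behav[l] <- exceed_behav[l] + 1L
    }
  }
  list(r_brain = r_brain, p_brain = (1 + exceed_brain) / (n_perm + 1),
       r_behav = r_behav, p_behav = (1 + exceed_behav) / (n_perm + 1))
}

#' Cross-sample replication of latent variables
#'
#' Applies each sample's salience weights to the other sample's data and
#' correlates the derived subject scores with the natively estimated ones
#' (Pearson), separately for the brain (connectivity) and behaviour sides.
#' Significance per direction is a permutation test that breaks the target
#' sample's brain-behaviour pairing (shuffling its behaviour rows) and
#' refits that sample's saliences on every draw, so the null distribution
#' of the correlation includes chance alignment between independently
#' estimated salience vectors (two-sided on `|r|`, add-one formula). An LV
#' is flagged as replicated on a given side when the correlations in both
#' directions are significant at `alpha`.
#'
#' @param model_a,model_b `pls_model`s fitted on samples A and B with
#'   identical preprocessing settings.
#' @param X_a,Y_a,X_b,Y_b the two samples' data blocks.
#' @param n_perm permutations per direction (the reference analysis used
#'   5000).
#' @param alpha significance level for the both-directions rule.
#' @param seed integer seed.
#' @return a `replication_result`: list with per-side data frames (`brain`,
#'   `behaviour`) holding `lv`, `r_ab`, `p_ab`, `r_ba`, `p_ba`,
#'   `replicated`, plus `n_perm`, `alpha`, `seed`.
#' @export
cross_replicate <- function(model_a, X_a, Y_a, model_b, X_b, Y_b,
                            n_perm = 5000, alpha = 0.05, seed = 1) {
  stopifnot(inherits(model_a, "pls_model"), inherits(model_b, "pls_model"),
            n_perm >= 1)
  if (!identical(model_a$mode, model_b$mode) ||
      !identical(model_a$rank_x, model_b$rank_x))
    stop("models were fitted with different processing settings")
  ab <- replicate_direction(model_a, X_b, Y_b, model_b, n_perm, seed)
  ba <- replicate_direction(model_b, X_a, Y_a, model_a, n_perm, seed + 1L)
  L <- length(ab$r_brain)
  side_table <- function(rab, pab, rba, pba) data.frame(
    lv = seq_len(L), r_ab = rab, p_ab = pab, r_ba = rba, p_ba = pba,
    replicated = (pab < alpha) & (pba < alpha)
  )
  structure(
    list(brain = side_table(ab$r_brain, ab$p_brain, ba$r_brain, ba$p_brain),
         behaviour = side_table(ab$r_behav, ab$p_behav, ba$r_behav, ba$p_behav),
         n_perm = n_perm, alpha = alpha, seed = seed),
    class = "replication_result"
  )
}

#' Score derivation through an external weight chain
#'
#' Composes a dimension-reduction projection (e.g. PCA weights estimated
#' in another cohort) with PLS salience weights from that cohort:
#' `scores = processed data x reduction_weights x pls_weights`. With an
#' identity reduction this equals [project_scores()].
#'
#' @param reduction_weights features x components matrix.
#' @param pls_weights components x n_LV matrix.
#' @param data subjects x features matrix.
#' @inheritParams project_scores
#' @return subjects x n_LV score matrix.
#' @export
external_weight_transfer <- function(reduction_weights, pls_weights, data,
                                     mode = "spearman", do_rank = TRUE) {
  if (!is.matrix(reduction_weights))
    reduction_weights <- matrix(reduction_weights, ncol = 1)
  if (!is.matrix(pls_weights)) pls_weights <- matrix(pls_weights, ncol = 1)
  if (ncol(data) != nrow(reduction_weights))
    stop("chain mismatch: data has ", ncol(data),
         " features but reduction weights expect ", nrow(reduction_weights))
  if (ncol(reduction_weights) != nrow(pls_weights))
    stop("chain mismatch: ", ncol(reduction_weights),
         " components vs PLS weights for ", nrow(pls_weights))
  project_scores(reduction_weights %*% pls_weights, data, mode, do_rank)
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("Cross-sample replication (n_perm = %d, alpha = %g)\n",
              x$n_perm, x$alpha))
  cat("brain side:\n")
  print(x$brain, row.names = FALSE, digits = 3)
  cat("behaviour side:\n")
  print(x$behaviour, row.names = FALSE, digits = 3)
  invisible(x)
}
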