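#' Rank-transform then z-score each column
#'
#' Replaces every column by average ranks (ties averaged) and standardizes
#' to mean 0, population standard deviation 1 (denominator `n`). Running
#' Pearson machinery on this output implements Spearman rank correlation;
#' the output is invariant under strictly increasing transforms of any
#' column.
#'
#' @param x complete numeric matrix (subjects x features).
#' @return matrix of rank-z scores, same dimnames.
#' @export
rank_z <- function(x) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop("rank_z requires a complete matrix")
  n <- nrow(x)
  r <- apply(x, 2L, rank, ties.method = "average")
  mu <- colMeans(r)
  sdp <- sqrt(colMeans(sweep(r, 2L, mu, "-")^2))   # population SD
  const <- sdp < .Machine$double.eps^0.5
  sdp[const] <- 1
  z <- sweep(sweep(r, 2L, mu, "-"), 2L, sdp, "/")
  z[, const] <- 0
  dimnames(z) <- dimnames(x)
  z
}

# mode-dependent block processing shared by fitting and projection:
# spearman + do_rank -> rank_z; otherwise z-score (sample SD)
pls_process <- function(x, mode, do_rank = TRUE) {
  if (identical(mode, "spearman") && do_rank) rank_z(x) else zscore_columns(x)
}

# cross-block correlation with a guard for zero-variance columns
cross_cor <- function(Yp, Xp) {
  suppressWarnings(R <- stats::cor(Yp, Xp))
  if (anyNA(R)) {
    warning("constant column(s) in a block; their cross-correlations set to 0")
    R[is.na(R)] <- 0
  }
  R
}

lv_score_cor <- function(bs, ys) {
  vapply(seq_len(ncol(bs)), function(l) {
    if (stats::sd(bs[, l]) == 0 || stats::sd(ys[, l]) == 0) return(NA_real_)
    stats::cor(bs[, l], ys[, l])
  }, numeric(1))
}

#' Rotated behavioural PLS correlation
#'
#' Singular value decomposition of the cross-block correlation matrix
#' between a behaviour block and an edge (connectivity) block. In
#' `"spearman"` mode both blocks are rank-transformed ([rank_z()]) before
#' the Pearson machinery, so the decomposed matrix holds Spearman rank
#' correlations; with `rank_x = FALSE` only the behaviour block is ranked.
#' The decomposition yields one latent variable (LV) per behaviour variable
#' (when there are fewer behaviour variables than edges): paired unit-norm
#' salience vectors, subject scores by projection, the correlation between
#' the paired score vectors, and the percentage of cross-block covariance
#' explained (`100 s_l^2 / sum s^2`). Signs are fixed so the
#' largest-magnitude element of each behaviour salience is positive.
#'
#' @param X subjects x edges matrix.
#' @param Y subjects x behaviour-variables matrix (same subject order).
#' @param mode `"spearman"` (default) or `"pearson"`.
#' @param rank_x rank-transform the edge block too in spearman mode
#'   (default `TRUE`).
#' @return a `pls_model`: list with `singular_values`, `brain_saliences`
#'   (LV x edges), `behaviour_saliences` (LV x variables), `brain_scores`,
#'   `behaviour_scores` (subjects x LV), `lv_corr`, `covexp`, `mode`,
#'   `rotated`, `rank_x`.
#' @export
rotated_pls <- function(X, Y, mode = c("spearman", "pearson"), rank_x = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  if (nrow(X) < 3) stop("at least 3 subjects are required")
  Xp <- pls_process(X, mode, rank_x)
  Yp <- pls_process(Y, mode, TRUE)
  R <- cross_cor(Yp, Xp)
  sv <- svd(R)
  L <- length(sv$d)
  u <- sv$u
  v <- sv$v
  for (l in seq_len(L)) {
    jm <- which.max(abs(u[, l]))
    if (u[jm, l] < 0) {
      u[, l] <- -u[, l]
      v[, l] <- -v[, l]
    }
  }
  brain_scores <- Xp %*% v
  behaviour_scores <- Yp %*% u
  lvn <- paste0("LV", seq_len(L))
  dimnames(brain_scores) <- list(rownames(X), lvn)
  dimnames(behaviour_scores) <- list(rownames(Y), lvn)
  model <- list(
    singular_values = sv$d,
    brain_saliences = structure(t(v), dimnames = list(lvn, colnames(X))),
    behaviour_saliences = structure(t(u), dimnames = list(lvn, colnames(Y))),
    brain_scores = brain_scores,
    behaviour_scores = behaviour_scores,
    lv_corr = lv_score_cor(brain_scores, behaviour_scores),
    covexp = covexp_table(sv$d),
    mode = mode,
    rotated = TRUE,
    rank_x = rank_x,
    n = nrow(X)
  )
  class(model) <- "pls_model"
  model
}

#' Build single-diagnosis contrasts
#'
#' One contrast row per diagnosis column (optionally excluding a reference
#' such as `"no_diagnosis"`), each testing that diagnosis while the others
#' are controlled for via [nonrotated_pls()]'s `control` scheme.
#'
#' @param y_names column names of the diagnosis block.
#' @param exclude names to skip (default `"no_diagnosis"`).
#' @return contrasts matrix (n_contrast x n_vars) with named rows/columns.
#' @export
diagnosis_contrasts <- function(y_names, exclude = "no_diagnosis") {
  targets <- setdiff(y_names, exclude)
  if (length(targets) == 0) stop("no diagnosis columns left after exclusion")
  C <- matrix(0, length(targets), length(y_names),
              dimnames = list(targets, y_names))
  C[cbind(seq_along(targets), match(targets, y_names))] <- 1
  C
}

#' Non-rotated (contrast) behavioural PLS
#'
#' Instead of letting the SVD rotate the behaviour space, each latent
#' variable is pinned to a user-specified contrast over behaviour columns
#' (rows of `contrasts`, normalized to unit norm). The brain salience for
#' contrast `c` is `R' c / ||R' c||` with singular value `||R' c||`, where
#' `R` is the cross-block correlation matrix. With
#' `control = "residualize_target"` every behaviour column involved in a
#' contrast is first residualized on the block's remaining columns, so a
#' single-diagnosis contrast tests that diagnosis while controlling for all
#' other diagnosis categories.
#'
#' @inheritParams rotated_pls
#' @param contrasts n_contrast x n_vars numeric matrix; columns must match
#'   `colnames(Y)` when named.
#' @param control `"residualize_target"` (default) or `"none"`.
#' @return a `pls_model` with `rotated = FALSE`; one LV per contrast, in
#'   row order of `contrasts`.
#' @export
nonrotated_pls <- function(X, Y, contrasts,
                           control = c("residualize_target", "none"),
                           mode = c("spearman", "pearson"), rank_x = TRUE) {
  control <- match.arg(control)
  mode <- match.arg(mode)
  stopifnot(is.matrix(X), is.matrix(Y), nrow(X) == nrow(Y))
  if (nrow(X) < 3) stop("at least 3 subjects are required")
  if (!is.matrix(contrasts)) contrasts <- matrix(contrasts, nrow = 1)
  if (ncol(contrasts) != ncol(Y)) {
    if (!is.null(colnames(contrasts)) && all(colnames(contrasts) %in% colnames(Y))) {
      full <- matrix(0, nrow(contrasts), ncol(Y),
                     dimnames = list(rownames(contrasts), colnames(Y)))
      full[, colnames(contrasts)] <- contrasts
      contrasts <- full
    } else {
      stop("contrast columns (", ncol(contrasts),
           ") do not match behaviour variables (", ncol(Y), ")")
    }
  }
  nrm <- sqrt(rowSums(contrasts^2))
  if (any(nrm < .Machine$double.eps^0.5))
    stop("contrast row(s) are zero after normalization")
  Cn <- contrasts / nrm
  L <- nrow(Cn)

  Xp <- pls_process(X, mode, rank_x)
  Yp <- pls_process(Y, mode, TRUE)
  n <- nrow(Xp)
  lvn <- if (!is.null(rownames(Cn))) rownames(Cn) else paste0("LV", seq_len(L))

  s <- numeric(L)
  V <- matrix(0, ncol(X), L)
  brain_scores <- matrix(0, n, L, dimnames = list(rownames(X), lvn))
  behaviour_scores <- matrix(0, n, L, dimnames = list(rownames(Y), lvn))
  for (l in seq_len(L)) {
    cl <- Cn[l, ]
    cf <- contrast_fit(Xp, Yp, cl, control)
    s[l] <- cf$s
    if (s[l] < .Machine$double.eps^0.5)
      warning("contrast ", lvn[l], " has a numerically zero singular value")
    V[, l] <- if (s[l] > 0) cf$u_raw / s[l] else 0
    brain_scores[, l] <- Xp %*% V[, l]
    Ymod <- Yp
    Ymod[, cf$targets] <- cf$ytargets
    behaviour_scores[, l] <- Ymod %*% cl
  }
  model <- list(
    singular_values = s,
    brain_saliences = structure(t(V), dimnames = list(lvn, colnames(X))),
    behaviour_saliences = structure(Cn, dimnames = list(lvn, colnames(Y))),
    brain_scores = brain_scores,
    behaviour_scores = behaviour_scores,
    lv_corr = lv_score_cor(brain_scores, behaviour_scores),
    covexp = covexp_table(s),
    mode = mode,
    rotated = FALSE,
    rank_x = rank_x,
    contrasts = Cn,
    control = control,
    n = n
  )
  class(model) <- "pls_model"
  model
}

# one contrast on processed blocks: optional control residualization of the
# involved behaviour columns on the remaining ones, then u_raw = R' c
contrast_fit <- function(Xp, Yp, cl, control) {
  targets <- which(abs(cl) > 0)
  ytargets <- Yp[, targets, drop = FALSE]
  if (control == "residualize_target" && length(targets) < ncol(Yp)) {
    qr_o <- qr(cbind(1, Yp[, -targets, drop = FALSE]))
    ytargets <- qr.resid(qr_o, ytargets)
  }
  Rl <- cross_cor(ytargets, Xp)
  u_raw <- drop(crossprod(Rl, cl[targets]))
  list(u_raw = u_raw, s = sqrt(sum(u_raw^2)),
       targets = targets, ytargets = ytargets)
}

# salience vectors (v: edges x L, u: vars x L), on already-processed blocks
# (used in replication permutations; signs left arbitrary)
pls_vectors <- function(Xp, Yp, model) {
  if (isTRUE(model$rotated)) {
    sv <- svd(cross_cor(Yp, Xp))
    list(v = sv$v, u = sv$u)
  } else {
    L <- nrow(model$contrasts)
    v <- matrix(0, ncol(Xp), L)
    for (l in seq_len(L)) {
      cf <- contrast_fit(Xp, Yp, model$contrasts[l, ], model$control)
      if (cf$s > 0) v[, l] <- cf$u_raw / cf$s
    }
    list(v = v, u = t(model$contrasts))
  }
}

# singular values only, on already-processed blocks (used in permutations)
pls_sv <- function(Xp, Yp, model) {
  if (isTRUE(model$rotated)) {
    svd(cross_cor(Yp, Xp), nu = 0, nv = 0)$d
  } else {
    vapply(seq_len(nrow(model$contrasts)), function(l)
      contrast_fit(Xp, Yp, model$contrasts[l, ], model$control)$s, numeric(1))
  }
}

# single entry point used by permutation/bootstrap refits
refit_pls <- function(X, Y, model) {
  if (isTRUE(model$rotated)) {
    rotated_pls(X, Y, mode = model$mode, rank_x = model$rank_x)
  } else {
    nonrotated_pls(X, Y, contrasts = model$contrasts, control = model$control,
                   mode = model$mode, rank_x = model$rank_x)
  }
}

#' Loadings: correlations between LV scores and original data
#'
#' For each latent variable, the brain loading of an edge is the Pearson
#' correlation between the subjects' brain scores and that edge's original
#' (pre-rank, original-scale) values; behaviour loadings are analogous with
#' the behaviour scores. Constant features get loading 0 with a warning.
#'
#' @param model fitted `pls_model`.
#' @param X,Y the original data blocks the model was fitted on.
#' @return list with `brain_loadings` (LV x edges) and `behaviour_loadings`
#'   (LV x variables), entries in \[-1, 1\].
#' @export
pls_loadings <- function(model, X, Y) {
  stopifnot(inherits(model, "pls_model"),
            nrow(X) == nrow(model$brain_scores),
            nrow(Y) == nrow(model$behaviour_scores))
  load_block <- function(scores, data) {
    sds <- apply(data, 2L, stats::sd)
    const <- sds < .Machine$double.eps^0.5
    if (any(const))
      warning(sum(const), " constant feature(s); loading set to 0")
    suppressWarnings(r <- stats::cor(scores, data))
    r[, const] <- 0
    r[is.na(r)] <- 0
    r
  }
  list(
    brain_loadings = load_block(model$brain_scores, X),
    behaviour_loadings = load_block(model$behaviour_scores, Y)
  )
}

#' Percent cross-block covariance explained per LV
#'
#' `100 s_l^2 / sum(s^2)`; always sums to 100.
#'
#' @param s nonnegative singular values, not all zero.
#' @return numeric vector of percentages.
#' @export
covexp_table <- function(s) {
  stopifnot(all(s >= 0))
  tot <- sum(s^2)
  if (tot <= 0) stop("all singular values are zero")
  100 * s^2 / tot
}

#' Numeric scree elbow (advisory)
#'
#' Returns the LV index maximizing the second difference of the
#' percent-covariance-explained sequence — a numeric stand-in for visual
#' scree inspection. LV selection remains the analyst's decision.
#'
#' @param s singular values (length >= 3).
#' @return integer index of the elbow.
#' @export
scree_elbow <- function(s) {
  ce <- covexp_table(s)
  if (length(ce) < 3) return(1L)
  d2 <- ce[seq_len(length(ce) - 2L)] - 2 * ce[seq(2L, length(ce) - 1L)] +
    ce[seq(3L, length(ce))]
  as.integer(which.max(d2) + 1L)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("%s behavioural PLS (%s mode), %d subjects, %d LVs\n",
              if (x$rotated) "Rotated" else "Non-rotated (contrast)",
              x$mode, x$n, length(x$singular_values)))
  tab <- data.frame(
    LV = seq_along(x$singular_values),
    singular_value = round(x$singular_values, 4),
    covexp_pct = round(x$covexp, 2),
    score_r = round(x$lv_corr, 3)
  )
  if (!is.null(x$perm_p)) tab$perm_p <- signif(x$perm_p, 3)
  print(utils::head(tab, 10), row.names = FALSE)
  if (nrow(tab) > 10) cat("... (", nrow(tab) - 10, " more LVs)\n", sep = "")
  invisible(x)
}
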