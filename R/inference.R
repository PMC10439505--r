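#' Permutation test of latent-variable significance
#'
#' Shuffles the behaviour block's subject rows, refits the same
#' decomposition (rotated or contrast), and records the singular values in
#' LV order. The p-value for LV `l` is the add-one Monte-Carlo estimate
#' `(1 + #\{perm s_l >= observed s_l\}) / (n_perm + 1)`, comparing LV slot
#' to LV slot. With `max_stat = TRUE` every observed singular value is
#' instead compared against the permutation distribution of the largest
#' singular value (a stricter, familywise-style variant).
#'
#' Because column ranks and within-block residualization commute with a
#' joint permutation of subject rows, the blocks are processed once and the
#' processed behaviour rows are permuted, which is exactly equivalent to
#' refitting from raw data.
#'
#' @param X,Y the data blocks the model was fitted on.
#' @param model fitted `pls_model`.
#' @param n_perm number of permutations (>= 1; the reference analysis used
#'   5000).
#' @param seed integer seed for the permutation stream.
#' @param max_stat compare against the permuted largest singular value.
#' @return a `perm_result`: list with `n_perm`, `observed_s`, `perm_s`
#'   (n_perm x n_LV), `p_values`, `seed`, `max_stat`.
#' @export
permutation_test <- function(X, Y, model, n_perm = 5000, seed = 1,
                             max_stat = FALSE) {
  stopifnot(inherits(model, "pls_model"), n_perm >= 1,
            nrow(X) == model$n, nrow(Y) == model$n)
  Xp <- pls_process(X, model$mode, model$rank_x)
  Yp <- pls_process(Y, model$mode, TRUE)
  obs <- model$singular_values
  L <- length(obs)
  n <- nrow(X)
  set.seed(seed)
  perm_s <- matrix(NA_real_, n_perm, L)
  for (b in seq_len(n_perm)) {
    d <- pls_sv(Xp, Yp[sample.int(n), , drop = FALSE], model)
    perm_s[b, ] <- d[seq_len(L)]
  }
  ref <- if (max_stat) perm_s[, 1L] else perm_s
  p <- vapply(seq_len(L), function(l) {
    cmp <- if (max_stat) ref else perm_s[, l]
    (1 + sum(cmp >= obs[l])) / (n_perm + 1)
  }, numeric(1))
  structure(
    list(n_perm = n_perm, observed_s = obs, perm_s = perm_s,
         p_values = p, seed = seed, max_stat = max_stat),
    class = "perm_result"
  )
}

#' Bootstrap stability (pseudo-z) of edge saliences
#'
#' Resamples subjects with replacement, refits the model from raw data
#' (ranks are recomputed within each resample), aligns each bootstrap
#' salience to the original by sign (flipped when the dot product with the
#' original brain salience is negative; LV order is kept), and forms the
#' bootstrap ratio `bsr[l, e] = original salience / SD over bootstrap
#' saliences`. Edges with `|bsr|` strictly greater than `threshold` form
#' the stable-edge mask. A zero bootstrap SD yields `bsr = +/-cap`
#' (0 when the original salience is also 0); draws with fewer than 3
#' distinct subjects are redrawn.
#'
#' @inheritParams permutation_test
#' @param n_boot number of bootstrap resamples (>= 2; the reference
#'   analysis used 1000).
#' @param threshold pseudo-z stability threshold (default 3, strict).
#' @param cap value substituted for an infinite ratio (default 50).
#' @return a `boot_stability`: list with `n_boot`, `bsr` (n_LV x n_edges),
#'   `stable_mask`, `threshold`, `seed`.
#' @export
bootstrap_stability <- function(X, Y, model, n_boot = 1000, threshold = 3,
                                seed = 1, cap = 50) {
  stopifnot(inherits(model, "pls_model"), n_boot >= 2,
            nrow(X) == model$n, nrow(Y) == model$n)
  n <- nrow(X)
  orig <- model$brain_saliences
  L <- nrow(orig)
  E <- ncol(orig)
  set.seed(seed)
  s1 <- matrix(0, L, E)
  s2 <- matrix(0, L, E)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= 3) break
    }
    mb <- suppressWarnings(refit_pls(X[idx, , drop = FALSE],
                                     Y[idx, , drop = FALSE], model))
    sal <- mb$brain_saliences[seq_len(L), , drop = FALSE]
    flip <- rowSums(sal * orig) < 0
    sal[flip, ] <- -sal[flip, , drop = FALSE]
    s1 <- s1 + sal
    s2 <- s2 + sal^2
  }
  sd_boot <- sqrt(pmax(s2 - s1^2 / n_boot, 0) / (n_boot - 1))
  bsr <- orig / sd_boot
  zero_sd <- sd_boot < .Machine$double.eps^0.5
  bsr[zero_sd] <- cap * sign(orig[zero_sd])
  dimnames(bsr) <- dimnames(orig)
  structure(
    list(n_boot = n_boot, bsr = bsr, stable_mask = abs(bsr) > threshold,
         threshold = threshold, seed = seed),
    class = "boot_stability"
  )
}

#' Indices of significant latent variables
#'
#' LVs with permutation `p < alpha`; no multiplicity correction is applied,
#' matching the raw per-LV reporting convention.
#'
#' @param perm a `perm_result`.
#' @param alpha significance level (default 0.05).
#' @return integer vector of LV indices.
#' @export
significant_lvs <- function(perm, alpha = 0.05) {
  stopifnot(inherits(perm, "perm_result"))
  which(perm$p_values < alpha)
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test (n_perm = %d%s, seed = %d)\n", x$n_perm,
              if (x$max_stat) ", max-statistic" else "", x$seed))
  print(data.frame(LV = seq_along(x$observed_s),
                   s = round(x$observed_s, 4),
                   p = signif(x$p_values, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
print.boot_stability <- function(x, ...) {
  cat(sprintf("Bootstrap stability (n_boot = %d, |pseudo-z| > %g)\n",
              x$n_boot, x$threshold))
  cat("stable edges per LV:", rowSums(x$stable_mask), "\n")
  invisible(x)
}
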