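# Brain-behavior covariation: random-forest imputation of behavioral scales,
# PCA reduction of the deviation table, canonical correlation analysis with
# out-of-sample cross-validation, and a within-site permutation null.

behavior_matrix <- function(behavior) {
  if (is.data.frame(behavior)) {
    num <- behavior[setdiff(names(behavior), "subject_id")]
    as.matrix(num)
  } else {
    as.matrix(behavior)
  }
}

#' Iterative random-forest imputation of behavioral scales
#'
#' Missing cells are initialized with column medians, then columns are
#' revisited (most complete first) fitting a random-forest regression of
#' each column on the others over its observed rows and predicting its
#' missing cells, until the largest cell change drops below `tol` or
#' `max_sweeps` sweeps. Observed cells are never altered.
#'
#' @param behavior Data frame (optionally with a `subject_id` column) or
#'   matrix of behavioral scales, `NA` for missing.
#' @param seed Integer seed (forest fitting is stochastic).
#' @param max_sweeps,tol Stopping rule (defaults 10 sweeps, 1e-3).
#' @param ntree Trees per forest (default 100).
#' @return Object of the same shape with no missing cells.
#' @export
impute_behavior_rf <- function(behavior, seed = 1L, max_sweeps = 10L,
                               tol = 1e-3, ntree = 100L) {
  M <- behavior_matrix(behavior)
  n <- nrow(M)
  if (n < 20L) stop("need at least 20 subjects for imputation")
  fully_missing <- colSums(!is.na(M)) == 0L
  if (any(fully_missing)) {
    stop(sprintf("fully missing column(s): %s",
                 paste(colnames(M)[fully_missing], collapse = ", ")))
  }
  miss <- is.na(M)
  if (!any(miss)) return(behavior)

  with_seed(seed, {
    X <- M
    for (j in seq_len(ncol(X))) {
      X[miss[, j], j] <- stats::median(M[, j], na.rm = TRUE)
    }
    order_cols <- order(colSums(miss))
    for (sweep_i in seq_len(max_sweeps)) {
      max_change <- 0
      for (j in order_cols) {
        if (!any(miss[, j])) next
        obs <- !miss[, j]
        rf <- randomForest::randomForest(
          x = X[obs, -j, drop = FALSE], y = M[obs, j], ntree = ntree)
        pred <- stats::predict(rf, X[miss[, j], -j, drop = FALSE])
        max_change <- max(max_change, abs(pred - X[miss[, j], j]))
        X[miss[, j], j] <- pred
      }
      if (max_change < tol) break
    }
    if (is.data.frame(behavior)) {
      out <- behavior
      out[colnames(X)] <- as.data.frame(X)
      out
    } else {
      X
    }
  })
}

# Principal decomposition of a centered matrix, via the Gram matrix when
# subjects are fewer than edges. Scores are in the same row order as X.
pca_train <- function(X, k) {
  n <- nrow(X); p <- ncol(X)
  if (k >= n) stop(sprintf("`k` (%d) must be below the number of subjects (%d)",
                           k, n))
  k <- min(k, p)
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  if (n <= p) {
    e <- eigen(tcrossprod(Xc), symmetric = TRUE)
    ev <- pmax(e$values, 0)
    d <- sqrt(ev[seq_len(k)])
    d_safe <- pmax(d, 1e-12)
    basis <- crossprod(Xc, e$vectors[, seq_len(k), drop = FALSE])
    basis <- basis / rep(d_safe, each = p)
    scores <- e$vectors[, seq_len(k), drop = FALSE] * rep(d_safe, each = n)
    eigvals <- ev / (n - 1)
  } else {
    e <- eigen(crossprod(Xc) / (n - 1), symmetric = TRUE)
    eigvals <- pmax(e$values, 0)
    basis <- e$vectors[, seq_len(k), drop = FALSE]
    scores <- Xc %*% basis
  }
  list(center = center, basis = basis, scores = scores,
       eigenvalues = eigvals,
       var_explained = eigvals[seq_len(k)] / sum(eigvals))
}

#' Principal-component reduction of a deviation table
#'
#' Column-centered principal decomposition of the subjects x edges deviation
#' matrix; the top `k` variance components (default 10) make the subsequent
#' CCA well-posed. Scores, the orthonormal edge basis (for back-projection)
#' and explained-variance fractions are retained.
#'
#' @param dev A `"deviance_table"` or subjects x E matrix (typically the
#'   autistic subjects only).
#' @param k Number of components (default 10; must be below the subject
#'   count).
#' @return List of class `"reduced_brain"`: `scores` (n x k), `basis`
#'   (E x k), `center` (E), `var_explained` (k fractions, decreasing),
#'   `eigenvalues`.
#' @export
reduce_dimensionality <- function(dev, k = 10L) {
  X <- if (inherits(dev, "deviance_table")) dev$z else as.matrix(dev)
  p <- pca_train(X, k)
  structure(p, class = "reduced_brain")
}

inv_sqrt_sym <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < tol * max(e$values)) {
    stop("rank-deficient block after standardization")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Canonical correlation analysis via whitened cross-covariance SVD
#'
#' Columns of both sides are standardized internally (training statistics
#' recorded for out-of-sample projection); canonical weight pairs come from
#' the singular decomposition of `Sxx^-1/2 Sxy Syy^-1/2`. The sign of each
#' weight pair is fixed so the SRS behavior weight (first behavior column if
#' no `"SRS"` column exists) is non-negative, making weights comparable
#' across refits.
#'
#' @param X,Y Numeric matrices, n x kx and n x ky, with `n > kx + ky`.
#' @return List of class `"cca_fit"`: `xweights` (kx x m), `yweights`
#'   (ky x m), `cors` (m canonical correlations, decreasing),
#'   `x_center`, `x_scale`, `y_center`, `y_scale`.
#' @export
cca_fit <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n <= ncol(X) + ncol(Y)) {
    stop("need more subjects than total variables (n > kx + ky)")
  }
  x_center <- colMeans(X); y_center <- colMeans(Y)
  x_scale <- apply(X, 2L, stats::sd); y_scale <- apply(Y, 2L, stats::sd)
  if (any(x_scale == 0) || any(y_scale == 0)) {
    stop("zero-variance column: rank deficiency after standardization")
  }
  Xs <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  Ys <- sweep(sweep(Y, 2L, y_center), 2L, y_scale, "/")
  Sxx <- crossprod(Xs) / (n - 1)
  Syy <- crossprod(Ys) / (n - 1)
  Sxy <- crossprod(Xs, Ys) / (n - 1)
  Kx <- inv_sqrt_sym(Sxx)
  Ky <- inv_sqrt_sym(Syy)
  sv <- svd(Kx %*% Sxy %*% Ky)
  m <- min(ncol(X), ncol(Y))
  wx <- Kx %*% sv$u[, seq_len(m), drop = FALSE]
  wy <- Ky %*% sv$v[, seq_len(m), drop = FALSE]
  rownames(wy) <- colnames(Y)
  srs_row <- if (!is.null(colnames(Y)) && "SRS" %in% colnames(Y)) {
    match("SRS", colnames(Y))
  } else {
    1L
  }
  # Sign convention: the SRS variable's structure correlation with the
  # behavior variate is non-negative (for standardized Y this is
  # (Syy w)[srs]), so loadings read along the impairment axis and weights
  # are comparable across refits.
  srs_load <- Syy %*% wy
  for (j in seq_len(m)) {
    flip <- if (srs_load[srs_row, j] != 0) srs_load[srs_row, j] < 0 else wy[srs_row, j] < 0
    if (flip) {
      wx[, j] <- -wx[, j]
      wy[, j] <- -wy[, j]
    }
  }
  structure(list(xweights = wx, yweights = wy,
                 cors = pmin(pmax(sv$d[seq_len(m)], 0), 1),
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, y_scale = y_scale),
            class = "cca_fit")
}

# Canonical variates of (possibly held-out) data under a fitted CCA.
cca_variates <- function(fit, X, Y) {
  Xs <- sweep(sweep(as.matrix(X), 2L, fit$x_center), 2L, fit$x_scale, "/")
  Ys <- sweep(sweep(as.matrix(Y), 2L, fit$y_center), 2L, fit$y_scale, "/")
  list(vx = Xs %*% fit$xweights, vy = Ys %*% fit$yweights)
}

# One tenfold out-of-sample pass: returns the pooled held-out first canonical
# correlation and (optionally) per-fold loading stabilities vs an all-data
# reference. Stability is measured on loadings (variable-variate
# correlations over the training fold) rather than raw weights, which are
# unstable under collinearity even when the variates are not; brain loadings
# are evaluated at the edge level so fold-specific component spaces are
# comparable.
oos_cca_pass <- function(B, Ybeh, fold, n_components, global_pca,
                         global_scores = NULL, global_basis = NULL,
                         ref_brain_load = NULL, ref_beh_load = NULL) {
  n <- nrow(Ybeh)
  k_folds <- max(fold)
  vx_pool <- numeric(n); vy_pool <- numeric(n)
  stab_b <- numeric(k_folds); stab_y <- numeric(k_folds)
  want_stab <- !is.null(ref_beh_load)
  for (f in seq_len(k_folds)) {
    te <- fold == f
    if (sum(te) < 2L) stop("fold with fewer than 2 subjects")
    if (global_pca) {
      Str <- global_scores[!te, , drop = FALSE]
      Ste <- global_scores[te, , drop = FALSE]
    } else {
      p <- pca_train(B[!te, , drop = FALSE], n_components)
      Str <- p$scores
      Ste <- sweep(B[te, , drop = FALSE], 2L, p$center) %*% p$basis
    }
    fit <- cca_fit(Str, Ybeh[!te, , drop = FALSE])
    vtr <- cca_variates(fit, Str, Ybeh[!te, , drop = FALSE])
    v <- cca_variates(fit, Ste, Ybeh[te, , drop = FALSE])
    vx_pool[te] <- v$vx[, 1L]
    vy_pool[te] <- v$vy[, 1L]
    if (want_stab) {
      brain_feat <- if (global_pca) Str else B[!te, , drop = FALSE]
      stab_b[f] <- stats::cor(drop(stats::cor(brain_feat, vtr$vx[, 1L])),
                              ref_brain_load)
      stab_y[f] <- stats::cor(drop(stats::cor(Ybeh[!te, , drop = FALSE],
                                              vtr$vy[, 1L])),
                              ref_beh_load)
    }
  }
  list(r = stats::cor(vx_pool, vy_pool),
       stability_brain = if (want_stab) mean(stab_b) else NA_real_,
       stability_behavior = if (want_stab) mean(stab_y) else NA_real_)
}

resolve_brain_input <- function(brain, n_components) {
  if (inherits(brain, "reduced_brain")) {
    list(B = NULL, global = brain, force_global = TRUE)
  } else {
    B <- if (inherits(brain, "deviance_table")) brain$z else as.matrix(brain)
    list(B = B, global = reduce_dimensionality(B, n_components),
         force_global = FALSE)
  }
}

#' Out-of-sample cross-validated CCA
#'
#' Repeats `n_splits` random partitions of the subjects into `k_folds`
#' folds. In each fold the dimensionality reduction, standardization and
#' CCA weights are fit on the training folds only; held-out subjects are
#' projected and their first-variate pairs pooled across folds into one
#' out-of-sample canonical correlation per split (pooling is stabler than
#' averaging ten small-fold correlations). Each split also records the mean
#' correlation between fold-training loadings (variable-variate structure
#' correlations; brain side at the edge level, so fold-specific component
#' spaces are comparable) and the all-data reference loadings, quantifying
#' the stability of the canonical mode.
#'
#' With `global_pca = TRUE` (or a pre-reduced `"reduced_brain"` input) the
#' principal decomposition is fit once on all subjects and only the
#' standardization and CCA are refit per fold - the literal form of a
#' one-global-reduction protocol, at the cost of a leakage caveat.
#'
#' @param brain Subjects x E deviation matrix, `"deviance_table"`, or
#'   `"reduced_brain"`.
#' @param behavior Complete subjects x scales matrix or data frame (impute
#'   first; see [impute_behavior_rf()]).
#' @param n_splits Number of random tenfold splits (default 1000).
#' @param k_folds Folds per split (default 10).
#' @param n_components Components kept by the reduction (default 10).
#' @param seed Integer seed.
#' @param global_pca Fit the reduction once on all subjects (default FALSE).
#' @return List of class `"cca_crossval"`: `test_dist` (n_splits pooled
#'   out-of-sample correlations), `stability_brain`, `stability_behavior`
#'   (n_splits each), `reference` (all-data fit: `fit`, `reduced`,
#'   `edge_weights`), plus the call parameters.
#' @export
crossval_cca <- function(brain, behavior, n_splits = 1000L, k_folds = 10L,
                         n_components = 10L, seed = 1L, global_pca = FALSE) {
  if (n_splits < 1L) stop("`n_splits` must be >= 1")
  Ybeh <- behavior_matrix(behavior)
  if (anyNA(Ybeh)) stop("behavior must be complete; impute first")
  bi <- resolve_brain_input(brain, n_components)
  if (bi$force_global) global_pca <- TRUE
  n <- nrow(Ybeh)
  if (n < 2L * k_folds) stop("need at least 2 * k_folds subjects")

  ref_fit <- cca_fit(bi$global$scores, Ybeh)
  ref_edge_w <- drop(bi$global$basis %*% ref_fit$xweights[, 1L])
  ref_v <- cca_variates(ref_fit, bi$global$scores, Ybeh)
  ref_brain_feat <- if (global_pca) bi$global$scores else bi$B
  ref_brain_load <- drop(stats::cor(ref_brain_feat, ref_v$vx[, 1L]))
  ref_beh_load <- drop(stats::cor(Ybeh, ref_v$vy[, 1L]))

  test_dist <- numeric(n_splits)
  stab_b <- numeric(n_splits); stab_y <- numeric(n_splits)
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      fold <- sample(rep_len(seq_len(k_folds), n))
      res <- oos_cca_pass(bi$B, Ybeh, fold, n_components, global_pca,
                          global_scores = bi$global$scores,
                          global_basis = bi$global$basis,
                          ref_brain_load = ref_brain_load,
                          ref_beh_load = ref_beh_load)
      test_dist[s] <- res$r
      stab_b[s] <- res$stability_brain
      stab_y[s] <- res$stability_behavior
    }
  })
  structure(list(test_dist = test_dist,
                 stability_brain = stab_b, stability_behavior = stab_y,
                 reference = list(fit = ref_fit, reduced = bi$global,
                                  edge_weights = ref_edge_w),
                 n_splits = n_splits, k_folds = k_folds,
                 n_components = n_components, global_pca = global_pca),
            class = "cca_crossval")
}

#' Within-site permutation null for the out-of-sample CCA
#'
#' Each permutation shuffles the behavior rows only within scanner-site
#' strata (preserving site structure while destroying the brain-behavior
#' coupling), then computes one tenfold pooled out-of-sample first canonical
#' correlation exactly as in [crossval_cca()]. A site with a single subject
#' leaves that subject unpermuted (with a warning).
#'
#' @inheritParams crossval_cca
#' @param site_labels Per-subject site labels.
#' @param n_permutations Number of permutations (default 1000).
#' @return Numeric vector of `n_permutations` null correlations.
#' @export
permutation_null_cca <- function(brain, behavior, site_labels,
                                 n_permutations = 1000L, k_folds = 10L,
                                 n_components = 10L, seed = 1L,
                                 global_pca = FALSE) {
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1")
  Ybeh <- behavior_matrix(behavior)
  if (anyNA(Ybeh)) stop("behavior must be complete; impute first")
  bi <- resolve_brain_input(brain, n_components)
  if (bi$force_global) global_pca <- TRUE
  n <- nrow(Ybeh)
  site_labels <- factor(site_labels)
  if (length(site_labels) != n) stop("`site_labels` must align with subjects")
  if (any(table(site_labels) < 2L)) {
    warning("site(s) with a single subject: those subjects are left unpermuted")
  }
  strata <- split(seq_len(n), site_labels)

  null_dist <- numeric(n_permutations)
  with_seed(seed, {
    for (s in seq_len(n_permutations)) {
      perm <- seq_len(n)
      for (idx in strata) {
        if (length(idx) > 1L) perm[idx] <- idx[sample.int(length(idx))]
      }
      fold <- sample(rep_len(seq_len(k_folds), n))
      res <- oos_cca_pass(bi$B, Ybeh[perm, , drop = FALSE], fold,
                          n_components, global_pca,
                          global_scores = bi$global$scores,
                          global_basis = bi$global$basis)
      null_dist[s] <- res$r
    }
  })
  null_dist
}

#' Significance decision for the cross-validated CCA
#'
#' The relationship is declared significant when the mean of the test
#' distribution exceeds the 95th percentile (configurable) of the
#' permutation null.
#'
#' @param test_dist Out-of-sample correlations from [crossval_cca()] (the
#'   `test_dist` element is extracted automatically).
#' @param null_dist Null correlations from [permutation_null_cca()].
#' @param percentile Null percentile to beat (default 95).
#' @return List: `significant`, `test_mean`, `null_quantile`,
#'   `exceedance` (fraction of null values at or above the test mean).
#' @export
assess_significance <- function(test_dist, null_dist, percentile = 95) {
  if (inherits(test_dist, "cca_crossval")) test_dist <- test_dist$test_dist
  if (length(test_dist) == 0L || length(null_dist) == 0L) {
    stop("test and null distributions must be nonempty")
  }
  tm <- mean(test_dist)
  nq <- unname(stats::quantile(null_dist, percentile / 100))
  list(significant = tm > nq, test_mean = tm, null_quantile = nq,
       exceedance = mean(null_dist >= tm))
}

#' Canonical loadings (structure correlations)
#'
#' The loading of a variable is the Pearson correlation between that
#' variable and its own side's first canonical variate; signs inherit the
#' convention of [cca_fit()] (SRS behavior weight non-negative).
#'
#' @param fit A `"cca_fit"`.
#' @param X,Y The data the loadings are evaluated on (any consistent set,
#'   typically the training data).
#' @return List: `brain` (kx loadings), `behavior` (ky loadings).
#' @export
canonical_loadings <- function(fit, X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (any(apply(X, 2L, stats::sd) == 0) || any(apply(Y, 2L, stats::sd) == 0)) {
    stop("zero-variance variable: loading undefined")
  }
  v <- cca_variates(fit, X, Y)
  list(brain = drop(stats::cor(X, v$vx[, 1L])),
       behavior = drop(stats::cor(Y, v$vy[, 1L])))
}

#' Back-project canonical brain weights to edge space
#'
#' Maps the first canonical brain weight vector from component space to edge
#' space through the reduction basis: `edge weights = basis x weights`.
#'
#' @param fit A `"cca_fit"` whose X side was the component scores.
#' @param basis A `"reduced_brain"` (its `basis` is used) or an E x k matrix
#'   from the same reduction used in the fit.
#' @return Numeric E-vector of edge-level weights.
#' @export
backproject_brain_weights <- function(fit, basis) {
  Bm <- if (inherits(basis, "reduced_brain")) basis$basis else as.matrix(basis)
  if (ncol(Bm) != nrow(fit$xweights)) {
    stop("basis and fit dimensions do not match")
  }
  drop(Bm %*% fit$xweights[, 1L])
}
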