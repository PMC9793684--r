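# Behavioral imputation, PCA reduction, CCA, out-of-sample cross-validation
# with permutation null, loadings and back-projection.

test_that("random-forest imputation respects observed cells and beats medians", {
  withr::with_seed(5, {
    n <- 100
    latent <- rnorm(n)
    M <- sapply(1:7, function(k) 0.9 * latent + rnorm(n, 0, 0.55))
    colnames(M) <- behavior_scales()$scale
    mask <- matrix(runif(n * 7) < 0.1, n, 7)
  })
  Mna <- M; Mna[mask] <- NA

  expect_identical(impute_behavior_rf(M, seed = 1), M)

  imp1 <- impute_behavior_rf(Mna, seed = 1)
  imp2 <- impute_behavior_rf(Mna, seed = 1)
  expect_identical(imp1, imp2)
  expect_false(anyNA(imp1))
  expect_equal(imp1[!mask], Mna[!mask])

  rmse_rf <- sqrt(mean((imp1[mask] - M[mask])^2))
  med <- Mna
  for (j in 1:7) med[mask[, j], j] <- median(Mna[, j], na.rm = TRUE)
  rmse_med <- sqrt(mean((med[mask] - M[mask])^2))
  expect_lt(rmse_rf, rmse_med)

  Mbad <- Mna; Mbad[, 3] <- NA
  expect_error(impute_behavior_rf(Mbad, seed = 1), "SSP")
  expect_error(impute_behavior_rf(Mna[1:10, ], seed = 1), "at least 20")
})

test_that("PCA reduction matches eigenstructure and reconstructs the input", {
  # rank-2 input: variance beyond the second component vanishes
  withr::with_seed(9, {
    u <- matrix(rnorm(30 * 2), 30)
    v <- matrix(rnorm(2 * 80), 2)
  })
  X2 <- u %*% v
  r2 <- reduce_dimensionality(X2, k = 5)
  expect_lt(sum(r2$var_explained[3:5]), 1e-10)

  X <- withr::with_seed(10, matrix(rnorm(25 * 40), 25))
  r <- reduce_dimensionality(X, k = 24)
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(r$scores %*% t(r$basis) - Xc)), 1e-8)
  # score variances equal the sample-covariance eigenvalues
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(apply(r$scores, 2, var), ev[1:24], tolerance = 1e-8)
  expect_true(all(diff(r$var_explained) <= 1e-12))

  expect_error(reduce_dimensionality(X, k = 25), "below the number")
})

test_that("CCA recovers exact, null and transformation-invariant structure", {
  X <- withr::with_seed(11, matrix(rnorm(200 * 7), 200))
  colnames(X) <- behavior_scales()$scale
  fit_same <- cca_fit(X, X)
  expect_equal(fit_same$cors, rep(1, 7), tolerance = 1e-8)

  Xn <- withr::with_seed(12, matrix(rnorm(1000 * 2), 1000))
  Yn <- withr::with_seed(13, matrix(rnorm(1000 * 2), 1000))
  expect_lt(cca_fit(Xn, Yn)$cors[1], 0.15)

  Y <- withr::with_seed(14, matrix(rnorm(200 * 4), 200))
  A <- matrix(c(2, 0.5, 0, 1, 1, 0, 0.3, 0, 2, 0, 0, 0.1, 0, 0, 1, 3), 4)
  f1 <- cca_fit(X[, 1:5], Y)
  f2 <- cca_fit(X[, 1:5], Y %*% A)
  expect_equal(f1$cors, f2$cors, tolerance = 1e-8)

  # independent oracle: canonical correlations from stats::cancor
  cc <- stats::cancor(scale(X[, 1:5]), scale(Y))
  expect_equal(f1$cors, cc$cor, tolerance = 1e-8)

  Xdup <- cbind(X[, 1:3], X[, 3])
  expect_error(cca_fit(Xdup, Y), "rank-deficient")
  expect_error(cca_fit(X[1:10, ], X[1:10, ]), "more subjects")
})

test_that("the SRS structure correlation fixes the canonical sign", {
  withr::with_seed(15, {
    latent <- rnorm(300)
    X <- sapply(1:5, function(k) latent + rnorm(300, 0, 0.8))
    sc <- behavior_scales()
    Y <- sapply(1:7, function(k) sc$direction[k] * latent + rnorm(300, 0, 0.8))
    colnames(Y) <- sc$scale
  })
  fit <- cca_fit(X, Y)
  loads <- canonical_loadings(fit, X, Y)
  expect_gte(loads$behavior["SRS"], 0)
  expect_true(all(loads$behavior[c("SRS", "RBS", "SSP")] > 0))
  expect_true(all(loads$behavior[c("Vineland", "IQ")] < 0))
})

test_that("canonical loadings follow the closed form on orthonormal data", {
  # Helmert contrasts: columns exactly orthogonal AND zero-sum, so sample
  # correlations between distinct columns are exactly zero.
  Q <- scale(stats::contr.helmert(50)[, 1:4], center = FALSE,
             scale = apply(stats::contr.helmert(50)[, 1:4], 2, sd))
  fake <- structure(list(
    xweights = diag(4)[, 1, drop = FALSE], yweights = diag(4)[, 1, drop = FALSE],
    cors = 1, x_center = rep(0, 4), x_scale = rep(1, 4),
    y_center = rep(0, 4), y_scale = rep(1, 4)), class = "cca_fit")
  loads <- canonical_loadings(fake, Q, Q)
  expect_equal(unname(loads$brain), c(1, 0, 0, 0), tolerance = 1e-10)

  bad <- Q; bad[, 2] <- 0
  expect_error(canonical_loadings(fake, bad, Q), "zero-variance")
})

test_that("back-projection is the basis-weight product", {
  w <- matrix(c(0.5, -1, 2), 3, 1)
  fit <- structure(list(xweights = w), class = "cca_fit")
  expect_equal(backproject_brain_weights(fit, diag(3)), drop(w))
  Q <- qr.Q(qr(withr::with_seed(17, matrix(rnorm(40 * 3), 40))))
  bw <- backproject_brain_weights(fit, Q)
  expect_equal(sqrt(sum(bw^2)), sqrt(sum(w^2)), tolerance = 1e-10)
  expect_equal(bw, drop(Q %*% w), tolerance = 1e-12)
  expect_error(backproject_brain_weights(fit, diag(4)), "do not match")
})

test_that("cross-validated CCA detects a noise-free latent mode", {
  withr::with_seed(18, {
    n <- 60
    u <- rnorm(n)
    B <- outer(u, rnorm(40)) + 1e-3 * matrix(rnorm(n * 40), n)
    Y <- outer(u, c(1, 1, 1, 1, 1, -1, -1)) + 1e-3 * matrix(rnorm(n * 7), n)
    colnames(Y) <- behavior_scales()$scale
  })
  cv <- crossval_cca(B, Y, n_splits = 20, k_folds = 10, n_components = 5,
                     seed = 2)
  expect_gt(mean(cv$test_dist), 0.95)
  expect_gt(mean(cv$stability_behavior), 0.99)

  cv2 <- crossval_cca(B, Y, n_splits = 20, k_folds = 10, n_components = 5,
                      seed = 2)
  expect_identical(cv$test_dist, cv2$test_dist)

  expect_error(crossval_cca(B, Y, n_splits = 0), ">= 1")
  expect_error(crossval_cca(B[1:15, ], Y[1:15, ], n_splits = 2,
                            k_folds = 10, n_components = 3),
               "2 \\* k_folds")
  Yna <- Y; Yna[1, 1] <- NA
  expect_error(crossval_cca(B, Yna, n_splits = 2), "impute")
})

test_that("one split equals an independently coded fold pipeline", {
  # Re-implements one tenfold pass with prcomp + cancor and compares the
  # pooled out-of-sample correlation; this also certifies the training-fold
  # parameters are leakage-free, since the oracle only ever sees training
  # rows when fitting.
  withr::with_seed(19, {
    n <- 50
    u <- rnorm(n)
    B <- outer(u, rnorm(30)) + matrix(rnorm(n * 30), n)
    Y <- sapply(1:4, function(k) u + rnorm(n))
    colnames(Y) <- c("SRS", "RBS", "SSP", "IQ")
  })
  k <- 5; ncomp <- 3; seed <- 77
  cv <- crossval_cca(B, Y, n_splits = 1, k_folds = k, n_components = ncomp,
                     seed = seed)

  fold <- withr::with_seed(seed, sample(rep_len(seq_len(k), n)))
  vx <- vy <- numeric(n)
  for (f in seq_len(k)) {
    te <- fold == f
    pc <- stats::prcomp(B[!te, ], center = TRUE, scale. = FALSE)
    Str <- pc$x[, 1:ncomp]
    Ste <- sweep(B[te, , drop = FALSE], 2, pc$center) %*%
      pc$rotation[, 1:ncomp]
    xm <- colMeans(Str); xs <- apply(Str, 2, sd)
    ym <- colMeans(Y[!te, ]); ys <- apply(Y[!te, ], 2, sd)
    Xtr <- scale(Str, xm, xs); Ytr <- scale(Y[!te, ], ym, ys)
    cc <- stats::cancor(Xtr, Ytr)
    wx1 <- cc$xcoef[, 1] * sqrt(n - sum(te) - 1)
    wy1 <- cc$ycoef[, 1] * sqrt(n - sum(te) - 1)
    if (cor(Ytr %*% wy1, Ytr[, "SRS"]) < 0) {
      wx1 <- -wx1; wy1 <- -wy1
    }
    vx[te] <- scale(Ste, xm, xs) %*% wx1
    vy[te] <- scale(Y[te, , drop = FALSE], ym, ys) %*% wy1
  }
  expect_equal(cv$test_dist[1], cor(vx, vy), tolerance = 1e-6)
})

test_that("the permutation null preserves site structure", {
  # Brain-behavior coupling that lives entirely in site means survives
  # within-site permutation: the null stays close to the test distribution.
  withr::with_seed(20, {
    n <- 80
    site <- rep(paste0("s", 1:4), each = 20)
    site_eff <- rnorm(4)[as.integer(factor(site))]
    B <- outer(site_eff, rnorm(30)) + 0.3 * matrix(rnorm(n * 30), n)
    Y <- sapply(1:4, function(k) site_eff + 0.3 * rnorm(n))
    colnames(Y) <- c("SRS", "RBS", "SSP", "IQ")
  })
  cv <- crossval_cca(B, Y, n_splits = 20, k_folds = 10, n_components = 3,
                     seed = 4)
  null_within <- permutation_null_cca(B, Y, site, n_permutations = 20,
                                      k_folds = 10, n_components = 3,
                                      seed = 5)
  expect_identical(null_within,
                   permutation_null_cca(B, Y, site, n_permutations = 20,
                                        k_folds = 10, n_components = 3,
                                        seed = 5))
  expect_gt(mean(null_within), 0.8 * mean(cv$test_dist))

  # singleton site warns
  site1 <- site; site1[1] <- "solo"
  expect_warning(permutation_null_cca(B, Y, site1, n_permutations = 2,
                                      k_folds = 10, n_components = 3,
                                      seed = 6), "single subject")
})

test_that("significance compares the test mean to the null percentile", {
  expect_true(assess_significance(rep(0.9, 10), seq(0, 0.3, 0.01))$significant)
  expect_false(assess_significance(rep(0.2, 10),
                                   seq(0, 0.4, 0.01))$significant)
  d <- withr::with_seed(21, rnorm(200, 0, 0.1))
  expect_false(assess_significance(d, d)$significant)
  expect_error(assess_significance(numeric(0), 1), "nonempty")
})
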