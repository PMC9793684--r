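# Connectome construction: shrinkage covariance, partial correlations,
# Fisher-Z, mixture normalization, task potency, edge vectorization.

test_that("shrinkage covariance is consistent, PD, and honors forced intensity", {
  withr::with_seed(1, {
    X <- matrix(rnorm(1e4 * 5), ncol = 5)
  })
  S <- shrinkage_covariance(X)
  expect_lt(sqrt(sum((S - diag(5))^2)), 0.05)
  expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_true(attr(S, "shrinkage") >= 0 && attr(S, "shrinkage") <= 1)

  S1 <- shrinkage_covariance(X, shrinkage = 1)
  m <- attr(S1, "target_scale")
  expect_equal(unname(S1), diag(m, 5), ignore_attr = TRUE)

  Xc <- X; Xc[, 3] <- 2
  expect_error(shrinkage_covariance(Xc), "constant")
  expect_error(shrinkage_covariance(X[1:20, ]), "at least 30")
})

test_that("partial correlations match the residual-regression oracle", {
  expect_equal(partial_correlation(diag(4)), matrix(0, 4, 4))

  S2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  expect_equal(partial_correlation(S2)[1, 2], 0.6)

  for (s in 1:5) {
    p <- sample(4:8, 1)
    A <- withr::with_seed(s, matrix(rnorm(p * p), p))
    S <- crossprod(A) + diag(p) * 0.5
    expect_lt(max(abs(partial_correlation(S) - partial_correlation_oracle(S))),
              1e-8)
  }

  expect_error(partial_correlation(matrix(c(1, 1, 1, 1), 2)), "singular")
})

test_that("fisher_z is arctanh with protected diagonal", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  m <- diag(4)  # unit diagonal must be zeroed, not atanh'ed
  m[1, 2] <- m[2, 1] <- 0.5
  z <- fisher_z(m)
  expect_equal(diag(z), rep(0, 4))
  expect_equal(z[1, 2], atanh(0.5))
  bad <- matrix(0, 3, 3); bad[1, 2] <- bad[2, 1] <- 1
  expect_error(fisher_z(bad), "< 1")
  expect_error(fisher_z(c(0.2, 1.2)), "< 1")
})

test_that("mixture fit recovers a pure Gaussian with negligible gamma mass", {
  v <- withr::with_seed(42, rnorm(14028, 2, 3))
  f <- fit_edge_mixture(v)
  expect_true(f$converged)
  expect_lt(abs(f$mean_gauss - 2), 0.1)
  expect_lt(abs(f$sd_gauss - 3), 0.15)
  expect_lt(f$weight_pos, 0.05)
  expect_lt(f$weight_neg, 0.05)
  expect_lt(abs(f$weight_gauss + f$weight_pos + f$weight_neg - 1), 1e-8)
})

test_that("mixture fit recovers Gaussian-gamma component weights", {
  n <- 14028
  v <- withr::with_seed(7, {
    comp <- sample(1:3, n, replace = TRUE, prob = c(0.8, 0.1, 0.1))
    ifelse(comp == 1, rnorm(n),
           ifelse(comp == 2, rgamma(n, 3, scale = 1), -rgamma(n, 3, scale = 1)))
  })
  f <- fit_edge_mixture(v)
  expect_true(f$converged)
  expect_lt(abs(f$weight_gauss - 0.8), 0.05)
  expect_lt(abs(f$weight_pos - 0.1), 0.05)
  expect_lt(abs(f$weight_neg - 0.1), 0.05)

  expect_error(fit_edge_mixture(rep(1, 1000)), "constant")
  expect_error(fit_edge_mixture(rnorm(100)), "at least 500")
})

make_raw_matrix <- function(R = 60, mu = 0.3, sd = 0.2, seed = 3) {
  sub <- taskpotency:::edge_subscripts(R)
  vals <- withr::with_seed(seed, mu + sd * rnorm(nrow(sub)))
  m <- matrix(0, R, R)
  m[sub] <- vals
  m[sub[, 2:1]] <- vals
  taskpotency:::new_connectivity_matrix(m, "s1", "rest", "raw_fisher_z")
}

test_that("normalization maps edges by the main-Gaussian location and scale", {
  cm <- make_raw_matrix()
  fit0 <- list(weight_gauss = 1, mean_gauss = 0, sd_gauss = 1,
               weight_pos = 0, shape_pos = 1, scale_pos = 1,
               weight_neg = 0, shape_neg = 1, scale_neg = 1,
               loglik = 0, converged = TRUE)
  class(fit0) <- "mixture_fit"
  nm0 <- normalize_connectivity(cm, fit0)
  expect_equal(nm0$values, cm$values)

  fit23 <- fit0; fit23$mean_gauss <- 2; fit23$sd_gauss <- 3
  cm8 <- cm; cm8$values[1, 2] <- cm8$values[2, 1] <- 8
  nm <- normalize_connectivity(cm8, fit23)
  expect_equal(nm$values[1, 2], 2)
  expect_equal(diag(nm$values), rep(0, 60))

  fitbad <- fit0; fitbad$sd_gauss <- 0
  expect_error(normalize_connectivity(cm, fitbad), "> 0")
  expect_error(normalize_connectivity(nm0), "raw_fisher_z")
})

test_that("normalization is self-consistent and shift-equivariant", {
  cm <- make_raw_matrix(R = 168)
  nm <- normalize_connectivity(cm)
  sub <- taskpotency:::edge_subscripts(168)
  refit <- fit_edge_mixture(nm$values[sub])
  expect_lt(abs(refit$mean_gauss), 0.05)
  expect_lt(abs(refit$sd_gauss - 1), 0.05)

  shifted <- cm
  shifted$values <- cm$values + 5
  diag(shifted$values) <- 0
  nm_s <- normalize_connectivity(shifted)
  expect_lt(max(abs(nm_s$values[sub] - nm$values[sub])), 0.02)
})

test_that("task potency is the difference of normalized matrices", {
  cm <- make_raw_matrix()
  nm <- normalize_connectivity(cm)
  zero <- task_potency(nm, nm)
  expect_equal(zero$values, matrix(0, 60, 60))

  cm2 <- make_raw_matrix(mu = 0.1, seed = 4)
  cm2$condition <- "taskA"
  nm2 <- normalize_connectivity(cm2)
  ab <- task_potency(nm2, nm)
  ba <- task_potency(nm, nm2)
  expect_equal(ab$values, -ba$values)

  one_t <- nm; one_t$values <- matrix(0, 60, 60); one_t$values[1, 2] <- one_t$values[2, 1] <- 1.5
  one_r <- nm; one_r$values <- matrix(0, 60, 60); one_r$values[1, 2] <- one_r$values[2, 1] <- 0.5
  expect_equal(task_potency(one_t, one_r)$values[1, 2], 1.0)

  other <- nm2; other$subject_id <- "s2"
  expect_error(task_potency(other, nm), "subject mismatch")
  expect_error(task_potency(cm2, nm), "normalized")
})

test_that("edge vectorization uses the frozen order and round-trips exactly", {
  idx4 <- edge_index(4)
  expect_equal(nrow(idx4), 6L)
  expect_equal(idx4$i[1:3], c(0L, 0L, 0L))
  expect_equal(idx4$j[1:3], c(1L, 2L, 3L))
  expect_equal(idx4$i[4], 1L)
  expect_equal(nrow(edge_index(168)), 14028L)

  m <- matrix(0, 5, 5)
  sub <- taskpotency:::edge_subscripts(5)
  vals <- withr::with_seed(1, rnorm(10))
  m[sub] <- vals; m[sub[, 2:1]] <- vals
  et <- vectorize_edges(list(m), task = "t", subject_ids = "s1")
  expect_equal(ncol(et$values), 10L)
  expect_equal(unvectorize_edges(et$values[1, ], 5), m)
  expect_error(unvectorize_edges(1:9, 5), "expected 10")
  expect_error(vectorize_edges(list(m, matrix(0, 4, 4))), "same region count")
})
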