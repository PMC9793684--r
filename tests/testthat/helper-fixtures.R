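# Shared fixtures and independent oracles used across test files.

# A desk-scale simulation configuration: 16 regions in 4 networks keeps every
# covariance/mixture operation fast while preserving the block structure.
small_cfg <- function(...) {
  defaults <- list(n_autism = 6L, n_td = 6L, n_sites = 2L, n_regions = 16L,
                   n_networks = 4L, n_timepoints = 100L,
                   conditions = c("rest", "taskA", "taskB"),
                   master_seed = 7L)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Brute-force partial correlation: correlate the residuals of each variable
# pair after regressing both on all remaining variables.
partial_correlation_oracle <- function(S) {
  p <- nrow(S)
  # work from a large exact sample: use the covariance directly via
  # regression algebra on the population scale
  out <- diag(0, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- setdiff(seq_len(p), c(i, j))
      if (length(others) == 0) {
        out[i, j] <- out[j, i] <- S[i, j] / sqrt(S[i, i] * S[j, j])
        next
      }
      Soo <- S[others, others, drop = FALSE]
      # residual covariance of (i, j) given others
      Sio <- S[c(i, j), others, drop = FALSE]
      R <- S[c(i, j), c(i, j)] - Sio %*% solve(Soo, t(Sio))
      out[i, j] <- out[j, i] <- R[1, 2] / sqrt(R[1, 1] * R[2, 2])
    }
  }
  out
}

# Double-loop region scores: mean |edge value| over all edges touching r.
region_scores_oracle <- function(edge_values, n_regions) {
  idx <- edge_index(n_regions)
  scores <- numeric(n_regions)
  for (r in seq_len(n_regions) - 1L) {
    touching <- which(idx$i == r | idx$j == r)
    scores[r + 1L] <- mean(abs(edge_values[touching]))
  }
  scores
}

# Oracle deviation Z-scores from the generating model of
# simulate_potency_cohort (site-free case).
oracle_z <- function(sim, task = names(sim$edges)[1]) {
  tr <- sim$truth
  n <- nrow(sim$cohort); E <- length(tr$intercepts)
  mu <- matrix(tr$intercepts, n, E, byrow = TRUE) +
    outer(sim$cohort$age - tr$age_center, tr$age_slopes) +
    outer(as.numeric(sim$cohort$sex == "male"), tr$sex_offsets)
  (sim$edges[[task]]$values - mu) / matrix(tr$noise_sd, n, E, byrow = TRUE)
}

# Behavior scales generated from a latent severity axis, in the impairment
# direction of each scale.
behavior_from_severity <- function(severity, loading = 0.7, noise_sd = 0.7,
                                   seed = 1) {
  sc <- behavior_scales()
  withr::with_seed(seed, {
    Y <- vapply(seq_len(7), function(k) {
      sc$direction[k] * loading * severity +
        stats::rnorm(length(severity), 0, noise_sd)
    }, numeric(length(severity)))
    colnames(Y) <- sc$scale
    Y
  })
}

expect_symmetric_zero_diag <- function(m, tol = 1e-10) {
  expect_lt(max(abs(m - t(m))), tol)
  expect_lt(max(abs(diag(m))), tol)
}
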