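# Synthetic cohort generator: determinism, marginal structure, and the
# positive-definiteness guarantees the connectome stage relies on.

test_that("cohort generation respects group sizes, bounds and determinism", {
  cfg <- small_cfg(n_autism = 0L, n_td = 10L)
  co <- generate_cohort(cfg, seed = 3)
  expect_equal(nrow(co), 10L)
  expect_true(all(co$group == "td"))
  expect_true(all(co$age >= 6 & co$age <= 30))
  expect_false(anyDuplicated(co$subject_id) > 0)
  expect_true(all(co$site %in% paste0("site", 1:2)))

  expect_identical(generate_cohort(cfg, seed = 3), co)
  expect_false(identical(generate_cohort(cfg, seed = 4), co))
})

test_that("sites are assigned near-uniformly", {
  cfg <- small_cfg(n_autism = 150L, n_td = 150L, n_sites = 3L)
  co <- generate_cohort(cfg, seed = 12)
  counts <- table(co$site)
  expect_equal(length(counts), 3L)
  # multinomial bound: 100 +/- 3 * sqrt(100 * 2/3)
  expect_true(all(abs(counts - 100) <= 3 * sqrt(100 * 2 / 3)))
})

test_that("severity is unit-variance with the configured group offset", {
  cfg <- small_cfg(n_autism = 400L, n_td = 400L)
  co <- generate_cohort(cfg, seed = 5)
  expect_lt(abs(mean(co$severity[co$group == "td"])), 0.2)
  expect_lt(abs(mean(co$severity[co$group == "autism"]) - cfg$severity_offset), 0.2)
  expect_lt(abs(sd(co$severity[co$group == "td"]) - 1), 0.15)
})

test_that("ground truth has the promised support and PD structure", {
  cfg <- small_cfg(deviation_support_frac = 0)
  gt <- generate_ground_truth(cfg, seed = 1)
  expect_length(gt$deviation_support, 0L)

  cfg2 <- small_cfg(task_mod_frac = 0)
  gt2 <- generate_ground_truth(cfg2, seed = 1)
  for (task in setdiff(cfg2$conditions, "rest")) {
    expect_equal(gt2$task_modulations[[task]], matrix(0, 16, 16))
  }

  cfg3 <- small_cfg(n_regions = 40L, n_networks = 4L,
                    deviation_support_frac = 0.05)
  gt3 <- generate_ground_truth(cfg3, seed = 2)
  expect_gt(min(eigen(gt3$rest_precision, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  E <- 40 * 39 / 2
  expect_length(gt3$deviation_support, round(0.05 * E))
  # every subject/condition precision emitted downstream is PD
  co <- generate_cohort(cfg3, seed = 2)
  for (cond in cfg3$conditions) {
    Om <- taskpotency:::subject_precision(co[1, ], cond, gt3, cfg3)
    expect_gt(min(eigen(Om, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("large-T time series reproduce the ground-truth partial correlations", {
  cfg <- small_cfg(site_effect_scale = 0, age_slope_scale = 0,
                   sex_effect_scale = 0, deviation_amplitude = 0)
  gt <- generate_ground_truth(cfg, seed = 9)
  co <- generate_cohort(cfg, seed = 9)
  td_row <- co[co$group == "td", ][1, ]
  ts <- simulate_condition_timeseries(td_row, "rest", gt, cfg, seed = 4,
                                      n_timepoints = 1e5)
  # ground-truth partials from the precision matrix
  d <- sqrt(diag(gt$rest_precision))
  p_true <- -gt$rest_precision / tcrossprod(d)
  diag(p_true) <- 0
  p_hat <- partial_correlation(stats::cov(ts$values))
  expect_lt(max(abs(p_hat - p_true)), 0.02)
})

test_that("time-series simulation is deterministic and validates inputs", {
  cfg <- small_cfg()
  gt <- generate_ground_truth(cfg, seed = 1)
  co <- generate_cohort(cfg, seed = 1)
  a <- simulate_condition_timeseries(co[1, ], "taskA", gt, cfg, seed = 5)
  b <- simulate_condition_timeseries(co[1, ], "taskA", gt, cfg, seed = 5)
  expect_identical(a, b)
  expect_error(simulate_condition_timeseries(co[1, ], "nback", gt, cfg, 1),
               "nback")
  expect_error(simulate_condition_timeseries(co[1, ], "rest", gt, cfg, 1,
                                             n_timepoints = 10),
               ">= 30")
})

test_that("behavior scales track severity in their impairment direction", {
  cfg <- small_cfg(n_autism = 250L, n_td = 250L, missing_rate = 0)
  co <- generate_cohort(cfg, seed = 21)
  beh <- generate_behavior(co, cfg, seed = 21)
  expect_false(anyNA(beh$behavior))
  sc <- behavior_scales()
  for (k in seq_len(7)) {
    r <- cor(beh$truth[[sc$scale[k]]], co$severity)
    expect_gt(r * sc$direction[k], 0.2)
  }

  # zero loadings leave scales uncorrelated with severity
  cfg0 <- small_cfg(n_autism = 250L, n_td = 250L,
                    behavior_loadings = rep(0, 7))
  beh0 <- generate_behavior(co, cfg0, seed = 24)
  for (k in seq_len(7)) {
    expect_lt(abs(cor(beh0$truth[[sc$scale[k]]], co$severity)), 0.1)
  }
})

test_that("behavioral missingness is MCAR at the configured rate", {
  cfg <- small_cfg(n_autism = 50L, n_td = 50L, missing_rate = 0.1)
  co <- generate_cohort(cfg, seed = 2)
  beh <- generate_behavior(co, cfg, seed = 2)
  n_missing <- sum(is.na(beh$behavior[behavior_scales()$scale]))
  expect_true(abs(n_missing - 70) <= 2 * sqrt(700 * 0.09))
  # observed cells agree with the pre-masking truth
  sc <- behavior_scales()$scale
  obs <- !is.na(as.matrix(beh$behavior[sc]))
  expect_equal(as.matrix(beh$behavior[sc])[obs],
               as.matrix(beh$truth[sc])[obs])
})

test_that("groups are exchangeable when all group effects are off", {
  # With deviation amplitude and site/age/sex scales at zero, autism and TD
  # time series share one generating law: two-sample tests on per-subject
  # mean edge strength should reject at the nominal rate only.
  n_reject <- 0L
  for (s in 1:50) {
    cfg <- small_cfg(n_autism = 5L, n_td = 5L, n_regions = 10L,
                     n_networks = 2L, n_timepoints = 60L,
                     conditions = c("rest", "taskA"),
                     deviation_amplitude = 0, site_effect_scale = 0,
                     age_slope_scale = 0, sex_effect_scale = 0)
    co <- generate_cohort(cfg, seed = s)
    gt <- generate_ground_truth(cfg, seed = s)
    stat <- vapply(seq_len(nrow(co)), function(i) {
      ts <- simulate_condition_timeseries(co[i, ], "taskA", gt, cfg,
                                          seed = 1000 + 7 * s + i)
      m <- connectivity_from_timeseries(ts)
      mean(m$values[upper.tri(m$values)])
    }, numeric(1))
    p <- stats::t.test(stat[co$group == "autism"],
                       stat[co$group == "td"])$p.value
    if (p < 0.01) n_reject <- n_reject + 1L
  }
  # binomial(50, 0.01): P(X > 4) < 2e-4
  expect_lte(n_reject, 4L)
})
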