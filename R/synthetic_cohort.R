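#' Simulation configuration for a synthetic multi-site cohort
#'
#' Bundles every knob of the synthetic cohort generator. Defaults emulate a
#' multi-site autism case-control fMRI cohort: 282 autistic and 221 typically
#' developing (TD) participants aged 6-30 scanned at 6 European sites, with a
#' resting-state acquisition plus five activation tasks, 168 atlas regions in
#' 11 networks, additive site effects, age/sex trends on connectivity edges,
#' an autism-specific deviation pattern shared across tasks, and latent
#' brain-behavior covariation over seven behavioral scales with missing
#' entries.
#'
#' @param n_autism,n_td Group sizes.
#' @param n_sites Number of acquisition sites (subjects assigned uniformly).
#' @param n_regions,n_networks Atlas size; regions are split into
#'   `n_networks` contiguous blocks (remainder goes to the last block).
#' @param n_timepoints Time points per condition (rows of each time series).
#' @param conditions Ordered condition labels; must contain `"rest"` exactly
#'   once. The non-rest labels are the task conditions.
#' @param age_range Length-2 numeric, years.
#' @param sex_balance Probability a subject is male.
#' @param severity_offset Mean shift of the latent impairment axis in the
#'   autism group (TD centered at 0; unit variance in both groups).
#' @param site_effect_scale SD of per-site additive shifts on edge precision.
#' @param age_slope_scale SD of per-edge linear age trends (per year).
#' @param sex_effect_scale SD of per-edge male-vs-female offsets.
#' @param task_mod_frac,task_mod_scale Fraction of edges modulated by each
#'   task and the SD of the modulation strengths.
#' @param deviation_support_frac Fraction of edges in the shared autism
#'   atypicality support (identical edge set in every task).
#' @param deviation_amplitude Strength of the autism deviation on the support.
#' @param td_pattern_amplitude Strength of an optional weak shared deviation
#'   pattern in TD (0 = unstructured TD noise, the default).
#' @param behavior_loadings Length-7 non-negative loadings of the latent
#'   severity on the scales (SRS, RBS, SSP, ADHD hyperactivity/impulsivity,
#'   ADHD inattentiveness, Vineland, IQ); impairment direction (up for the
#'   first five, down for Vineland and IQ) is applied internally.
#' @param behavior_noise_sd Per-scale residual SD (standardized units).
#' @param missing_rate Probability any behavioral cell is missing (MCAR).
#' @param master_seed Integer master seed; stage seeds are derived from it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_autism = 282L,
                       n_td = 221L,
                       n_sites = 6L,
                       n_regions = 168L,
                       n_networks = 11L,
                       n_timepoints = 180L,
                       conditions = c("rest", "hariri", "flanker",
                                      "reward_s", "reward_ns", "tom"),
                       age_range = c(6, 30),
                       sex_balance = 0.68,
                       severity_offset = 1.5,
                       site_effect_scale = 0.02,
                       age_slope_scale = 0.002,
                       sex_effect_scale = 0.01,
                       task_mod_frac = 0.05,
                       task_mod_scale = 0.08,
                       deviation_support_frac = 0.05,
                       deviation_amplitude = 0.08,
                       td_pattern_amplitude = 0,
                       behavior_loadings = c(0.8, 0.7, 0.6, 0.55, 0.55, 0.6, 0.35),
                       behavior_noise_sd = 0.7,
                       missing_rate = 0.08,
                       master_seed = 20080L) {
  cfg <- list(
    n_autism = as.integer(n_autism), n_td = as.integer(n_td),
    n_sites = as.integer(n_sites), n_regions = as.integer(n_regions),
    n_networks = as.integer(n_networks),
    n_timepoints = as.integer(n_timepoints),
    conditions = as.character(conditions),
    age_range = as.numeric(age_range), sex_balance = as.numeric(sex_balance),
    severity_offset = as.numeric(severity_offset),
    site_effect_scale = as.numeric(site_effect_scale),
    age_slope_scale = as.numeric(age_slope_scale),
    sex_effect_scale = as.numeric(sex_effect_scale),
    task_mod_frac = as.numeric(task_mod_frac),
    task_mod_scale = as.numeric(task_mod_scale),
    deviation_support_frac = as.numeric(deviation_support_frac),
    deviation_amplitude = as.numeric(deviation_amplitude),
    td_pattern_amplitude = as.numeric(td_pattern_amplitude),
    behavior_loadings = as.numeric(behavior_loadings),
    behavior_noise_sd = as.numeric(behavior_noise_sd),
    missing_rate = as.numeric(missing_rate),
    master_seed = as.integer(master_seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_autism < 0L || n_td < 0L || n_autism + n_td < 1L) {
      stop("group sizes must be non-negative and sum to >= 1")
    }
    if (n_sites < 1L) stop("`n_sites` must be >= 1")
    if (n_regions < 2L) stop("`n_regions` must be >= 2")
    if (n_networks < 1L || n_networks > n_regions) {
      stop("`n_networks` must be in [1, n_regions]")
    }
    if (n_timepoints < 30L) stop("`n_timepoints` must be >= 30")
    if (sum(conditions == "rest") != 1L) {
      stop("`conditions` must contain \"rest\" exactly once")
    }
    if (anyDuplicated(conditions)) stop("`conditions` must be unique")
    if (length(age_range) != 2L || diff(age_range) <= 0) {
      stop("`age_range` must be an increasing length-2 interval")
    }
    for (p in c("sex_balance", "missing_rate", "task_mod_frac",
                "deviation_support_frac")) {
      v <- get(p)
      if (v < 0 || v > 1) stop(sprintf("`%s` must be in [0, 1]", p))
    }
    for (p in c("site_effect_scale", "age_slope_scale", "sex_effect_scale",
                "task_mod_scale", "deviation_amplitude",
                "td_pattern_amplitude", "behavior_noise_sd")) {
      if (get(p) < 0) stop(sprintf("`%s` must be >= 0", p))
    }
    if (length(behavior_loadings) != 7L) {
      stop("`behavior_loadings` must have length 7")
    }
  })
  invisible(cfg)
}

#' Behavioral scale metadata
#'
#' The seven scales entering the brain-behavior analysis, with the direction
#' in which each indicates greater impairment (+1: higher is more impaired;
#' -1: lower is more impaired, i.e. adaptive functioning and IQ).
#' @return Data frame with columns `scale` and `direction`.
#' @export
behavior_scales <- function() {
  data.frame(
    scale = c("SRS", "RBS", "SSP", "ADHD_hyperimpulsive",
              "ADHD_inattentive", "Vineland", "IQ"),
    direction = c(1, 1, 1, 1, 1, -1, -1)
  )
}

#' Generate a synthetic cohort table
#'
#' Draws subject metadata: site (uniform over sites), age (uniform over the
#' configured range), sex (Bernoulli with `sex_balance` probability of male),
#' group, and a latent unit-variance severity axis centered at
#' `severity_offset` in the autism group and 0 in TD. Severity is defined for
#' every subject so behavior generation is uniform; only autistic subjects
#' receive connectome deviations.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the same `(cfg, seed)` always yields the same
#'   table.
#' @return Data frame with columns `subject_id`, `site`, `age`, `sex`,
#'   `group`, `severity`.
#' @export
generate_cohort <- function(cfg, seed = cfg$master_seed) {
  validate_sim_config(cfg)
  n <- cfg$n_autism + cfg$n_td
  with_seed(seed, {
    group <- rep(c("autism", "td"), c(cfg$n_autism, cfg$n_td))
    cohort <- data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      site = paste0("site", sample.int(cfg$n_sites, n, replace = TRUE)),
      age = stats::runif(n, cfg$age_range[1], cfg$age_range[2]),
      sex = ifelse(stats::runif(n) < cfg$sex_balance, "male", "female"),
      group = group,
      severity = stats::rnorm(n) +
        ifelse(group == "autism", cfg$severity_offset, 0)
    )
    cohort
  })
}

# Random symmetric zero-diagonal perturbation supported on given edges.
sym_perturbation <- function(n_regions, edges, values) {
  P <- matrix(0, n_regions, n_regions)
  sub <- edge_subscripts(n_regions)[edges, , drop = FALSE]
  P[sub] <- values
  P[sub[, 2:1, drop = FALSE]] <- values
  P
}

#' Generate the ground-truth connectivity structure
#'
#' Builds the latent structure the downstream analyses are meant to detect:
#' a block-structured positive-definite rest precision matrix (stronger
#' within-network conditional dependence), a sparse symmetric per-task
#' modulation on task-specific edge subsets, one deviation support (the edge
#' set on which autistic subjects deviate, identical in every task, with a
#' fixed signed effect pattern), per-edge age slopes and sex offsets, and
#' per-site per-edge offsets.
#'
#' @inheritParams generate_cohort
#' @return List of class `"ground_truth"`: `rest_precision`,
#'   `task_modulations` (named list of R x R matrices), `deviation_support`
#'   (integer edge indices into [edge_index()]), `deviation_pattern` (signed
#'   unit-scale effects on the support), `age_slopes`, `sex_offsets`
#'   (E-vectors), `site_offsets` (sites x E matrix), `td_pattern`.
#' @export
generate_ground_truth <- function(cfg, seed = cfg$master_seed) {
  validate_sim_config(cfg)
  R <- cfg$n_regions
  E <- R * (R - 1L) / 2L
  idx <- edge_index(R)
  tasks <- setdiff(cfg$conditions, "rest")
  with_seed(derive_seed(seed, 1L), {
    # Block-structured precision: negative within-network off-diagonals give
    # positive within-network partial correlations.
    sizes <- rep(R %/% cfg$n_networks, cfg$n_networks)
    sizes[cfg$n_networks] <- sizes[cfg$n_networks] + R %% cfg$n_networks
    network <- rep.int(seq_len(cfg$n_networks), sizes)
    Omega <- matrix(0, R, R)
    same_net <- outer(network, network, "==")
    within_strength <- 0.9 / max(sizes)   # diagonal dominance with margin
    Omega[same_net] <- -stats::runif(sum(same_net), 0.5, 1) * within_strength
    Omega <- (Omega + t(Omega)) / 2
    diag(Omega) <- 1
    # sparse weak between-network couplings
    nb <- round(0.02 * E)
    if (nb > 0) {
      between <- which(!same_net[edge_subscripts(R)])
      picked <- sample(between, min(nb, length(between)))
      Omega <- Omega + sym_perturbation(R, picked,
                                        stats::rnorm(length(picked), 0, 0.02))
    }
    Omega <- ensure_pd(Omega, floor_frac = 0.05)

    task_modulations <- lapply(tasks, function(task) {
      ne <- round(cfg$task_mod_frac * E)
      if (ne == 0) return(matrix(0, R, R))
      picked <- sample.int(E, ne)
      sym_perturbation(R, picked, stats::rnorm(ne, 0, cfg$task_mod_scale))
    })
    names(task_modulations) <- tasks

    ns <- round(cfg$deviation_support_frac * E)
    deviation_support <- if (ns > 0) sort(sample.int(E, ns)) else integer(0)
    deviation_pattern <- if (ns > 0) {
      sample(c(-1, 1), ns, replace = TRUE) * stats::runif(ns, 0.5, 1)
    } else {
      numeric(0)
    }

    td_ns <- round(cfg$deviation_support_frac * E)
    td_support <- if (cfg$td_pattern_amplitude > 0 && td_ns > 0) {
      sort(sample.int(E, td_ns))
    } else {
      integer(0)
    }

    gt <- list(
      network = network,
      rest_precision = Omega,
      task_modulations = task_modulations,
      deviation_support = deviation_support,
      deviation_pattern = deviation_pattern,
      td_support = td_support,
      age_slopes = stats::rnorm(E, 0, cfg$age_slope_scale),
      sex_offsets = stats::rnorm(E, 0, cfg$sex_effect_scale),
      site_offsets = matrix(stats::rnorm(cfg$n_sites * E, 0,
                                         cfg$site_effect_scale),
                            nrow = cfg$n_sites,
                            dimnames = list(paste0("site",
                                                   seq_len(cfg$n_sites)),
                                            idx$label))
    )
    class(gt) <- "ground_truth"
    gt
  })
}

# Shift eigenvalues up if needed so the matrix is safely positive-definite.
ensure_pd <- function(M, floor_frac = 0.05) {
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  floor_val <- floor_frac * mean(diag(M))
  if (min(ev) < floor_val) {
    M <- M + diag(floor_val - min(ev), nrow(M))
  }
  M
}

# Subject- and condition-specific precision matrix; rescales the perturbation
# (halving) if it would break positive-definiteness. Never emits non-PD.
subject_precision <- function(subject, condition, gt, cfg) {
  R <- cfg$n_regions
  P <- matrix(0, R, R)
  if (condition != "rest") {
    P <- P + gt$task_modulations[[condition]]
    if (subject$group == "autism" && length(gt$deviation_support) > 0) {
      amp <- cfg$deviation_amplitude * (1 + pmax(subject$severity, 0))
      P <- P + sym_perturbation(R, gt$deviation_support,
                                amp * gt$deviation_pattern)
    }
    if (subject$group == "td" && length(gt$td_support) > 0) {
      P <- P + sym_perturbation(R, gt$td_support,
                                cfg$td_pattern_amplitude * gt$deviation_pattern)
    }
    # Age, sex and site act on how the task modulates connectivity, so the
    # trends survive the rest-subtraction that defines potency.
    E <- R * (R - 1L) / 2L
    age_c <- subject$age - mean(cfg$age_range)
    nuisance <- gt$age_slopes * age_c +
      gt$sex_offsets * (subject$sex == "male") +
      gt$site_offsets[subject$site, ]
    P <- P + sym_perturbation(R, seq_len(E), nuisance)
  }

  Omega <- gt$rest_precision + P
  tries <- 0L
  while (tries < 30L &&
         min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values) <= 1e-6) {
    P <- P / 2
    Omega <- gt$rest_precision + P
    tries <- tries + 1L
  }
  if (tries > 0L) {
    message(sprintf("perturbation rescaled by 2^-%d for %s/%s to keep the precision positive-definite",
                    tries, subject$subject_id, condition))
  }
  Omega
}

#' Simulate a BOLD-like time series for one subject and condition
#'
#' Rows are independent draws from a zero-mean multivariate normal whose
#' precision matrix is the ground-truth rest precision plus the condition's
#' task modulation, the autism deviation on the shared support (scaled by
#' `deviation_amplitude * (1 + severity)`), and the subject's age, sex and
#' site terms. No hemodynamics, autocorrelation or drift are modelled: the
#' downstream pipeline consumes only covariance structure.
#'
#' @param subject One row of a [generate_cohort()] table.
#' @param condition A label from `cfg$conditions`.
#' @param gt A [generate_ground_truth()] object.
#' @param cfg The [sim_config()].
#' @param seed Integer seed.
#' @param n_timepoints Number of rows (default `cfg$n_timepoints`; minimum 30).
#' @return List of class `"time_series"`: `subject_id`, `condition`, `values`
#'   (T x R matrix with region-id column names).
#' @export
simulate_condition_timeseries <- function(subject, condition, gt, cfg,
                                          seed = cfg$master_seed,
                                          n_timepoints = cfg$n_timepoints) {
  validate_sim_config(cfg)
  if (!condition %in% cfg$conditions) {
    stop(sprintf("unknown condition \"%s\"", condition))
  }
  if (n_timepoints < 30L) stop("`n_timepoints` must be >= 30")
  Omega <- subject_precision(subject, condition, gt, cfg)
  U <- chol(Omega)   # Omega = U'U, so x = U^{-1} z has covariance Omega^{-1}
  X <- with_seed(seed, {
    Z <- matrix(stats::rnorm(n_timepoints * cfg$n_regions), ncol = n_timepoints)
    t(backsolve(U, Z))
  })
  colnames(X) <- sprintf("region%03d", seq_len(cfg$n_regions) - 1L)
  structure(list(subject_id = subject$subject_id, condition = condition,
                 values = X),
            class = "time_series")
}

#' Generate behavioral scale scores from the latent severity axis
#'
#' Each scale is `direction * loading * severity + noise` in standardized
#' units, where `direction` encodes the impairment direction (SRS, RBS, SSP
#' and the two ADHD scales increase with impairment; Vineland and IQ
#' decrease). Cells are then masked missing-completely-at-random at
#' `missing_rate`. The pre-masking table is returned alongside as the oracle
#' for imputation tests.
#'
#' @param cohort A [generate_cohort()] table.
#' @inheritParams generate_cohort
#' @return List with `behavior` (data frame, `subject_id` plus the 7 scales,
#'   `NA` for missing) and `truth` (same, unmasked).
#' @export
generate_behavior <- function(cohort, cfg, seed = cfg$master_seed) {
  validate_sim_config(cfg)
  if (nrow(cohort) == 0L) stop("`cohort` must be nonempty")
  scales <- behavior_scales()
  n <- nrow(cohort)
  with_seed(derive_seed(seed, 2L), {
    vals <- vapply(seq_len(7L), function(k) {
      scales$direction[k] * cfg$behavior_loadings[k] * cohort$severity +
        stats::rnorm(n, 0, cfg$behavior_noise_sd)
    }, numeric(n))
    if (n == 1L) vals <- matrix(vals, nrow = 1L)
    colnames(vals) <- scales$scale
    truth <- data.frame(subject_id = cohort$subject_id, vals,
                        check.names = FALSE)
    masked <- vals
    masked[matrix(stats::runif(n * 7L) < cfg$missing_rate, n, 7L)] <- NA_real_
    behavior <- data.frame(subject_id = cohort$subject_id, masked,
                           check.names = FALSE)
    list(behavior = behavior, truth = truth)
  })
}

#' Simulate a full cohort of time series
#'
#' Convenience wrapper running [simulate_condition_timeseries()] for every
#' subject and condition with per-subject-condition derived seeds.
#'
#' @inheritParams generate_behavior
#' @param gt A [generate_ground_truth()] object.
#' @return Nested list `ts[[condition]][[subject_id]]` of `"time_series"`.
#' @export
simulate_cohort_timeseries <- function(cohort, gt, cfg,
                                       seed = cfg$master_seed) {
  out <- lapply(cfg$conditions, function(cond) {
    ci <- match(cond, cfg$conditions)
    lst <- lapply(seq_len(nrow(cohort)), function(s) {
      simulate_condition_timeseries(cohort[s, ], cond, gt, cfg,
                                    seed = derive_seed(seed, 1000L * ci + s))
    })
    names(lst) <- cohort$subject_id
    lst
  })
  names(out) <- cfg$conditions
  out
}
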