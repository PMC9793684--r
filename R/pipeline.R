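# End-to-end orchestration: synthetic cohort -> connectomes -> potency ->
# harmonization -> normative deviations -> cross-task similarity -> CCA ->
# region-level report.

#' Pipeline configuration
#'
#' Collects the analysis constants in one place: the deviation threshold
#' (|z| > 2.571, nominally the 1% two-tailed normal cut), 10 principal
#' components for the CCA, tenfold cross-validation with 1000 splits and
#' 1000 within-site permutations, the 95th-percentile significance rule,
#' and the top-10% region report.
#'
#' @param sim A [sim_config()] describing the synthetic cohort.
#' @param z_threshold Deviation threshold (default 2.571).
#' @param pca_components Components kept for the CCA (default 10).
#' @param cv_splits,cv_folds Cross-validation splits and folds (defaults
#'   1000 and 10).
#' @param permutations Permutation-null size (default 1000).
#' @param significance_percentile Null percentile to beat (default 95).
#' @param top_region_fraction Fraction of regions reported (default 0.10).
#' @param normative_folds Folds for the TD out-of-sample scheme (default 10).
#' @param normative_basis `"quadratic"` or `"linear"`.
#' @param global_pca Fit the CCA reduction once on all subjects instead of
#'   within training folds (default FALSE).
#' @param run_harmonization,run_cca Stage toggles.
#' @param seed Master seed; stage seeds are derived from it.
#' @param out_dir Optional directory for the JSON report and intermediates.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            z_threshold = 2.571,
                            pca_components = 10L,
                            cv_splits = 1000L,
                            cv_folds = 10L,
                            permutations = 1000L,
                            significance_percentile = 95,
                            top_region_fraction = 0.10,
                            normative_folds = 10L,
                            normative_basis = "quadratic",
                            global_pca = FALSE,
                            run_harmonization = TRUE,
                            run_cca = TRUE,
                            seed = sim$master_seed,
                            out_dir = NULL) {
  stopifnot(z_threshold > 0, pca_components >= 1L, cv_splits >= 1L,
            cv_folds >= 2L, permutations >= 1L,
            significance_percentile > 0, significance_percentile < 100,
            top_region_fraction > 0, top_region_fraction <= 1,
            normative_folds >= 2L)
  structure(list(sim = sim, z_threshold = z_threshold,
                 pca_components = as.integer(pca_components),
                 cv_splits = as.integer(cv_splits),
                 cv_folds = as.integer(cv_folds),
                 permutations = as.integer(permutations),
                 significance_percentile = significance_percentile,
                 top_region_fraction = top_region_fraction,
                 normative_folds = as.integer(normative_folds),
                 normative_basis = normative_basis,
                 global_pca = isTRUE(global_pca),
                 run_harmonization = isTRUE(run_harmonization),
                 run_cca = isTRUE(run_cca),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage \"%s\" failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort, simulates time series, builds normalized
#' partial-correlation connectomes and task-potency edge tables, harmonizes
#' sites, fits per-edge normative models in the typically developing group
#' (scored out-of-sample by cross-validation; autistic subjects scored by
#' the all-TD model), computes percent-atypical case-control statistics
#' with BH correction across tasks, the cross-task similarity comparison,
#' and (optionally) the per-task out-of-sample CCA against the behavioral
#' scales with a within-site permutation null. Subjects missing a
#' condition's time series are excluded from that task only; subjects
#' missing rest are excluded throughout.
#'
#' @param config A [pipeline_config()].
#' @param timeseries Optional pre-simulated nested list
#'   `ts[[condition]][[subject_id]]` (entries may be missing); simulated
#'   from `config$sim` when `NULL`.
#' @return A report bundle (list) with per-task group comparisons, deviance
#'   summaries, region top-lists, the similarity analysis, and per-task CCA
#'   results; written as `report.json` under `config$out_dir` when set.
#' @export
run_pipeline <- function(config, timeseries = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  seed <- config$seed
  tasks <- setdiff(cfg$conditions, "rest")

  cohort <- run_stage("simulate", generate_cohort(cfg, seed))
  gt <- run_stage("simulate", generate_ground_truth(cfg, seed))
  beh <- run_stage("simulate", generate_behavior(cohort, cfg, seed))
  if (is.null(timeseries)) {
    timeseries <- run_stage("simulate",
                            simulate_cohort_timeseries(cohort, gt, cfg, seed))
  }
  if (cfg$n_autism < 1L || cfg$n_td < 1L) {
    stop("pipeline stage \"simulate\" failed: both groups must be nonempty for the case-control analyses")
  }

  # --- connectome stage: normalized matrices and potency edge tables -------
  edge_tables <- run_stage("connectome", {
    rest_ids <- names(timeseries[["rest"]])
    norm_rest <- lapply(timeseries[["rest"]], function(ts) {
      normalize_connectivity(connectivity_from_timeseries(ts))
    })
    lapply_named(tasks, function(task) {
      ids <- intersect(rest_ids, names(timeseries[[task]]))
      pots <- lapply(ids, function(id) {
        task_m <- normalize_connectivity(
          connectivity_from_timeseries(timeseries[[task]][[id]]))
        task_potency(task_m, norm_rest[[id]])
      })
      vectorize_edges(pots, task = task, subject_ids = ids)
    })
  })

  # --- harmonization -------------------------------------------------------
  if (config$run_harmonization && cfg$n_sites > 1L) {
    edge_tables <- run_stage("harmonize", lapply_named(tasks, function(task) {
      et <- edge_tables[[task]]
      rows <- match(et$subject_ids, cohort$subject_id)
      combat_harmonize(et, site = cohort$site[rows],
                       covariates = cohort[rows, c("age", "sex", "group")])
    }))
  }

  # --- normative deviations and case-control statistics --------------------
  normative <- run_stage("normative", lapply_named(tasks, function(task) {
    et <- edge_tables[[task]]
    rows <- match(et$subject_ids, cohort$subject_id)
    grp <- cohort$group[rows]
    covs <- cohort[rows, c("age", "sex")]
    td <- grp == "td"; aut <- grp == "autism"
    k <- min(config$normative_folds, sum(td))
    td_dev <- td_crossval_deviations(et$values[td, , drop = FALSE],
                                     covs[td, , drop = FALSE], k = k,
                                     seed = derive_seed(seed, 11L),
                                     basis = config$normative_basis)
    td_dev$task <- task
    model <- fit_normative_model(et$values[td, , drop = FALSE],
                                 covs[td, , drop = FALSE],
                                 basis = config$normative_basis)
    aut_dev <- deviation_scores(model, et$values[aut, , drop = FALSE],
                                covs[aut, , drop = FALSE],
                                provenance = "autism_full_model")
    aut_dev$task <- task
    aut_dev$subject_ids <- et$subject_ids[aut]
    perc_td <- atypicality_percentage(td_dev, config$z_threshold)
    perc_aut <- atypicality_percentage(aut_dev, config$z_threshold)
    cmp <- compare_groups(perc_aut, perc_td, task = task)
    list(td_dev = td_dev, aut_dev = aut_dev, model = model,
         perc_td = perc_td, perc_autism = perc_aut, comparison = cmp)
  }))
  qvals <- bh_fdr(vapply(normative, function(x) x$comparison$p, numeric(1)))
  group_table <- data.frame(
    task = tasks,
    t = vapply(normative, function(x) x$comparison$t, numeric(1)),
    df = vapply(normative, function(x) x$comparison$df, numeric(1)),
    p = vapply(normative, function(x) x$comparison$p, numeric(1)),
    q = qvals,
    cohens_d = vapply(normative, function(x) x$comparison$cohens_d, numeric(1)),
    mean_autism = vapply(normative, function(x) x$comparison$mean_autism, numeric(1)),
    mean_td = vapply(normative, function(x) x$comparison$mean_td, numeric(1)),
    row.names = NULL)

  # --- cross-task similarity ----------------------------------------------
  crosstask <- run_stage("crosstask", {
    pat_aut <- lapply_named(tasks, function(task) {
      group_mean_pattern(normative[[task]]$aut_dev)
    })
    pat_td <- lapply_named(tasks, function(task) {
      group_mean_pattern(normative[[task]]$td_dev)
    })
    sim_aut <- task_similarity_matrix(pat_aut)
    sim_td <- task_similarity_matrix(pat_td)
    list(similarity_autism = sim_aut, similarity_td = sim_td,
         mean_offdiag_autism = mean(sim_aut[upper.tri(sim_aut)]),
         mean_offdiag_td = mean(sim_td[upper.tri(sim_td)]),
         wilcoxon = compare_similarity(sim_aut, sim_td))
  })

  # --- region-level atypicality report ------------------------------------
  atlas <- make_atlas(cfg$n_regions, cfg$n_networks)
  region_report <- lapply_named(tasks, function(task) {
    rs <- region_scores(group_mean_pattern(normative[[task]]$aut_dev), atlas)
    list(scores = rs, top = top_regions(rs, config$top_region_fraction))
  })

  # --- brain-behavior CCA (autistic subjects only) ------------------------
  cca <- NULL
  if (config$run_cca) {
    cca <- run_stage("cca", {
      beh_imp <- impute_behavior_rf(beh$behavior,
                                    seed = derive_seed(seed, 21L))
      lapply_named(tasks, function(task) {
        ids <- normative[[task]]$aut_dev$subject_ids
        rows <- match(ids, cohort$subject_id)
        Y <- behavior_matrix(beh_imp[rows, , drop = FALSE])
        cv <- crossval_cca(normative[[task]]$aut_dev, Y,
                           n_splits = config$cv_splits,
                           k_folds = config$cv_folds,
                           n_components = config$pca_components,
                           seed = derive_seed(seed, 31L),
                           global_pca = config$global_pca)
        null_dist <- permutation_null_cca(normative[[task]]$aut_dev, Y,
                                          cohort$site[rows],
                                          n_permutations = config$permutations,
                                          k_folds = config$cv_folds,
                                          n_components = config$pca_components,
                                          seed = derive_seed(seed, 41L),
                                          global_pca = config$global_pca)
        sig <- assess_significance(cv$test_dist, null_dist,
                                   config$significance_percentile)
        loads <- canonical_loadings(cv$reference$fit,
                                    cv$reference$reduced$scores, Y)
        rs <- region_scores(cv$reference$edge_weights, atlas)
        list(crossval = cv, null_dist = null_dist, significance = sig,
             behavior_loadings = loads$behavior,
             edge_weights = cv$reference$edge_weights,
             top_regions = top_regions(rs, config$top_region_fraction))
      })
    })
  }

  report <- list(
    n_subjects = nrow(cohort),
    n_autism = cfg$n_autism, n_td = cfg$n_td,
    tasks = tasks,
    group_comparisons = group_table,
    crosstask = list(
      similarity_autism = unclass(crosstask$similarity_autism),
      similarity_td = unclass(crosstask$similarity_td),
      mean_offdiag_autism = crosstask$mean_offdiag_autism,
      mean_offdiag_td = crosstask$mean_offdiag_td,
      wilcoxon_p = crosstask$wilcoxon$p,
      wilcoxon_statistic = crosstask$wilcoxon$statistic),
    top_regions = lapply(region_report, function(x) x$top),
    cca = if (!is.null(cca)) lapply(cca, function(x) {
      list(test_mean = x$significance$test_mean,
           null_quantile = x$significance$null_quantile,
           significant = x$significance$significant,
           stability_behavior = mean(x$crossval$stability_behavior),
           stability_brain = mean(x$crossval$stability_brain),
           behavior_loadings = x$behavior_loadings,
           top_regions = x$top_regions)
    })
  )
  bundle <- list(report = report, cohort = cohort, behavior = beh$behavior,
                 edge_tables = edge_tables, normative = normative,
                 crosstask = crosstask, region = region_report, cca = cca,
                 atlas = atlas, config = config)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(cohort, file.path(config$out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(beh$behavior, file.path(config$out_dir, "behavior.csv"),
                     row.names = FALSE)
    for (task in tasks) {
      write_edge_table(edge_tables[[task]],
                       file.path(config$out_dir,
                                 sprintf("potency_edges_%s.tsv", task)))
    }
    write_atlas(atlas, file.path(config$out_dir, "atlas.tsv"))
  }
  invisible(bundle)
}

lapply_named <- function(x, fn) {
  out <- lapply(x, fn)
  names(out) <- x
  out
}
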