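# Edge-level synthetic generators. These simulate potency edge tables (and
# deviation-score tables) directly, skipping the time-series stage, so that
# the normative, cross-task and brain-behavior analyses can be exercised and
# calibrated at realistic subject counts in seconds.

#' Simulate a cohort of potency edge tables with known generating model
#'
#' Each edge follows a linear normative surface
#' `y = b0 + b_age * age_c + b_sex * male + site offset + noise`, with
#' heterogeneous per-edge noise SDs. Autistic subjects additionally express,
#' on one support edge set shared by every task, a fixed signed deviation
#' pattern scaled by their severity-dependent amplitude - the ground truth
#' that the normative deviation, cross-task similarity and brain-behavior
#' analyses are meant to recover. The generating parameters are returned so
#' tests can compute oracle deviation Z-scores.
#'
#' @param n_autism,n_td Group sizes (either may be 0).
#' @param n_edges Number of edges E.
#' @param tasks Character vector of task labels.
#' @param n_sites Number of sites.
#' @param age_range,sex_balance Cohort covariate distributions.
#' @param severity_offset Autism mean shift of the latent severity axis.
#' @param noise_sd_range Per-edge residual SDs drawn uniformly from this range.
#' @param age_slope_sd,sex_effect_sd,site_effect_sd SDs of the per-edge age
#'   slopes, sex offsets and per-site offsets.
#' @param support_frac Fraction of edges in the shared deviation support.
#' @param deviation_sd Deviation amplitude (in units of the edge's own noise
#'   SD) for an autistic subject at severity equal to the group mean;
#'   per-subject amplitude is `deviation_sd * (1 + (severity -
#'   severity_offset) / 4)`, floored at 0, so severity modulates deviation
#'   strength.
#' @param seed Integer seed.
#' @return List: `cohort` (with `subject_id`, `site`, `age`, `sex`, `group`,
#'   `severity`), `edges` (named list of `"edge_table"`s, one per task),
#'   `truth` (list with `intercepts`, `age_slopes`, `sex_offsets`,
#'   `site_offsets`, `noise_sd`, `support`, `dev_scale` (per subject),
#'   `age_center`).
#' @export
simulate_potency_cohort <- function(n_autism, n_td, n_edges,
                                    tasks = c("hariri", "flanker", "reward_s",
                                              "reward_ns", "tom"),
                                    n_sites = 1L,
                                    age_range = c(6, 30),
                                    sex_balance = 0.5,
                                    severity_offset = 1.5,
                                    noise_sd_range = c(0.8, 1.2),
                                    age_slope_sd = 0.02,
                                    sex_effect_sd = 0.1,
                                    site_effect_sd = 0,
                                    support_frac = 0.05,
                                    deviation_sd = 0,
                                    seed = 1L) {
  n <- n_autism + n_td
  stopifnot(n >= 1L, n_edges >= 1L)
  with_seed(seed, {
    group <- rep(c("autism", "td"), c(n_autism, n_td))
    severity <- stats::rnorm(n) + ifelse(group == "autism", severity_offset, 0)
    cohort <- data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      site = paste0("site", sample.int(n_sites, n, replace = TRUE)),
      age = stats::runif(n, age_range[1], age_range[2]),
      sex = ifelse(stats::runif(n) < sex_balance, "male", "female"),
      group = group,
      severity = severity
    )
    age_center <- mean(age_range)
    truth <- list(
      intercepts = stats::rnorm(n_edges, 0, 0.3),
      age_slopes = stats::rnorm(n_edges, 0, age_slope_sd),
      sex_offsets = stats::rnorm(n_edges, 0, sex_effect_sd),
      site_offsets = matrix(stats::rnorm(n_sites * n_edges, 0, site_effect_sd),
                            nrow = n_sites),
      noise_sd = stats::runif(n_edges, noise_sd_range[1], noise_sd_range[2]),
      support = sort(sample.int(n_edges, round(support_frac * n_edges))),
      age_center = age_center
    )
    dev_scale <- ifelse(group == "autism" & deviation_sd > 0,
                        pmax(deviation_sd *
                               (1 + (severity - severity_offset) / 4), 0),
                        0)
    truth$dev_scale <- dev_scale

    mu <- matrix(truth$intercepts, n, n_edges, byrow = TRUE) +
      outer(cohort$age - age_center, truth$age_slopes) +
      outer(as.numeric(cohort$sex == "male"), truth$sex_offsets) +
      truth$site_offsets[as.integer(sub("site", "", cohort$site)), ,
                         drop = FALSE]
    sd_row <- matrix(truth$noise_sd, n, n_edges, byrow = TRUE)

    # Fixed signed deviation pattern on the support, shared by every task:
    # autistic subjects express it proportionally to their severity-scaled
    # deviation amplitude, giving a consistent spatial pattern across
    # individuals and tasks.
    truth$pattern <- sample(c(-1, 1), length(truth$support),
                            replace = TRUE) *
      stats::runif(length(truth$support), 0.6, 1)
    edges <- lapply(tasks, function(task) {
      Y <- mu + matrix(stats::rnorm(n * n_edges), n, n_edges) * sd_row
      if (length(truth$support) > 0 && any(dev_scale > 0)) {
        dev <- outer(dev_scale, truth$pattern) *
          sd_row[, truth$support, drop = FALSE]
        Y[, truth$support] <- Y[, truth$support] + dev
      }
      rownames(Y) <- cohort$subject_id
      edge_table(Y, subject_ids = cohort$subject_id, task = task)
    })
    names(edges) <- tasks
    list(cohort = cohort, edges = edges, truth = truth)
  })
}

#' Simulate deviation-score tables with a shared autism support
#'
#' Draws subjects x edges Z-score tables directly: standard normal everywhere,
#' with autistic subjects' Z-scores inflated (SD `1 + deviation_sd`) on one
#' support edge set shared by all tasks, and optionally a weak shared TD
#' pattern. This is the minimal structure under which the cross-task
#' similarity analysis should find correlated group-mean atypicality patterns
#' in autism but not TD.
#'
#' @param n_autism,n_td Group sizes.
#' @param n_edges Number of edges.
#' @param tasks Task labels.
#' @param support_frac Fraction of edges in the shared support.
#' @param deviation_sd Extra SD of autism Z-scores on the support.
#' @param td_deviation_sd Extra SD of TD Z-scores on a separate TD support
#'   (0 = unstructured TD noise).
#' @param seed Integer seed.
#' @return List: `cohort` (subject_id, group), `deviations` (named list per
#'   task of subjects x E Z matrices), `support` (edge indices).
#' @export
simulate_deviation_tables <- function(n_autism, n_td, n_edges,
                                      tasks = c("hariri", "flanker",
                                                "reward_s", "reward_ns",
                                                "tom"),
                                      support_frac = 0.05,
                                      deviation_sd = 1,
                                      td_deviation_sd = 0,
                                      seed = 1L) {
  n <- n_autism + n_td
  with_seed(seed, {
    group <- rep(c("autism", "td"), c(n_autism, n_td))
    support <- sort(sample.int(n_edges, round(support_frac * n_edges)))
    td_support <- if (td_deviation_sd > 0) {
      sort(sample.int(n_edges, round(support_frac * n_edges)))
    } else {
      integer(0)
    }
    deviations <- lapply(tasks, function(task) {
      Z <- matrix(stats::rnorm(n * n_edges), n, n_edges)
      if (length(support) > 0 && n_autism > 0) {
        aut <- which(group == "autism")
        Z[aut, support] <- Z[aut, support] *
          (1 + deviation_sd)
      }
      if (length(td_support) > 0 && n_td > 0) {
        td <- which(group == "td")
        Z[td, td_support] <- Z[td, td_support] * (1 + td_deviation_sd)
      }
      rownames(Z) <- sprintf("sub-%04d", seq_len(n))
      Z
    })
    names(deviations) <- tasks
    list(cohort = data.frame(subject_id = sprintf("sub-%04d", seq_len(n)),
                             group = group),
         deviations = deviations, support = support)
  })
}
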