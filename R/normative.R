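# Per-edge normative modelling of potency against age and sex in typically
# developing subjects, out-of-sample deviation Z-scores, the percent-atypical
# statistic, and case-control comparisons.

edge_values_of <- function(edges) {
  if (inherits(edges, "edge_table")) edges$values else as.matrix(edges)
}

# Design matrix for the normative basis. `age_center` is the training mean.
normative_design <- function(covariates, basis, age_center, keep = NULL) {
  if (!all(c("age", "sex") %in% names(covariates))) {
    stop("covariates must contain `age` and `sex`")
  }
  age_c <- covariates$age - age_center
  male <- as.numeric(covariates$sex == "male")
  X <- switch(basis,
    quadratic = cbind(intercept = 1, age = age_c, age2 = age_c^2, sex = male),
    linear = cbind(intercept = 1, age = age_c, sex = male),
    stop(sprintf("unknown basis \"%s\"", basis))
  )
  if (!is.null(keep)) X <- X[, keep, drop = FALSE]
  X
}

#' Fit per-edge normative models of potency on age and sex
#'
#' Bayesian linear regression of every edge on the basis
#' `[1, age_c, age_c^2, sex]` (age centered on the training mean; a purely
#' linear basis is available via `basis = "linear"`), fit in typically
#' developing subjects only. With a flat coefficient prior the posterior is
#' available in closed form; the coefficient posterior covariance
#' `sigma2 * (X'X)^-1` is retained so predictions carry uncertainty from the
#' local availability of training data in covariate space.
#'
#' Columns of the design that are constant in the training set (e.g. `sex`
#' in a single-sex cohort) are dropped with a warning.
#'
#' @param td_edges `"edge_table"` or subjects x E matrix for the typically
#'   developing training subjects.
#' @param covariates Data frame aligned with the rows of `td_edges`, with
#'   numeric `age` (years) and `sex` in `{"female", "male"}`.
#' @param basis `"quadratic"` (default) or `"linear"`.
#' @param min_train Minimum number of training subjects (default 20).
#' @param var_floor Floor on the per-edge residual variance (default 1e-6),
#'   guarding against degenerate (noise-free) edges.
#' @return List of class `"normative_model"`: `coef` (p x E), `sigma2` (E),
#'   `xtx_inv` (p x p), `basis`, `columns`, `age_center`, `n_train`.
#' @export
fit_normative_model <- function(td_edges, covariates, basis = "quadratic",
                                min_train = 20L, var_floor = 1e-6) {
  Y <- edge_values_of(td_edges)
  n <- nrow(Y)
  if (n < min_train) {
    stop(sprintf("need at least %d training subjects, got %d", min_train, n))
  }
  if (nrow(covariates) != n) stop("covariates must align with edge rows")
  if (anyNA(covariates$age) || anyNA(covariates$sex)) {
    stop("training covariates must be complete")
  }
  age_center <- mean(covariates$age)
  X <- normative_design(covariates, basis, age_center)
  const <- apply(X[, -1L, drop = FALSE], 2L, function(x) stats::sd(x) == 0)
  if (any(const)) {
    dropped <- colnames(X)[-1L][const]
    warning(sprintf("dropping constant design column(s): %s",
                    paste(dropped, collapse = ", ")))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  p <- ncol(X)
  xtx <- crossprod(X)
  xtx_inv <- solve(xtx)
  B <- xtx_inv %*% crossprod(X, Y)             # p x E
  resid <- Y - X %*% B
  sigma2 <- pmax(colSums(resid^2) / max(n - p, 1L), var_floor)
  structure(list(coef = B, sigma2 = sigma2, xtx_inv = xtx_inv,
                 basis = basis, columns = colnames(X),
                 age_center = age_center, n_train = n),
            class = "normative_model")
}

#' Deviation Z-scores against a normative model
#'
#' For each subject and edge, `Z = (y - yhat) / sigma_pred` with predictive
#' variance `sigma_pred^2 = sigma2 * (1 + x' (X'X)^-1 x)`: the residual
#' variance plus the coefficient-uncertainty term, so subjects in sparsely
#' sampled covariate regions are judged against wider normative ranges.
#' Because covariate effects enter through `yhat`, downstream statistics on
#' Z are inherently corrected for age and sex.
#'
#' Subjects with missing covariates are excluded (with a message).
#'
#' @param model A `"normative_model"`.
#' @param edges `"edge_table"` or subjects x E matrix to score.
#' @param covariates Data frame aligned with `edges` rows (`age`, `sex`).
#' @param provenance Row provenance label stored in the result (e.g.
#'   `"autism_full_model"`).
#' @return List of class `"deviance_table"`: `task`, `subject_ids`,
#'   `z` (subjects x E), `provenance` (per row).
#' @export
deviation_scores <- function(model, edges, covariates,
                             provenance = "scored") {
  stopifnot(inherits(model, "normative_model"))
  Y <- edge_values_of(edges)
  ids <- if (inherits(edges, "edge_table")) edges$subject_ids else rownames(Y)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_len(nrow(Y)))
  if (nrow(covariates) != nrow(Y)) stop("covariates must align with edge rows")
  ok <- !(is.na(covariates$age) | is.na(covariates$sex))
  if (!all(ok)) {
    message(sprintf("excluding %d subject(s) with missing covariates: %s",
                    sum(!ok), paste(ids[!ok], collapse = ", ")))
    Y <- Y[ok, , drop = FALSE]
    covariates <- covariates[ok, , drop = FALSE]
    ids <- ids[ok]
  }
  X <- normative_design(covariates, model$basis, model$age_center,
                        keep = model$columns)
  pred <- X %*% model$coef
  h <- rowSums((X %*% model$xtx_inv) * X)
  # sigma_pred^2 = sigma2 (per edge) * (1 + h) (per subject)
  sigma_pred <- sqrt(outer(1 + h, model$sigma2))
  Z <- (Y - pred) / sigma_pred
  structure(list(task = if (inherits(edges, "edge_table")) edges$task else NULL,
                 subject_ids = ids, z = Z,
                 provenance = rep(provenance, nrow(Z))),
            class = "deviance_table")
}

#' @export
print.deviance_table <- function(x, ...) {
  cat(sprintf("<deviance_table> task=%s subjects=%d edges=%d\n",
              x$task %||% "?", nrow(x$z), ncol(x$z)))
  invisible(x)
}

#' Out-of-sample deviation scores for the normative (TD) group via k-fold CV
#'
#' Splits the typically developing subjects into `k` folds; each fold is
#' scored by the normative model fit on the remaining folds, so every TD
#' subject receives a Z-score row that their own data did not influence.
#'
#' @inheritParams fit_normative_model
#' @param k Number of folds (default 10; must satisfy `2 <= k <= n`).
#' @param seed Integer seed for the fold assignment.
#' @return A `"deviance_table"` with one row per TD subject (original row
#'   order), provenance `"td_crossval"`.
#' @export
td_crossval_deviations <- function(td_edges, covariates, k = 10L, seed = 1L,
                                   basis = "quadratic") {
  Y <- edge_values_of(td_edges)
  n <- nrow(Y)
  if (k < 2L) stop("`k` must be >= 2")
  if (k > n) stop(sprintf("`k` (%d) exceeds the number of TD subjects (%d)",
                          k, n))
  ids <- if (inherits(td_edges, "edge_table")) td_edges$subject_ids else rownames(Y)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_len(n))
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  Z <- matrix(NA_real_, n, ncol(Y), dimnames = list(ids, colnames(Y)))
  for (f in seq_len(k)) {
    test <- fold == f
    model <- fit_normative_model(Y[!test, , drop = FALSE],
                                 covariates[!test, , drop = FALSE],
                                 basis = basis)
    dt <- deviation_scores(model, Y[test, , drop = FALSE],
                           covariates[test, , drop = FALSE])
    Z[test, ] <- dt$z
  }
  structure(list(task = if (inherits(td_edges, "edge_table")) td_edges$task else NULL,
                 subject_ids = ids, z = Z,
                 provenance = rep("td_crossval", n),
                 folds = fold),
            class = "deviance_table")
}

#' Percentage of edges flagged as atypical
#'
#' The fraction (as a percentage) of a subject's edges whose deviation
#' Z-score exceeds the threshold in magnitude. The default threshold 2.571
#' nominally captures the 1% most extreme positive and negative values of a
#' standard normal.
#'
#' @param z One subject's Z-score vector, or a subjects x E matrix (then one
#'   percentage per row is returned).
#' @param z_threshold Magnitude threshold (default 2.571).
#' @return Percentage(s) in `[0, 100]`.
#' @export
atypicality_percentage <- function(z, z_threshold = 2.571) {
  if (inherits(z, "deviance_table")) z <- z$z
  if (is.matrix(z)) {
    if (ncol(z) == 0L) stop("no edges")
    if (any(!is.finite(z))) stop("non-finite Z-scores present")
    return(100 * rowMeans(abs(z) > z_threshold))
  }
  if (length(z) == 0L) stop("no edges")
  if (any(!is.finite(z))) stop("non-finite Z-scores present")
  100 * mean(abs(z) > z_threshold)
}

#' Case-control comparison of percent-atypical scores
#'
#' Two-sample t test (pooled variance by default, matching the pooled-SD
#' Cohen's d; Welch via `var_equal = FALSE`) of the subject-level
#' percent-atypical scores, plus Cohen's d with pooled SD.
#'
#' @param perc_autism,perc_td Percent-atypical scores per subject.
#' @param task Optional task label carried into the result.
#' @param var_equal Pooled-variance t test if `TRUE` (default).
#' @return List of class `"group_comparison"`: `task`, `t`, `df`, `p`,
#'   `cohens_d`, `mean_autism`, `mean_td`, `sd_autism`, `sd_td`,
#'   `n_autism`, `n_td` (`q` is added across tasks by the caller via
#'   [bh_fdr()]).
#' @export
compare_groups <- function(perc_autism, perc_td, task = NULL,
                           var_equal = TRUE) {
  if (length(perc_autism) < 2L || length(perc_td) < 2L) {
    stop("each group needs at least 2 subjects")
  }
  tt <- stats::t.test(perc_autism, perc_td, var.equal = var_equal)
  n1 <- length(perc_autism); n2 <- length(perc_td)
  sp <- sqrt(((n1 - 1) * stats::var(perc_autism) +
                (n2 - 1) * stats::var(perc_td)) / (n1 + n2 - 2))
  d <- if (sp > 0) (mean(perc_autism) - mean(perc_td)) / sp else 0
  structure(list(task = task,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, cohens_d = d,
                 mean_autism = mean(perc_autism), mean_td = mean(perc_td),
                 sd_autism = stats::sd(perc_autism), sd_td = stats::sd(perc_td),
                 n_autism = n1, n_td = n2),
            class = "group_comparison")
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]) with
#' input validation; in this pipeline the family is the set of per-task
#' case-control p values.
#'
#' @param pvals Numeric vector of p values in `[0, 1]`.
#' @return Adjusted q values, same length, capped at 1.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}
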