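# Multi-site harmonization of potency edge tables: parametric empirical-Bayes
# location/scale adjustment per edge (the original ComBat model), with
# biological covariates (age, sex, group) protected.

#' Harmonize an edge table across acquisition sites
#'
#' Removes additive and multiplicative site effects from every edge while
#' protecting the covariate effects: each edge is standardized against the
#' covariate-adjusted grand mean and pooled variance, per-site location
#' (gamma) and scale (delta) parameters are estimated and shrunk toward
#' their across-edge priors by parametric empirical Bayes
#' (normal / inverse-gamma), and the adjusted values are back-transformed
#' with covariate effects re-added.
#'
#' Diagnostic group is included as a protected covariate by default so that
#' case-control differences are not absorbed as site effects. Edges that are
#' constant across all subjects are passed through unchanged with a warning.
#' A single-site table is returned unchanged.
#'
#' @param edges An `"edge_table"` (subjects x E) or numeric matrix.
#' @param site Per-subject site labels (length = number of subjects).
#' @param covariates Data frame with one row per subject; columns `age`
#'   (numeric), `sex`, `group` (factors or characters) are used when present.
#'   May be `NULL` for a covariate-free model.
#' @param eb_tol,eb_max_iter Convergence of the empirical-Bayes fixed-point
#'   iteration for the per-site posteriors.
#' @return The harmonized `"edge_table"`; the fitted model (class
#'   `"harmonization_model"`: `gamma_star`, `delta_star` (sites x E),
#'   `sites`, `covariates_used`, `var_pooled`) is attached as
#'   `$harmonization`.
#' @export
combat_harmonize <- function(edges, site, covariates = NULL,
                             eb_tol = 1e-4, eb_max_iter = 100L) {
  et <- if (inherits(edges, "edge_table")) edges else edge_table(as.matrix(edges))
  Y <- et$values                      # subjects x E
  n <- nrow(Y)
  site <- factor(site)
  if (length(site) != n) stop("`site` must have one label per subject")
  counts <- table(site)
  if (any(counts < 2L)) {
    stop(sprintf("site(s) with fewer than 2 subjects: %s",
                 paste(names(counts)[counts < 2L], collapse = ", ")))
  }
  if (!is.null(covariates) && nrow(covariates) != n) {
    stop("`covariates` must have one row per subject")
  }

  cov_used <- character(0)
  Xcov <- NULL
  if (!is.null(covariates)) {
    keep <- intersect(c("age", "sex", "group"), names(covariates))
    if (length(keep) > 0) {
      cv <- covariates[keep]
      if (anyNA(cv)) stop("covariates must be complete (no missing values)")
      mm <- stats::model.matrix(~ ., data = cv)[, -1L, drop = FALSE]
      # drop constant covariate columns (e.g. single-sex cohorts)
      mm <- mm[, apply(mm, 2L, function(x) stats::sd(x) > 0), drop = FALSE]
      if (ncol(mm) > 0) {
        Xcov <- mm
        cov_used <- colnames(mm)
      }
    }
  }

  if (nlevels(site) < 2L) {
    message("single site: nothing to harmonize, returning input")
    et$harmonization <- structure(
      list(gamma_star = matrix(0, 1L, ncol(Y)),
           delta_star = matrix(1, 1L, ncol(Y)),
           sites = levels(site), covariates_used = cov_used,
           var_pooled = apply(Y, 2L, stats::var)),
      class = "harmonization_model")
    return(et)
  }

  const_edge <- apply(Y, 2L, function(x) stats::sd(x) == 0)
  if (any(const_edge)) {
    warning(sprintf("%d constant edge(s) passed through unharmonized",
                    sum(const_edge)))
  }
  active <- which(!const_edge)
  Ya <- Y[, active, drop = FALSE]

  B <- stats::model.matrix(~ site - 1)            # n x n.sites
  design <- cbind(B, Xcov)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    stop("site indicators and covariates are confounded (rank-deficient design)")
  }
  beta <- qr.coef(qrd, Ya)                        # (sites + q) x E
  ns <- nlevels(site)
  site_frac <- as.numeric(counts) / n
  grand_mean <- drop(crossprod(site_frac, beta[seq_len(ns), , drop = FALSE]))
  resid <- Ya - design %*% beta
  var_pooled <- colSums(resid^2) / n

  stand_mean <- matrix(grand_mean, n, length(active), byrow = TRUE)
  if (!is.null(Xcov)) {
    stand_mean <- stand_mean +
      Xcov %*% beta[-seq_len(ns), , drop = FALSE]
  }
  sd_row <- matrix(sqrt(var_pooled), n, length(active), byrow = TRUE)
  S <- (Ya - stand_mean) / sd_row                 # standardized data

  gamma_hat <- apply_by_site(S, site, colMeans)
  delta_hat <- apply_by_site(S, site, function(x) apply(x, 2L, stats::var))

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (b in seq_len(ns)) {
    idx <- which(site == levels(site)[b])
    nb <- length(idx)
    g_hat <- gamma_hat[b, ]
    d_hat <- delta_hat[b, ]
    g_bar <- mean(g_hat); t2 <- stats::var(g_hat)
    m <- mean(d_hat); s2 <- stats::var(d_hat)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    g_star <- g_hat; d_star <- d_hat
    Sb <- S[idx, , drop = FALSE]
    change <- Inf; it <- 0L
    while (change > eb_tol && it < eb_max_iter) {
      it <- it + 1L
      g_new <- (t2 * nb * g_hat + d_star * g_bar) / (t2 * nb + d_star)
      ss <- colSums((Sb - matrix(g_new, nb, ncol(Sb), byrow = TRUE))^2)
      d_new <- (b_prior + 0.5 * ss) / (nb / 2 + a_prior - 1)
      change <- max(abs(g_new - g_star) / abs(g_star + 1e-12),
                    abs(d_new - d_star) / abs(d_star + 1e-12))
      g_star <- g_new; d_star <- d_new
    }
    gamma_star[b, ] <- g_star
    delta_star[b, ] <- d_star
  }

  adj <- S
  for (b in seq_len(ns)) {
    idx <- which(site == levels(site)[b])
    adj[idx, ] <- (S[idx, , drop = FALSE] -
                     matrix(gamma_star[b, ], length(idx), ncol(S), byrow = TRUE)) /
      matrix(sqrt(delta_star[b, ]), length(idx), ncol(S), byrow = TRUE)
  }
  out <- Y
  out[, active] <- adj * sd_row + stand_mean

  res <- edge_table(out, subject_ids = et$subject_ids, task = et$task,
                    edge_idx = et$edge_index, n_regions = et$n_regions)
  full_gamma <- matrix(0, ns, ncol(Y))
  full_delta <- matrix(1, ns, ncol(Y))
  full_gamma[, active] <- gamma_star
  full_delta[, active] <- delta_star
  res$harmonization <- structure(
    list(gamma_star = full_gamma, delta_star = full_delta,
         sites = levels(site), covariates_used = cov_used,
         var_pooled_active = var_pooled, active_edges = active),
    class = "harmonization_model")
  res
}

apply_by_site <- function(S, site, fn) {
  t(vapply(levels(site), function(lv) {
    fn(S[site == lv, , drop = FALSE])
  }, numeric(ncol(S))))
}
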