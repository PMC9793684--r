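# Subject-level connectome construction: regularized covariance, partial
# correlations, Fisher-Z, per-matrix Gaussian-gamma mixture normalization,
# and task potency (normalized task minus normalized rest).

new_connectivity_matrix <- function(values, subject_id, condition, state) {
  check_symmetric_zero_diag(values, what = "connectivity matrix")
  structure(list(subject_id = subject_id, condition = condition,
                 values = values, state = state),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> subject=%s condition=%s state=%s (%d x %d)\n",
              x$subject_id, x$condition, x$state,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

ts_values <- function(ts) {
  if (inherits(ts, "time_series")) ts$values else as.matrix(ts)
}

#' Regularized covariance of a regional time series
#'
#' Ledoit-Wolf-type shrinkage of the sample covariance toward a scaled
#' identity target. The shrinkage intensity is estimated from the data
#' (minimizing expected Frobenius risk) and recorded in the result's
#' `"shrinkage"` attribute for audit; it can be forced via `shrinkage`.
#'
#' @param ts A `"time_series"` or a T x R numeric matrix (rows = time points).
#' @param shrinkage Optional fixed shrinkage intensity in `[0, 1]`;
#'   `NULL` (default) estimates it.
#' @param min_timepoints Minimum admissible T (default 30).
#' @return R x R symmetric positive-definite covariance matrix with
#'   attributes `"shrinkage"` and `"target_scale"`.
#' @export
shrinkage_covariance <- function(ts, shrinkage = NULL, min_timepoints = 30L) {
  X <- ts_values(ts)
  n <- nrow(X); p <- ncol(X)
  if (n < min_timepoints) {
    stop(sprintf("need at least %d time points, got %d", min_timepoints, n))
  }
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(X)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant time series in region(s): %s",
                 paste(bad, collapse = ", ")))
  }
  Xc <- sweep(X, 2L, colMeans(X))
  S <- crossprod(Xc) / n
  m <- mean(diag(S))
  if (is.null(shrinkage)) {
    d2 <- sum((S - diag(m, p))^2) / p
    sq_norms <- rowSums(Xc^2)
    cross <- sum((Xc %*% S) * Xc)
    b_bar2 <- (sum(sq_norms^2) - 2 * cross + n * sum(S^2)) / p / n^2
    b2 <- min(b_bar2, d2)
    lambda <- if (d2 > 0) b2 / d2 else 1
  } else {
    if (shrinkage < 0 || shrinkage > 1) stop("`shrinkage` must be in [0, 1]")
    lambda <- shrinkage
  }
  Sigma <- lambda * diag(m, p) + (1 - lambda) * S
  dimnames(Sigma) <- list(colnames(X), colnames(X))
  attr(Sigma, "shrinkage") <- lambda
  attr(Sigma, "target_scale") <- m
  Sigma
}

#' Partial correlations from a covariance matrix
#'
#' Inverts the covariance and rescales the precision matrix:
#' `p_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)`. The diagonal is set to 0.
#'
#' @param cov Symmetric positive-definite covariance matrix.
#' @return R x R partial-correlation matrix, values in `[-1, 1]`, diagonal 0.
#' @export
partial_correlation <- function(cov) {
  if (!is.matrix(cov) || nrow(cov) != ncol(cov)) stop("`cov` must be square")
  if (max(abs(cov - t(cov))) > 1e-8) stop("`cov` must be symmetric")
  U <- tryCatch(chol(cov),
                error = function(e) stop("`cov` is singular or not positive-definite"))
  Theta <- chol2inv(U)
  d <- sqrt(diag(Theta))
  P <- -Theta / tcrossprod(d)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  P[P > 1] <- 1; P[P < -1] <- -1
  dimnames(P) <- dimnames(cov)
  P
}

#' Fisher-Z (arctanh) transformation
#'
#' Variance-stabilizes correlations. For matrix input the diagonal is forced
#' to 0 before and after (arctanh(1) is undefined; self-correlations carry no
#' information).
#'
#' @param values Correlation matrix or numeric vector with off-diagonal
#'   magnitudes strictly below 1.
#' @return Same shape, elementwise `atanh`.
#' @export
fisher_z <- function(values) {
  if (is.matrix(values)) {
    v <- values
    diag(v) <- 0
    if (any(abs(v) >= 1)) stop("off-diagonal correlations must satisfy |r| < 1")
    z <- atanh(v)
    diag(z) <- 0
    z
  } else {
    if (any(abs(values) >= 1)) stop("correlations must satisfy |r| < 1")
    atanh(values)
  }
}

#' Fit a Gaussian-gamma mixture to a matrix's edge distribution
#'
#' Models one subject's Fisher-Z edge distribution as a central Gaussian
#' (null edges) plus a positive gamma for values above the Gaussian mean and
#' a mirrored negative gamma below it (reliable signal tails). Fitting is by
#' EM; gamma components are anchored at the current Gaussian mean and updated
#' by weighted method of moments. The main Gaussian's mean and SD are the
#' normalization parameters used by [normalize_connectivity()].
#'
#' If EM does not converge, or the main Gaussian ends up carrying half the
#' mass or less, the fit falls back to robust location/scale (median and
#' 1.4826 * MAD), flagged by `converged = FALSE` with a warning.
#'
#' @param values Numeric vector of at least 500 non-constant edge values
#'   (e.g. the upper triangle of a Fisher-Z matrix).
#' @param max_iter,tol EM stopping rule: stop when the mean per-observation
#'   log-likelihood change is below `tol` (default 1e-8; the likelihood has
#'   a shallow ridge trading Gaussian scale against gamma mass, so a loose
#'   tolerance stops visibly short of the optimum) or after `max_iter`
#'   (default 2000) iterations.
#' @param min_values Minimum number of values required (default 500).
#' @return List of class `"mixture_fit"`: `weight_gauss`, `mean_gauss`,
#'   `sd_gauss`, `weight_pos`, `shape_pos`, `scale_pos`, `weight_neg`,
#'   `shape_neg`, `scale_neg`, `loglik`, `converged`, `n_iter`.
#' @export
fit_edge_mixture <- function(values, max_iter = 2000L, tol = 1e-8,
                             min_values = 500L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < min_values) {
    stop(sprintf("need at least %d edge values, got %d", min_values, length(v)))
  }
  if (stats::sd(v) == 0) stop("edge values are constant; cannot fit mixture")

  mu <- stats::median(v)
  sigma <- stats::mad(v)
  if (sigma == 0) sigma <- stats::sd(v)
  # method-of-moments start for a gamma on tail excesses
  gamma_start <- function(d) {
    if (length(d) >= 5L && stats::sd(d) > 0) {
      m <- mean(d); s2 <- stats::var(d)
      c(shape = max(m^2 / s2, 0.1), scale = max(s2 / m, 1e-8))
    } else {
      c(shape = 2, scale = max(sigma, 1e-8))
    }
  }
  gp <- gamma_start(v[v > mu + 2 * sigma] - mu)
  gn <- gamma_start(mu - v[v < mu - 2 * sigma])
  w <- c(0.9, 0.05, 0.05)

  dens <- function(mu, sigma, gp, gn, w) {
    d <- cbind(w[1] * stats::dnorm(v, mu, sigma),
               ifelse(v > mu,
                      w[2] * stats::dgamma(v - mu, shape = gp[1], scale = gp[2]),
                      0),
               ifelse(v < mu,
                      w[3] * stats::dgamma(mu - v, shape = gn[1], scale = gn[2]),
                      0))
    d[!is.finite(d)] <- 0
    d
  }

  ll_old <- -Inf
  converged_em <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- dens(mu, sigma, gp, gn, w)
    rs <- rowSums(d)
    rs[rs <= 0] <- .Machine$double.xmin
    ll <- sum(log(rs))
    r <- d / rs
    # M-step
    nk <- colSums(r)
    w <- nk / length(v)
    mu_new <- sum(r[, 1] * v) / max(nk[1], 1e-12)
    sigma_new <- sqrt(sum(r[, 1] * (v - mu_new)^2) / max(nk[1], 1e-12))
    mu <- mu_new
    sigma <- max(sigma_new, 1e-8)
    # weighted gamma MLE on tail excesses (Newton in the shape)
    wgamma <- function(rk, d) {
      sk <- sum(rk)
      if (sk < 1e-8) return(NULL)
      d <- pmax(d, 1e-12)
      m <- sum(rk * d) / sk
      cstat <- log(m) - sum(rk * log(d)) / sk
      if (!is.finite(cstat) || cstat <= 0) return(NULL)
      s <- (3 - cstat + sqrt((cstat - 3)^2 + 24 * cstat)) / (12 * cstat)
      for (i in 1:8) {
        s <- s - (log(s) - digamma(s) - cstat) / (1 / s - trigamma(s))
        s <- min(max(s, 0.05), 1e4)
      }
      c(shape = s, scale = max(m / s, 1e-8))
    }
    up <- v > mu
    gp_new <- wgamma(r[up, 2], v[up] - mu)
    if (!is.null(gp_new)) gp <- gp_new
    dn <- v < mu
    gn_new <- wgamma(r[dn, 3], mu - v[dn])
    if (!is.null(gn_new)) gn <- gn_new
    if (abs(ll - ll_old) / length(v) < tol) {
      converged_em <- TRUE
      break
    }
    ll_old <- ll
  }

  fit <- list(weight_gauss = w[1], mean_gauss = mu, sd_gauss = sigma,
              weight_pos = w[2], shape_pos = unname(gp[1]),
              scale_pos = unname(gp[2]),
              weight_neg = w[3], shape_neg = unname(gn[1]),
              scale_neg = unname(gn[2]),
              loglik = ll, converged = converged_em, n_iter = iter)
  if (!converged_em || fit$weight_gauss <= 0.5) {
    warning("mixture fit degenerate (non-convergence or main Gaussian weight <= 0.5); falling back to robust location/scale")
    rmu <- stats::median(v)
    rsd <- stats::mad(v)
    if (rsd == 0) rsd <- stats::sd(v)
    fit$mean_gauss <- rmu
    fit$sd_gauss <- rsd
    fit$weight_gauss <- 1
    fit$weight_pos <- 0
    fit$weight_neg <- 0
    fit$converged <- FALSE
  }
  class(fit) <- "mixture_fit"
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> gauss: w=%.3f mu=%.4f sd=%.4f | gamma+: w=%.3f | gamma-: w=%.3f | converged=%s\n",
              x$weight_gauss, x$mean_gauss, x$sd_gauss,
              x$weight_pos, x$weight_neg, x$converged))
  invisible(x)
}

#' Build a raw Fisher-Z connectivity matrix from a time series
#'
#' Convenience composition: [shrinkage_covariance()] then
#' [partial_correlation()] then [fisher_z()].
#'
#' @param ts A `"time_series"` object or T x R matrix.
#' @param subject_id,condition Labels (taken from `ts` when available).
#' @return A `"connectivity_matrix"` with `state = "raw_fisher_z"` and the
#'   shrinkage intensity recorded in `$shrinkage`.
#' @export
connectivity_from_timeseries <- function(ts, subject_id = NULL,
                                         condition = NULL) {
  if (inherits(ts, "time_series")) {
    if (is.null(subject_id)) subject_id <- ts$subject_id
    if (is.null(condition)) condition <- ts$condition
  }
  S <- shrinkage_covariance(ts)
  Z <- fisher_z(partial_correlation(S))
  m <- new_connectivity_matrix(Z, subject_id, condition, "raw_fisher_z")
  m$shrinkage <- attr(S, "shrinkage")
  m
}

#' Normalize a connectivity matrix by its main-Gaussian parameters
#'
#' Every off-diagonal entry is mapped to `(v - mu0) / sigma0` where `mu0`,
#' `sigma0` are the fitted main-Gaussian mean and SD from the matrix's own
#' edge distribution; the diagonal stays 0.
#'
#' @param m A `"connectivity_matrix"` with `state = "raw_fisher_z"`.
#' @param fit A `"mixture_fit"` from this matrix's own edges; fitted here
#'   via [fit_edge_mixture()] if omitted.
#' @return The matrix with `state = "normalized"` and the fit attached as
#'   `$mixture_fit`.
#' @export
normalize_connectivity <- function(m, fit = NULL) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (m$state != "raw_fisher_z") {
    stop("input must be in state \"raw_fisher_z\"")
  }
  if (is.null(fit)) {
    R <- nrow(m$values)
    fit <- fit_edge_mixture(m$values[edge_subscripts(R)],
                            min_values = min(500L, R * (R - 1L) / 2L))
  }
  if (fit$sd_gauss <= 0) stop("main Gaussian SD must be > 0")
  V <- (m$values - fit$mean_gauss) / fit$sd_gauss
  diag(V) <- 0
  out <- new_connectivity_matrix(V, m$subject_id, m$condition, "normalized")
  out$mixture_fit <- fit
  out
}

#' Task potency: normalized task minus normalized rest connectivity
#'
#' The elementwise difference between a subject's normalized task matrix and
#' their normalized resting-state matrix, interpreted as the connectivity
#' modulation the task induces away from the subject's own baseline.
#'
#' @param task_m,rest_m Normalized `"connectivity_matrix"` objects for the
#'   same subject and region count.
#' @return List of class `"potency_matrix"`: `subject_id`, `task`, `values`.
#' @export
task_potency <- function(task_m, rest_m) {
  stopifnot(inherits(task_m, "connectivity_matrix"),
            inherits(rest_m, "connectivity_matrix"))
  if (task_m$state != "normalized" || rest_m$state != "normalized") {
    stop("both matrices must be normalized")
  }
  if (!identical(task_m$subject_id, rest_m$subject_id)) {
    stop("subject mismatch between task and rest matrices")
  }
  if (!identical(dim(task_m$values), dim(rest_m$values))) {
    stop("region-count mismatch between task and rest matrices")
  }
  structure(list(subject_id = task_m$subject_id, task = task_m$condition,
                 values = task_m$values - rest_m$values),
            class = "potency_matrix")
}

#' Edge table: vectorized symmetric matrices
#'
#' Stacks symmetric zero-diagonal matrices into a subjects x E matrix using
#' the frozen upper-triangle row-major edge order of [edge_index()].
#'
#' @param matrices List of `"potency_matrix"`/`"connectivity_matrix"` objects
#'   or plain symmetric matrices, one per subject.
#' @param task Task label for the table (taken from the first element when
#'   available).
#' @param subject_ids Subject identifiers (taken from elements when
#'   available).
#' @return List of class `"edge_table"`: `task`, `subject_ids`,
#'   `edge_index` (see [edge_index()]), `values` (subjects x E), `n_regions`.
#' @export
vectorize_edges <- function(matrices, task = NULL, subject_ids = NULL) {
  vals <- lapply(matrices, function(m) if (is.list(m)) m$values else m)
  R <- nrow(vals[[1L]])
  if (any(vapply(vals, function(v) !identical(dim(v), c(R, R)), logical(1)))) {
    stop("all matrices must share the same region count")
  }
  if (is.null(subject_ids)) {
    subject_ids <- vapply(seq_along(matrices), function(k) {
      m <- matrices[[k]]
      if (is.list(m) && !is.null(m$subject_id)) m$subject_id else sprintf("sub%03d", k)
    }, character(1))
  }
  if (is.null(task) && is.list(matrices[[1L]])) {
    task <- matrices[[1L]]$task %||% matrices[[1L]]$condition
  }
  sub <- edge_subscripts(R)
  values <- t(vapply(vals, function(v) v[sub], numeric(nrow(sub))))
  idx <- edge_index(R)
  rownames(values) <- subject_ids
  colnames(values) <- idx$label
  edge_table(values, subject_ids = subject_ids, task = task,
             edge_idx = idx, n_regions = R)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct an edge table directly from a subjects x E matrix
#'
#' Used by the edge-level simulators and file readers. When `n_regions` is
#' given, E must equal R(R-1)/2 and the frozen edge order is attached.
#'
#' @param values Subjects x E numeric matrix.
#' @param subject_ids Row identifiers.
#' @param task Task label.
#' @param edge_idx Optional [edge_index()] data frame.
#' @param n_regions Optional region count.
#' @return An `"edge_table"`.
#' @export
edge_table <- function(values, subject_ids = rownames(values), task = NULL,
                       edge_idx = NULL, n_regions = NULL) {
  values <- as.matrix(values)
  if (is.null(subject_ids)) subject_ids <- sprintf("sub%03d", seq_len(nrow(values)))
  if (!is.null(n_regions) && is.null(edge_idx)) {
    if (ncol(values) != n_regions * (n_regions - 1L) / 2L) {
      stop("E must equal R(R-1)/2 for the given `n_regions`")
    }
    edge_idx <- edge_index(n_regions)
  }
  structure(list(task = task, subject_ids = as.character(subject_ids),
                 edge_index = edge_idx, values = values,
                 n_regions = n_regions),
            class = "edge_table")
}

#' @export
print.edge_table <- function(x, ...) {
  cat(sprintf("<edge_table> task=%s subjects=%d edges=%d\n",
              x$task %||% "?", nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Rebuild a symmetric matrix from one row of edge values
#'
#' Inverse of [vectorize_edges()] for a single subject: exact round trip for
#' symmetric zero-diagonal matrices.
#'
#' @param edge_values E-vector in the frozen edge order.
#' @param n_regions Region count R with E = R(R-1)/2.
#' @return R x R symmetric matrix with zero diagonal.
#' @export
unvectorize_edges <- function(edge_values, n_regions) {
  R <- as.integer(n_regions)
  E <- R * (R - 1L) / 2L
  if (length(edge_values) != E) {
    stop(sprintf("expected %d edge values for R=%d, got %d",
                 E, R, length(edge_values)))
  }
  m <- matrix(0, R, R)
  sub <- edge_subscripts(R)
  m[sub] <- edge_values
  m[sub[, 2:1]] <- edge_values
  m
}
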