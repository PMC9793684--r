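# Cross-task similarity of the group-level deviation pattern: does the
# spatial layout of connectome atypicality repeat across task conditions?

#' Group-mean edgewise atypicality pattern
#'
#' Per-edge mean of the absolute deviation Z-score over a group's subjects
#' (signed means via `absolute = FALSE`).
#'
#' @param dev A `"deviance_table"` or subjects x E Z matrix.
#' @param subjects Subject ids or logical/integer row selector for the group;
#'   `NULL` uses all rows.
#' @param absolute Average `|Z|` (default) rather than signed Z.
#' @return Numeric E-vector.
#' @export
group_mean_pattern <- function(dev, subjects = NULL, absolute = TRUE) {
  Z <- if (inherits(dev, "deviance_table")) dev$z else as.matrix(dev)
  if (!is.null(subjects)) {
    rows <- if (is.character(subjects)) {
      ids <- if (inherits(dev, "deviance_table")) dev$subject_ids else rownames(Z)
      match(subjects, ids)
    } else {
      subjects
    }
    if (anyNA(rows)) stop("unknown subject id(s) in `subjects`")
    Z <- Z[rows, , drop = FALSE]
  }
  if (nrow(Z) == 0L) stop("empty group")
  if (absolute) colMeans(abs(Z)) else colMeans(Z)
}

#' Task-by-task similarity matrix of atypicality patterns
#'
#' Pairwise Pearson correlations between per-task group-mean edgewise
#' atypicality patterns.
#'
#' @param patterns Named list of E-vectors (one per task) or an E x T matrix
#'   with task column names.
#' @return T x T correlation matrix (class `"similarity_matrix"` attribute
#'   kept informal): symmetric, unit diagonal.
#' @export
task_similarity_matrix <- function(patterns) {
  P <- if (is.list(patterns)) do.call(cbind, patterns) else as.matrix(patterns)
  if (ncol(P) < 2L) stop("need at least 2 tasks")
  sds <- apply(P, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(P)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop(sprintf("constant atypicality pattern for task(s): %s",
                 paste(bad, collapse = ", ")))
  }
  S <- stats::cor(P)
  diag(S) <- 1
  S
}

#' Compare cross-task similarity between groups
#'
#' Paired Wilcoxon signed-rank test on the T(T-1)/2 unique off-diagonal
#' task-pair correlations of the two groups' similarity matrices. Zero
#' differences are dropped (the exact-method convention); the exact null
#' distribution is used for up to 25 remaining pairs, the normal
#' approximation above that. With 5 tasks and complete separation the exact
#' two-sided p attains its floor 2/2^10.
#'
#' @param sim_autism,sim_td T x T similarity matrices over the same task set.
#' @return List of class `"wilcoxon_result"`: `statistic` (V), `p`
#'   (two-sided), `n_pairs` (= T(T-1)/2), `n_used` (after dropping zeros),
#'   `differences` (autism minus TD, per pair).
#' @export
compare_similarity <- function(sim_autism, sim_td) {
  if (!identical(dim(sim_autism), dim(sim_td))) {
    stop("similarity matrices must have identical dimensions")
  }
  if (!is.null(colnames(sim_autism)) && !is.null(colnames(sim_td)) &&
      !identical(colnames(sim_autism), colnames(sim_td))) {
    stop("similarity matrices must cover the same task set in the same order")
  }
  Tn <- nrow(sim_autism)
  if (Tn < 2L) stop("need at least 2 tasks")
  ut <- upper.tri(sim_autism)
  d <- sim_autism[ut] - sim_td[ut]
  n_pairs <- length(d)
  dnz <- d[d != 0]
  if (length(dnz) == 0L) {
    warning("all task-pair differences are zero; signed-rank statistic undefined, returning p = 1")
    return(structure(list(statistic = NA_real_, p = 1,
                          n_pairs = n_pairs, n_used = 0L, differences = d),
                     class = "wilcoxon_result"))
  }
  wt <- stats::wilcox.test(dnz, mu = 0, exact = length(dnz) <= 25L,
                           correct = TRUE)
  structure(list(statistic = unname(wt$statistic), p = wt$p.value,
                 n_pairs = n_pairs, n_used = length(dnz), differences = d),
            class = "wilcoxon_result")
}
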