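# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
# All user-facing stochastic operations route through this so that identical
# (input, seed) pairs give identical output without clobbering the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Fan a master seed out to per-stage seeds by a fixed counter scheme.
# Keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) * 1009 + 97 * as.numeric(counter)) %% 2147483647)
}

#' Edge index for the frozen upper-triangle ordering
#'
#' Edges of an R-region symmetric zero-diagonal matrix are stored in a fixed
#' order: upper triangle (i < j), row-major, with 0-based region indices as
#' given by the atlas. For R = 4 the first edges are (0,1), (0,2), (0,3),
#' (1,2), ...
#'
#' @param n_regions Number of atlas regions R.
#' @return A data frame with integer columns `i` and `j` (0-based, i < j) and
#'   E = R(R-1)/2 rows, plus a `label` column `"i_j"`.
#' @export
edge_index <- function(n_regions) {
  R <- as.integer(n_regions)
  if (is.na(R) || R < 2L) stop("`n_regions` must be an integer >= 2")
  i <- rep.int(seq_len(R - 1L), times = (R - 1L):1L) - 1L
  j <- unlist(lapply(seq_len(R - 1L), function(k) (k + 1L):R), use.names = FALSE) - 1L
  data.frame(i = i, j = j, label = paste(i, j, sep = "_"))
}

# 1-based matrix subscripts for the frozen edge order.
edge_subscripts <- function(n_regions) {
  idx <- edge_index(n_regions)
  cbind(idx$i + 1L, idx$j + 1L)
}

check_symmetric_zero_diag <- function(m, tol = 1e-10, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop(sprintf("%s must be square", what), call. = FALSE)
  }
  if (any(!is.finite(m))) stop(sprintf("%s contains non-finite entries", what), call. = FALSE)
  if (max(abs(m - t(m))) > tol) stop(sprintf("%s is not symmetric", what), call. = FALSE)
  if (max(abs(diag(m))) > tol) stop(sprintf("%s diagonal is not zero", what), call. = FALSE)
  invisible(TRUE)
}
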