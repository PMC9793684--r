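# Atlas handling and region-level aggregation of edge scores.

#' Construct a block atlas definition
#'
#' Regions indexed 0..R-1, assigned to `n_networks` contiguous network
#' blocks (the remainder joins the last block). Region identity is abstract:
#' no operation in this package needs voxel geometry.
#'
#' @param n_regions,n_networks Atlas dimensions (defaults 168 regions in 11
#'   networks).
#' @return Data frame of class `"atlas"`: `index` (0-based), `name`,
#'   `network` (1..n_networks).
#' @export
make_atlas <- function(n_regions = 168L, n_networks = 11L) {
  R <- as.integer(n_regions)
  K <- as.integer(n_networks)
  if (K < 1L || K > R) stop("`n_networks` must be in [1, n_regions]")
  sizes <- rep(R %/% K, K)
  sizes[K] <- sizes[K] + R %% K
  atlas <- data.frame(index = seq_len(R) - 1L,
                      name = sprintf("region%03d", seq_len(R) - 1L),
                      network = rep.int(seq_len(K), sizes))
  class(atlas) <- c("atlas", "data.frame")
  atlas
}

#' Read / write an atlas TSV (columns: index, name, network)
#' @param path File path.
#' @return `read_atlas`: an `"atlas"` data frame.
#' @export
read_atlas <- function(path) {
  atlas <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("index", "name", "network") %in% names(atlas))) {
    stop("atlas file must have columns index, name, network")
  }
  if (!identical(as.integer(atlas$index), seq_len(nrow(atlas)) - 1L)) {
    stop("atlas indices must be contiguous 0..R-1")
  }
  class(atlas) <- c("atlas", "data.frame")
  atlas
}

#' @rdname read_atlas
#' @param atlas An `"atlas"` data frame.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(atlas, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Region-level scores from an edge-level vector
#'
#' A region's score is the mean absolute value over the R-1 edges incident
#' to it, turning edge-level atypicality (or CCA weight) maps into a
#' per-region profile.
#'
#' @param edge_values E-vector in the frozen edge order, E = R(R-1)/2.
#' @param atlas An `"atlas"` (or an integer region count).
#' @return Named numeric R-vector of region scores.
#' @export
region_scores <- function(edge_values, atlas) {
  R <- if (is.numeric(atlas) && length(atlas) == 1L) as.integer(atlas) else nrow(atlas)
  E <- R * (R - 1L) / 2L
  if (length(edge_values) != E) {
    stop(sprintf("expected %d edge values for R=%d regions, got %d",
                 E, R, length(edge_values)))
  }
  m <- unvectorize_edges(abs(edge_values), R)
  scores <- rowSums(m) / (R - 1L)
  names(scores) <- if (is.data.frame(atlas)) atlas$name else sprintf("region%03d", seq_len(R) - 1L)
  scores
}

#' Top-scoring regions
#'
#' The `ceiling(fraction * R)` regions with the highest scores, in
#' descending score order; ties are broken by ascending region index.
#'
#' @param scores Region score vector (e.g. from [region_scores()]).
#' @param fraction Fraction of regions to keep, in (0, 1] (default 0.10).
#' @return Data frame: `index` (0-based), `name`, `score`, ordered.
#' @export
top_regions <- function(scores, fraction = 0.10) {
  if (fraction <= 0 || fraction > 1) stop("`fraction` must be in (0, 1]")
  R <- length(scores)
  k <- ceiling(fraction * R)
  ord <- order(-scores, seq_len(R))[seq_len(k)]
  data.frame(index = ord - 1L,
             name = names(scores)[ord] %||% sprintf("region%03d", ord - 1L),
             score = unname(scores[ord]))
}

#' Write / read an edge table as TSV
#'
#' Rows are subjects, columns are edge labels `"i_j"` in the frozen
#' upper-triangle row-major order; the first column holds subject ids.
#'
#' @param et An `"edge_table"`.
#' @param path File path.
#' @export
write_edge_table <- function(et, path) {
  df <- data.frame(subject_id = et$subject_ids, et$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_table
#' @param task Task label to attach.
#' @param n_regions Optional region count (attaches the edge index).
#' @export
read_edge_table <- function(path, task = NULL, n_regions = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df[[1L]]
  edge_table(vals, subject_ids = df[[1L]], task = task,
             n_regions = n_regions)
}
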