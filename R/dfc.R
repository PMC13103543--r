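#' Enumerate sliding windows
#'
#' Returns the start indices of every fixed-length window that fits into a
#' scan of `T` time points when advanced by `step`: the count is
#' `floor((T - window_length)/step) + 1`, the first window starts at 0 and the
#' last ends at or before `T`. With 230 retained volumes, a 22-TR window and a
#' 1-TR step this gives 209 overlapping windows.
#'
#' @param n_time Number of time points `T`.
#' @param window_length Window length in time points (>= 2).
#' @param step Step between consecutive window starts (>= 1).
#' @return A data.frame with columns `index` (1-based ordinal), `start`
#'   (0-based inclusive) and `length`.
#' @export
enumerate_windows <- function(n_time, window_length, step = 1L) {
  stopifnot(window_length >= 2, step >= 1)
  if (n_time < window_length) {
    stop(sprintf("insufficient data: T = %d < window length %d",
                 n_time, window_length))
  }
  n_win <- (n_time - window_length) %/% step + 1L
  data.frame(index = seq_len(n_win),
             start = (seq_len(n_win) - 1L) * as.integer(step),
             length = as.integer(window_length))
}

#' Fisher r-to-z transform with boundary stabilization
#'
#' Correlations are clamped to `[-1 + epsilon, 1 - epsilon]` before `atanh`
#' so that perfectly correlated pairs map to a large finite z rather than
#' infinity. The transform is odd, strictly increasing and fixes 0.
#'
#' @param r Numeric vector of correlations.
#' @param epsilon Clamp half-width (default 1e-7).
#' @return Fisher-z values.
#' @export
fisher_z <- function(r, epsilon = 1e-7) {
  atanh(pmin(pmax(r, -1 + epsilon), 1 - epsilon))
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Edges are enumerated row-major over pairs `i < j` with node order equal to
#' the input column order, the order used for all edge vectors and centroids
#' in the package.
#'
#' @param m Symmetric numeric matrix.
#' @return Numeric vector of length `N(N-1)/2`.
#' @export
matrix_to_edge <- function(m) {
  tm <- t(m)
  tm[lower.tri(tm)]
}

#' Rebuild a symmetric matrix from an edge vector
#'
#' Inverse of [matrix_to_edge()]: the diagonal is zero and
#' `matrix_to_edge(edge_to_matrix(v, N))` reproduces `v` exactly.
#'
#' @param edge_vector Numeric vector of length `N(N-1)/2`.
#' @param n_nodes Number of nodes `N`.
#' @param labels Optional node labels for dimnames.
#' @return An `N x N` symmetric matrix with zero diagonal.
#' @export
edge_to_matrix <- function(edge_vector, n_nodes, labels = NULL) {
  e_expected <- n_nodes * (n_nodes - 1) / 2
  if (length(edge_vector) != e_expected) {
    stop(sprintf("edge vector length %d does not match N = %d (expected %d)",
                 length(edge_vector), n_nodes, e_expected))
  }
  tm <- matrix(0, n_nodes, n_nodes)
  tm[lower.tri(tm)] <- edge_vector
  m <- t(tm)
  m <- m + t(m)
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

#' Names for the edges of an edge vector
#'
#' @param labels Character vector of node labels.
#' @return Character vector `"<nodeA>__<nodeB>"` in edge-vector order.
#' @export
edge_names <- function(labels) {
  n <- length(labels)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  paste0(labels[idx[, 1]], "__", labels[idx[, 2]])
}

#' Windowed connectivity for a single window
#'
#' Pearson correlations over the window for every node pair `i < j`, clamped
#' at the +-1 boundary and Fisher z-transformed. A window is invalid when any
#' pairwise correlation is undefined (a node with zero variance in the
#' window) or any transformed value is non-finite; invalid windows carry an
#' `NA` edge vector and are excluded downstream rather than imputed.
#'
#' @param ts A `subject_timeseries`.
#' @param start 0-based window start.
#' @param window_length Window length in time points.
#' @param epsilon Boundary clamp half-width.
#' @return List with `edges` (length `N(N-1)/2`) and `valid` (logical).
#' @export
window_connectivity <- function(ts, start, window_length, epsilon = 1e-7) {
  stopifnot(inherits(ts, "subject_timeseries"),
            start >= 0, start + window_length <= nrow(ts$data))
  slab <- ts$data[(start + 1):(start + window_length), , drop = FALSE]
  r <- suppressWarnings(stats::cor(slab))
  edges <- matrix_to_edge(r)
  valid <- all(is.finite(edges))
  z <- fisher_z(edges, epsilon)
  valid <- valid && all(is.finite(z))
  list(edges = z, valid = valid)
}

#' Build the full windowed dFC series for one subject
#'
#' Applies [enumerate_windows()] and [window_connectivity()] over the scan,
#' preserving window order and validity flags; window slots are never dropped
#' here (exclusion of invalid windows happens at state-assignment time).
#'
#' @param ts A `subject_timeseries`.
#' @param cfg A [dfc_config()].
#' @return A `dfc_window_series` object: list with `subject_id`,
#'   `node_labels`, `windows` (data.frame `index`, `start`, `valid`), and
#'   `edges` (W x E matrix, rows of invalid windows all `NA`).
#' @export
build_dfc_series <- function(ts, cfg = dfc_config()) {
  wins <- enumerate_windows(nrow(ts$data), cfg$window_length_tr, cfg$step_tr)
  n_edge <- ncol(ts$data) * (ncol(ts$data) - 1) / 2
  edges <- matrix(NA_real_, nrow(wins), n_edge)
  valid <- logical(nrow(wins))
  for (w in seq_len(nrow(wins))) {
    res <- window_connectivity(ts, wins$start[w], wins$length[w],
                               cfg$fisher_epsilon)
    valid[w] <- res$valid
    if (res$valid) edges[w, ] <- res$edges
  }
  colnames(edges) <- edge_names(ts$node_labels)
  structure(list(subject_id = ts$subject_id, node_labels = ts$node_labels,
                 windows = cbind(wins, valid = valid), edges = edges),
            class = "dfc_window_series")
}

#' Indices of valid windows in a dFC series
#' @param series A `dfc_window_series`.
#' @return Integer vector of row indices into `series$edges`.
#' @export
valid_windows <- function(series) {
  which(series$windows$valid)
}

#' Export one subject's window dump as a data.frame
#'
#' @param series A `dfc_window_series`.
#' @return data.frame with `window_index` (1-based), `start`, `valid` and one
#'   column per edge named `"<nodeA>__<nodeB>"`.
#' @export
window_dump <- function(series) {
  cbind(data.frame(window_index = series$windows$index,
                   start = series$windows$start,
                   valid = series$windows$valid),
        as.data.frame(series$edges, check.names = FALSE))
}
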