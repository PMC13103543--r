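#' Fractional occupancy of each state
#'
#' Proportion of a subject's valid windows assigned to each state; unvisited
#' states get 0 and the vector sums to 1.
#'
#' @param labels Integer vector of state labels in `1..k` (a `state_sequence`
#'   is also accepted).
#' @param k Number of states.
#' @return Numeric k-vector.
#' @export
fractional_occupancy <- function(labels, k) {
  labels <- .seq_labels(labels)
  if (length(labels) == 0) stop("empty state sequence")
  tabulate(labels, nbins = k) / length(labels)
}

#' Mean dwell time per state (in windows)
#'
#' Run-length encodes the label sequence; the dwell time of state s is the
#' mean length of its maximal runs. States never visited are `NA` (undefined,
#' excluded listwise from group statistics), never 0. The final, censored run
#' counts like any other.
#'
#' @inheritParams fractional_occupancy
#' @return Numeric k-vector with `NA` for unvisited states.
#' @export
mean_dwell_time <- function(labels, k) {
  labels <- .seq_labels(labels)
  if (length(labels) == 0) stop("empty state sequence")
  r <- rle(labels)
  out <- rep(NA_real_, k)
  for (s in unique(r$values)) {
    out[s] <- mean(r$lengths[r$values == s])
  }
  out
}

#' Total number of state transitions
#'
#' Number of adjacent window pairs whose labels differ.
#'
#' @inheritParams fractional_occupancy
#' @return Non-negative integer.
#' @export
count_transitions <- function(labels) {
  labels <- .seq_labels(labels)
  if (length(labels) == 0) stop("empty state sequence")
  sum(labels[-1] != labels[-length(labels)])
}

#' Pairwise directed transition counts
#'
#' Entry (a, b) with a != b counts adjacent pairs going from state a to state
#' b; the diagonal is fixed at zero (self-transitions are not transitions) and
#' the matrix total equals [count_transitions()].
#'
#' @inheritParams fractional_occupancy
#' @return Integer k x k matrix with zero diagonal.
#' @export
pairwise_transition_counts <- function(labels, k) {
  labels <- .seq_labels(labels)
  if (length(labels) == 0) stop("empty state sequence")
  out <- matrix(0L, k, k)
  if (length(labels) > 1) {
    from <- labels[-length(labels)]
    to <- labels[-1]
    keep <- from != to
    for (i in which(keep)) {
      out[from[i], to[i]] <- out[from[i], to[i]] + 1L
    }
  }
  out
}

#' State-conditioned mean connectivity over a node subset
#'
#' For each state s, the mean over windows labeled s of the mean Fisher-z edge
#' value restricted to the subset's edges (all pairs within `nodes`, or all
#' pairs between `nodes` and `nodes_b` when the latter is given). With the
#' subset equal to the full node set this is the subject's state-wise FC
#' strength. Unvisited states are `NA`.
#'
#' @param series A `dfc_window_series`.
#' @param seq A `state_sequence` for the same subject.
#' @param k Number of states.
#' @param nodes Character vector of node labels (>= 2 unless `nodes_b` given).
#' @param nodes_b Optional disjoint second node set for between-set means.
#' @return Numeric k-vector with `NA` for unvisited states.
#' @export
state_mean_fc <- function(series, seq, k, nodes = series$node_labels,
                          nodes_b = NULL) {
  unknown <- setdiff(c(nodes, nodes_b), series$node_labels)
  if (length(unknown) > 0) {
    stop("unknown node label(s): ", paste(unknown, collapse = ", "))
  }
  n <- length(series$node_labels)
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  la <- series$node_labels[idx[, 1]]
  lb <- series$node_labels[idx[, 2]]
  if (is.null(nodes_b)) {
    stopifnot(length(nodes) >= 2)
    sel <- la %in% nodes & lb %in% nodes
  } else {
    if (length(intersect(nodes, nodes_b)) > 0) {
      stop("between-set node lists must be disjoint")
    }
    sel <- (la %in% nodes & lb %in% nodes_b) |
      (la %in% nodes_b & lb %in% nodes)
  }
  if (!any(sel)) stop("node subset selects no edges")
  vw <- valid_windows(series)
  win_mean <- rowMeans(series$edges[vw, sel, drop = FALSE])
  out <- rep(NA_real_, k)
  for (s in unique(seq$labels)) {
    out[s] <- mean(win_mean[seq$labels == s])
  }
  out
}

#' All temporal metrics for one subject
#'
#' @param series A `dfc_window_series`.
#' @param seq The subject's `state_sequence`.
#' @param k Number of states.
#' @param node_subsets Named list of node-label vectors passed to
#'   [state_mean_fc()] (the full node set is always included as `fc`).
#' @return One-row data.frame: `subject_id`, `n_windows`, `occupancy_s*`,
#'   `dwell_s*` (`NA` = undefined), `transitions`, `t_<a>to<b>` pair counts,
#'   and `<subset>_fc_s*` state-conditioned means.
#' @export
temporal_metrics <- function(series, seq, k, node_subsets = list()) {
  occ <- fractional_occupancy(seq$labels, k)
  dwell <- mean_dwell_time(seq$labels, k)
  trans <- count_transitions(seq$labels)
  pc <- pairwise_transition_counts(seq$labels, k)
  stopifnot(abs(sum(occ) - 1) < 1e-12, sum(pc) == trans)
  runs <- rle(seq$labels)
  for (s in unique(seq$labels)) {
    stopifnot(abs(sum(runs$values == s) * dwell[s] -
                    sum(seq$labels == s)) < 1e-9)
  }
  out <- data.frame(subject_id = seq$subject_id,
                    n_windows = length(seq$labels))
  for (s in seq_len(k)) out[[paste0("occupancy_s", s)]] <- occ[s]
  for (s in seq_len(k)) out[[paste0("dwell_s", s)]] <- dwell[s]
  out$transitions <- trans
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a != b) out[[paste0("t_", a, "to", b)]] <- pc[a, b]
  }
  subsets <- c(list(fc = series$node_labels), node_subsets)
  for (nm in names(subsets)) {
    v <- state_mean_fc(series, seq, k, subsets[[nm]])
    prefix <- if (nm == "fc") "fc" else paste0(nm, "_fc")
    for (s in seq_len(k)) out[[paste0(prefix, "_s", s)]] <- v[s]
  }
  out
}

.seq_labels <- function(labels) {
  if (inherits(labels, "state_sequence")) labels$labels else as.integer(labels)
}
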