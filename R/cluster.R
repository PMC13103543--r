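#' Exemplar windows: local maxima of connectivity variance
#'
#' Computes a per-window variance signal and returns the indices (into the
#' subject's valid windows) whose variance is strictly greater than both
#' temporal neighbors; endpoints are excluded. If no strict interior maximum
#' exists (monotone or constant signals), the first global argmax is returned
#' so that every subject contributes at least one exemplar.
#'
#' The default signal (`"across_edges"`) is the population variance over the E
#' edge values within each window; `"over_time"` instead scores each window by
#' the summed squared deviation of its edges from the subject's mean edge
#' vector (a per-edge temporal-variance reading of the same idea).
#'
#' @param series A `dfc_window_series`.
#' @param variance One of `"across_edges"`, `"over_time"`.
#' @return Integer vector of positions into `valid_windows(series)`.
#' @export
exemplar_windows <- function(series, variance = c("across_edges", "over_time")) {
  variance <- match.arg(variance)
  vw <- valid_windows(series)
  if (length(vw) < 3) {
    stop("degenerate series: fewer than 3 valid windows for subject ",
         series$subject_id)
  }
  x <- series$edges[vw, , drop = FALSE]
  v <- switch(variance,
    across_edges = {
      e <- ncol(x)
      rowSums(sweep(x, 1, rowMeans(x))^2) / e
    },
    over_time = rowSums(sweep(x, 2, colMeans(x))^2))
  local_maxima(v)
}

#' Strict local maxima of a numeric sequence
#'
#' Interior points strictly greater than both neighbors; falls back to the
#' first global argmax when none exists.
#'
#' @param v Numeric vector (length >= 3).
#' @return Integer vector of 1-based positions.
#' @export
local_maxima <- function(v) {
  n <- length(v)
  stopifnot(n >= 3)
  interior <- 2:(n - 1)
  hits <- interior[v[interior] > v[interior - 1] & v[interior] > v[interior + 1]]
  if (length(hits) == 0) hits <- which.max(v)
  hits
}

# Lloyd's k-means on a fixed set of initial centers. Ties in assignment break
# to the lowest cluster id; a cluster that empties is re-seeded at the point
# farthest from its assigned centroid.
.lloyd <- function(x, centers, max_iter) {
  k <- nrow(centers)
  xs <- rowSums(x^2)
  assign_prev <- integer(0)
  for (it in seq_len(max_iter)) {
    # squared distance up to the constant xs: -2 x.c + |c|^2
    half <- x %*% t(centers)
    d <- sweep(-2 * half, 2, rowSums(centers^2), "+")
    assignment <- max.col(-d, ties.method = "first")
    empty <- setdiff(seq_len(k), unique(assignment))
    if (length(empty) > 0) {
      dist_own <- xs + d[cbind(seq_along(assignment), assignment)]
      for (e in empty) {
        far <- which.max(dist_own)
        assignment[far] <- e
        dist_own[far] <- -Inf
      }
    }
    if (identical(assignment, assign_prev)) break
    counts <- tabulate(assignment, nbins = k)
    centers <- rowsum(x, assignment, reorder = TRUE) / counts
    assign_prev <- assignment
  }
  half <- x %*% t(centers)
  d <- sweep(-2 * half, 2, rowSums(centers^2), "+")
  assignment <- max.col(-d, ties.method = "first")
  wcss <- sum(pmax(xs + d[cbind(seq_along(assignment), assignment)], 0))
  list(centers = centers, assignment = assignment, wcss = wcss,
       iterations = it)
}

# Best-of-replicates Lloyd's k-means with uniform random distinct starting
# points; the master seed spawns one substream seed per replicate so the
# replicate set is a deterministic prefix-stable stream.
.kmeans_replicates <- function(x, k, replicates, max_iter, seed,
                               extra_starts = NULL) {
  stopifnot(nrow(x) >= k)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  best <- NULL
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    init <- x[sample.int(nrow(x), k), , drop = FALSE]
    fit <- .lloyd(x, init, max_iter)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  if (!is.null(extra_starts)) {
    for (init in extra_starts) {
      fit <- .lloyd(x, init, max_iter)
      if (fit$wcss < best$wcss) best <- fit
    }
  }
  best
}

#' Two-stage k-means state model
#'
#' Stage 1 clusters the pooled exemplar windows with best-of-`replicates`
#' Lloyd's k-means (lowest within-cluster sum of squares wins). Stage 2 runs a
#' single k-means over the full pooled window set initialized at the stage-1
#' centroids, which anchors the final solution while desensitizing it to
#' random starts. Deterministic given `seed`.
#'
#' @param exemplars Pooled exemplar matrix (windows x E).
#' @param all_windows Pooled matrix of every valid window (windows x E).
#' @param k Number of states.
#' @param replicates Stage-1 random initializations.
#' @param max_iter Lloyd iteration cap per run.
#' @param seed Master seed.
#' @return A `state_model`: list with `k`, `centroids` (k x E), `wcss`
#'   (stage-2 converged), `assignment` (stage-2 labels for `all_windows`),
#'   `seed`, `replicates`, `stage1_exemplar_count`, `stage1_wcss`.
#' @export
kmeans_two_stage <- function(exemplars, all_windows, k, replicates = 500L,
                             max_iter = 500L, seed = 1L) {
  exemplars <- as.matrix(exemplars)
  all_windows <- as.matrix(all_windows)
  stopifnot(ncol(exemplars) == ncol(all_windows))
  if (nrow(exemplars) < k) {
    stop(sprintf("infeasible: k = %d exceeds exemplar count %d",
                 k, nrow(exemplars)))
  }
  stage1 <- .kmeans_replicates(exemplars, k, replicates, max_iter, seed)
  stage2 <- .lloyd(all_windows, stage1$centers, max_iter)
  structure(list(k = as.integer(k), centroids = stage2$centers,
                 wcss = stage2$wcss, assignment = stage2$assignment,
                 seed = as.integer(seed), replicates = as.integer(replicates),
                 stage1_exemplar_count = nrow(exemplars),
                 stage1_wcss = stage1$wcss),
            class = "state_model")
}

#' Elbow curve of within-cluster sum of squares over k
#'
#' For each k in `k_range`, fits best-of-`replicates` k-means; each k > min is
#' additionally warm-started from the previous solution with its widest
#' cluster split (previous centroids plus the point farthest from its
#' centroid), which keeps the reported curve non-increasing even at modest
#' replicate counts. The knee is suggested as the k with the largest second
#' difference of log(WCSS), i.e. the strongest relative curvature of the
#' curve; the relative scale keeps the suggestion robust when one dominant
#' variance direction inflates the k = 1 to 2 drop. It is a suggestion, not
#' an automatic choice.
#'
#' @param all_windows Pooled window matrix (windows x E).
#' @param k_range Integer vector of k values (scanned in increasing order).
#' @param replicates Random initializations per k.
#' @param max_iter Lloyd iteration cap.
#' @param seed Master seed.
#' @return List with `curve` (data.frame `k`, `wcss`) and `knee` (suggested k).
#' @export
elbow_curve <- function(all_windows, k_range = 1:6, replicates = 50L,
                        max_iter = 500L, seed = 1L) {
  all_windows <- as.matrix(all_windows)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(all(k_range >= 1), max(k_range) <= nrow(all_windows))
  wcss <- numeric(length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    extra <- NULL
    if (!is.null(prev) && nrow(prev$centers) == k - 1) {
      dist_own <- rowSums((all_windows -
                             prev$centers[prev$assignment, , drop = FALSE])^2)
      split_point <- all_windows[which.max(dist_own), , drop = FALSE]
      extra <- list(rbind(prev$centers, split_point))
    }
    fit <- .kmeans_replicates(all_windows, k, replicates, max_iter,
                              seed + i - 1L, extra_starts = extra)
    wcss[i] <- fit$wcss
    prev <- fit
  }
  knee <- NA_integer_
  if (length(k_range) >= 3) {
    lw <- log(pmax(wcss, max(wcss) * 1e-12))
    second_diff <- lw[1:(length(lw) - 2)] - 2 * lw[2:(length(lw) - 1)] +
      lw[3:length(lw)]
    knee <- k_range[which.max(second_diff) + 1L]
  }
  list(curve = data.frame(k = k_range, wcss = wcss), knee = knee)
}

#' Assign windows to states by nearest centroid
#'
#' Each valid window is labeled with the centroid minimizing squared
#' Euclidean distance; ties break to the lowest state id and invalid windows
#' are omitted from the sequence.
#'
#' @param series A `dfc_window_series`.
#' @param model A `state_model`.
#' @return A `state_sequence`: list with `subject_id`, `window_index`
#'   (1-based original indices of the valid windows) and `labels` in `1..k`.
#' @export
assign_states <- function(series, model) {
  if (ncol(series$edges) != ncol(model$centroids)) {
    stop(sprintf("edge dimension mismatch: series has %d, model has %d",
                 ncol(series$edges), ncol(model$centroids)))
  }
  vw <- valid_windows(series)
  x <- series$edges[vw, , drop = FALSE]
  d <- sweep(-2 * x %*% t(model$centroids), 2,
             rowSums(model$centroids^2), "+")
  labels <- max.col(-d, ties.method = "first")
  structure(list(subject_id = series$subject_id,
                 window_index = series$windows$index[vw],
                 labels = labels),
            class = "state_sequence")
}

#' Reorder states into the reporting convention
#'
#' Model states are relabeled by ascending centroid mean z and then mapped to
#' the reporting numbering used for three-state solutions: the hypoconnected
#' (lowest mean) state is "State 2", the moderate state "State 1" and the
#' hyperconnected state "State 3". For k != 3 the ascending order itself is
#' used.
#'
#' @param model A `state_model`.
#' @return The model with centroid rows permuted, `assignment` relabeled, and
#'   a `state_map` field (old id -> new id).
#' @export
relabel_states <- function(model) {
  means <- rowMeans(model$centroids)
  asc <- order(means)  # asc[j] = old id with j-th smallest mean
  report_of_rank <- if (model$k == 3) c(2L, 1L, 3L) else seq_len(model$k)
  state_map <- integer(model$k)
  state_map[asc] <- report_of_rank
  new_order <- order(state_map[asc])  # ranks sorted by new id
  model$centroids <- model$centroids[asc[new_order], , drop = FALSE]
  model$assignment <- state_map[model$assignment]
  model$state_map <- state_map
  model
}

#' Best bijective matching between two labelings
#'
#' Exhaustive assignment over permutations (k <= 6) maximizing label
#' agreement; used to compare planted regimes with recovered states.
#'
#' @param labels_a,labels_b Integer label vectors of equal length in `1..k`.
#' @param k Number of labels.
#' @return List with `map` (label in `a` -> label in `b`) and `agreement`
#'   (fraction matched under the best map).
#' @export
match_labels <- function(labels_a, labels_b, k) {
  stopifnot(length(labels_a) == length(labels_b), k <= 6)
  conf <- matrix(0L, k, k)
  for (i in seq_along(labels_a)) {
    conf[labels_a[i], labels_b[i]] <- conf[labels_a[i], labels_b[i]] + 1L
  }
  perms <- .permutations(k)
  scores <- vapply(perms, function(p) sum(conf[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  list(map = best, agreement = max(scores) / length(labels_a))
}

.permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- .permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in 0:(k - 1L)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos)
    }
  }
  out
}
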