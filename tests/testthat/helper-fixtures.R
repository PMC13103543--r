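# Small in-code fixtures shared across test files.

# A clean multivariate-normal subject with the given correlation level.
make_ts <- function(n_time = 60, n_nodes = 5, rho = 0.2, seed = 1,
                    subject_id = "t1") {
  set.seed(seed)
  sig <- matrix(rho, n_nodes, n_nodes)
  diag(sig) <- 1
  x <- matrix(rnorm(n_time * n_nodes), ncol = n_nodes) %*% chol(sig)
  colnames(x) <- paste0("n", seq_len(n_nodes))
  subject_timeseries(x, subject_id = subject_id)
}

# Hand-made state sequence object.
make_seq <- function(labels, subject_id = "s1") {
  structure(list(subject_id = subject_id,
                 window_index = seq_along(labels),
                 labels = as.integer(labels)),
            class = "state_sequence")
}

# Hand-made window-series object from an explicit edge matrix.
make_series <- function(edges, node_labels, valid = rep(TRUE, nrow(edges)),
                        subject_id = "s1") {
  nm <- edge_names(node_labels)
  colnames(edges) <- if (length(nm) == ncol(edges)) nm
                     else paste0("e", seq_len(ncol(edges)))
  structure(list(subject_id = subject_id, node_labels = node_labels,
                 windows = data.frame(index = seq_len(nrow(edges)),
                                      start = seq_len(nrow(edges)) - 1,
                                      length = 2, valid = valid),
                 edges = edges),
            class = "dfc_window_series")
}

# Hand-made state model.
make_model <- function(centroids, k = nrow(centroids)) {
  structure(list(k = k, centroids = centroids, wcss = 0,
                 assignment = integer(0), seed = 1L, replicates = 1L,
                 stage1_exemplar_count = 0L, stage1_wcss = 0),
            class = "state_model")
}

# Three well-separated Gaussian blobs in E dims (centers ~10 sigma apart).
make_blobs <- function(n_per = 50, e = 10, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 3, e)
  centers[2, 1] <- sep
  centers[3, 2] <- sep
  x <- do.call(rbind, lapply(1:3, function(s)
    sweep(matrix(rnorm(n_per * e), n_per), 2, centers[s, ], "+")))
  list(x = x, labels = rep(1:3, each = n_per), centers = centers)
}

# Tiny calibrated regime set cached across tests (calibration is the slow bit).
tiny_regimes <- local({
  cache <- NULL
  function(n_nodes = 8, mc_windows = 2000) {
    if (is.null(cache)) {
      cache <<- build_regime_covariances(regime_spec(), n_nodes,
                                         seed = 99, mc_windows = mc_windows)
    }
    cache
  }
})
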