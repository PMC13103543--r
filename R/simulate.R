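#' Connectivity regime specification
#'
#' Defines the k latent connectivity regimes the simulator plants. Default
#' targets reproduce the per-state mean FC strength reported for the
#' three-state frontoparietal solution in the large multisite cohort that
#' anchors this package (moderate 0.198, hypoconnected 0.106, hyperconnected
#' 0.288, in reporting order), so regime 2 is the hypoconnected regime.
#'
#' @param target_mean_z Per-regime target mean Fisher-z edge connectivity of a
#'   windowed estimate.
#' @param jitter_sd SD (correlation scale) of the symmetric edge-level
#'   texture added to each regime's compound-symmetric correlation core.
#'   Empirical connectivity states differ in edge pattern, not only in mean
#'   level, and the default 0.2 gives regimes distinct edge topographies of
#'   realistic magnitude; with near-zero jitter the regimes degenerate to
#'   mean-shifted copies that no windowed estimator can tell apart reliably.
#' @param noise_sd SD of additive white observation noise on the signal.
#' @return List of class `regime_spec`.
#' @export
regime_spec <- function(target_mean_z = c(0.198, 0.106, 0.288),
                        jitter_sd = 0.2, noise_sd = 0) {
  stopifnot(length(target_mean_z) >= 1, jitter_sd >= 0, noise_sd >= 0)
  structure(list(target_mean_z = target_mean_z, jitter_sd = jitter_sd,
                 noise_sd = noise_sd),
            class = "regime_spec")
}

#' Group-specific Markov regime dynamics
#'
#' Row-stochastic transition matrices over the regimes for each group, plus
#' the minimum segment length. Defaults give both groups a majority of time
#' in the hypoconnected regime 2 and plant the case-control contrast as an
#' elevated self-transition of regime 2 in patients (0.97 vs 0.93), which
#' yields greater patient occupancy of and dwell time in the hypoconnected
#' regime and fewer total transitions -- the qualitative effect pattern the
#' pipeline is expected to recover.
#'
#' @param control,patient k x k transition matrices (rows sum to 1).
#' @param min_segment Minimum regime segment length in time points; switching
#'   is suppressed until the current segment reaches it. Keeps segments long
#'   relative to the 22-TR window so windows are regime-dominated.
#' @return List of class `group_dynamics` with per-group stationary initial
#'   distributions.
#' @export
group_dynamics <- function(
    control = matrix(c(0.91, 0.06, 0.03,
                       0.035, 0.93, 0.035,
                       0.03, 0.06, 0.91), 3, 3, byrow = TRUE),
    patient = matrix(c(0.92, 0.06, 0.02,
                       0.015, 0.97, 0.015,
                       0.02, 0.06, 0.92), 3, 3, byrow = TRUE),
    min_segment = 10L) {
  for (m in list(control, patient)) {
    stopifnot(nrow(m) == ncol(m), all(m >= 0),
              all(abs(rowSums(m) - 1) < 1e-9))
  }
  structure(list(control = control, patient = patient,
                 min_segment = as.integer(min_segment),
                 initial = list(control = stationary_distribution(control),
                                patient = stationary_distribution(patient))),
            class = "group_dynamics")
}

#' Stationary distribution of a Markov chain
#'
#' @param p Row-stochastic transition matrix.
#' @return Probability vector `pi` with `pi P = pi`.
#' @export
stationary_distribution <- function(p) {
  ev <- eigen(t(p))
  i <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, i]))
  v / sum(v)
}

#' Multisite acquisition model
#'
#' Per-site additive offset and multiplicative scale on the Fisher-z edge
#' features, realized exactly in expectation by transforming each regime's
#' correlation matrix elementwise (`r -> tanh(scale * (atanh(r) + offset))`)
#' for that site, plus the per-site subject allocation.
#'
#' @param offsets Per-site additive offsets on edge z.
#' @param scales Per-site multiplicative scales on edge z (> 0).
#' @param allocation Relative subject allocation per site (normalized).
#' @return List of class `site_model`.
#' @export
site_model <- function(offsets = c(-0.04, 0, 0.04),
                       scales = c(0.95, 1, 1.05),
                       allocation = rep(1, length(offsets))) {
  stopifnot(length(offsets) == length(scales),
            length(allocation) == length(offsets), all(scales > 0),
            all(allocation > 0))
  structure(list(n_sites = length(offsets), offsets = offsets,
                 scales = scales, allocation = allocation / sum(allocation)),
            class = "site_model")
}

# Project a symmetric matrix to the nearest unit-diagonal positive-definite
# correlation matrix (eigenvalue floor, then rescale).
.make_pd_correlation <- function(m, floor_frac = 1e-4) {
  m <- (m + t(m)) / 2
  ev <- eigen(m, symmetric = TRUE)
  lo <- floor_frac * max(ev$values)
  if (min(ev$values) < lo) {
    vals <- pmax(ev$values, lo)
    m <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
  }
  stats::cov2cor(m)
}

# Monte-Carlo estimate of the expected windowed mean edge z under Gaussian
# sampling from correlation matrix sig at the given window length.
.mc_mean_z <- function(sig, window_length, n_windows, noise_sd, epsilon) {
  n <- ncol(sig)
  ch <- chol(sig)
  x <- matrix(stats::rnorm(window_length * n_windows * n), ncol = n) %*% ch
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), sd = noise_sd)
  means <- numeric(n_windows)
  lower <- lower.tri(diag(n))
  for (w in seq_len(n_windows)) {
    r <- stats::cor(x[((w - 1) * window_length + 1):(w * window_length), ])
    means[w] <- mean(fisher_z(r[lower], epsilon))
  }
  mean(means)
}

#' Build calibrated per-regime correlation matrices
#'
#' Each regime's matrix is a compound-symmetric correlation core plus a fixed
#' symmetric jitter, projected to a positive-definite correlation matrix. The
#' core correlation is calibrated by internal Monte-Carlo so that the expected
#' windowed mean edge Fisher-z at the given window length matches the regime's
#' target within +-0.02 (finite windows bias the sample correlation, so the
#' naive `tanh(target)` is only the starting point).
#'
#' @param spec A [regime_spec()].
#' @param n_nodes Number of nodes N.
#' @param window_length Window length the targets refer to (in time points).
#' @param seed Seed for jitter and Monte-Carlo draws.
#' @param mc_windows Monte-Carlo windows per calibration evaluation (the final
#'   check uses this count; >= 1e4 recommended for the default tolerance).
#' @param iterations Calibration sweeps after the initial guess.
#' @return List of k unit-diagonal positive-definite correlation matrices with
#'   attribute `realized_mean_z` (the final Monte-Carlo check per regime).
#' @export
build_regime_covariances <- function(spec, n_nodes, window_length = 22L,
                                     seed = 1L, mc_windows = 10000L,
                                     iterations = 2L) {
  stopifnot(inherits(spec, "regime_spec"), n_nodes >= 2)
  k <- length(spec$target_mean_z)
  out <- vector("list", k)
  realized <- numeric(k)
  set.seed(seed)
  for (s in seq_len(k)) {
    target <- spec$target_mean_z[s]
    rho <- tanh(target)
    if (rho <= -1 / (n_nodes - 1) + 1e-6 || rho >= 0.999) {
      stop(sprintf("infeasible target mean z %.3f for regime %d", target, s))
    }
    jit <- matrix(stats::rnorm(n_nodes^2, sd = spec$jitter_sd), n_nodes)
    jit <- (jit + t(jit)) / 2
    diag(jit) <- 0
    build <- function(rho) {
      m <- matrix(rho, n_nodes, n_nodes) + jit
      diag(m) <- 1
      .make_pd_correlation(m)
    }
    sig <- build(rho)
    for (it in seq_len(iterations)) {
      mc <- .mc_mean_z(sig, window_length, mc_windows, spec$noise_sd, 1e-7)
      rho <- tanh(atanh(rho) + (target - mc))
      sig <- build(rho)
    }
    realized[s] <- .mc_mean_z(sig, window_length, mc_windows,
                              spec$noise_sd, 1e-7)
    if (abs(realized[s] - target) > 0.02) {
      stop(sprintf(
        "calibration failed for regime %d: realized %.4f vs target %.4f",
        s, realized[s], target))
    }
    out[[s]] <- sig
  }
  attr(out, "realized_mean_z") <- realized
  out
}

#' Simulate one subject's regime path and signal
#'
#' Samples a regime path from the Markov chain (one regime per time point,
#' with switching suppressed inside the minimum segment length), then draws
#' each time point from the current regime's multivariate normal.
#' Deterministic given `seed`.
#'
#' @param transition k x k transition matrix for this subject's group.
#' @param covariances List of k correlation matrices (one per regime).
#' @param n_time Number of time points T.
#' @param initial Initial regime distribution (default uniform).
#' @param min_segment Minimum segment length in time points.
#' @param noise_sd Additive white noise SD.
#' @param seed Integer seed.
#' @param subject_id Identifier for the returned series.
#' @param tr_seconds TR attached to the series.
#' @param node_labels Optional node labels.
#' @return List with `ts` (a `subject_timeseries`) and `path` (integer regime
#'   per time point).
#' @export
simulate_subject <- function(transition, covariances, n_time = 230L,
                             initial = NULL, min_segment = 10L, noise_sd = 0,
                             seed = 1L, subject_id = "sim",
                             tr_seconds = 2, node_labels = NULL) {
  k <- length(covariances)
  stopifnot(nrow(transition) == k, n_time >= 1)
  if (is.null(initial)) initial <- rep(1 / k, k)
  set.seed(seed)
  path <- integer(n_time)
  state <- sample.int(k, 1, prob = initial)
  seg <- 1L
  path[1] <- state
  for (t in seq_len(n_time)[-1]) {
    if (seg >= min_segment) {
      nxt <- sample.int(k, 1, prob = transition[state, ])
      if (nxt != state) seg <- 0L
      state <- nxt
    }
    seg <- seg + 1L
    path[t] <- state
  }
  n_nodes <- ncol(covariances[[1]])
  x <- matrix(NA_real_, n_time, n_nodes)
  for (s in unique(path)) {
    rows <- which(path == s)
    x[rows, ] <- matrix(stats::rnorm(length(rows) * n_nodes),
                        ncol = n_nodes) %*% chol(covariances[[s]])
  }
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), sd = noise_sd)
  if (is.null(node_labels)) node_labels <- paste0("fpn", seq_len(n_nodes))
  colnames(x) <- node_labels
  list(ts = subject_timeseries(x, tr_seconds = tr_seconds,
                               subject_id = subject_id),
       path = path)
}

#' Planted window-level regime labels
#'
#' Converts a per-time-point regime path into per-window ground truth: each
#' window takes its majority regime, ties resolved by the regime at the
#' window's center time point. A window overlapping a regime switch mixes two
#' covariance structures and, below some dominance fraction, has no
#' well-defined true label; `min_purity` marks such windows `NA` so recovery
#' can be scored where truth exists (0.5 keeps the plain majority label for
#' every window).
#'
#' @param path Integer regime path.
#' @param window_length,step Window parameters.
#' @param min_purity Minimum fraction of the window's time points the
#'   majority regime must cover; windows below it get `NA`.
#' @return Integer vector, one label per window (`NA` = ambiguous).
#' @export
planted_window_labels <- function(path, window_length = 22L, step = 1L,
                                  min_purity = 0.5) {
  path <- as.integer(path)
  wins <- enumerate_windows(length(path), window_length, step)
  vapply(seq_len(nrow(wins)), function(w) {
    seg <- path[(wins$start[w] + 1):(wins$start[w] + wins$length[w])]
    counts <- tabulate(seg)
    if (max(counts) < min_purity * length(seg)) return(NA_integer_)
    top <- which(counts == max(counts))
    if (length(top) == 1) top else seg[ceiling(length(seg) / 2)]
  }, integer(1))
}

#' Simulate pure regime-labeled connectivity windows
#'
#' Draws windows directly as planted Gaussian regimes in edge-feature space:
#' each window is an independent windowed Fisher-z estimate from exactly one
#' regime's multivariate normal (no regime mixing within a window), with
#' per-subject window counts and regime proportions. This is the clean
#' clustering benchmark: recovery failures cannot be blamed on boundary
#' windows.
#'
#' @param covariances List of k regime correlation matrices.
#' @param n_subjects Number of subjects.
#' @param windows_per_subject Windows per subject.
#' @param occupancy Regime proportions (defaults to equal).
#' @param window_length Time points per window estimate.
#' @param seed Integer seed.
#' @param epsilon Fisher boundary clamp.
#' @return List with `features` (windows x E matrix), `labels` (planted
#'   regime per window), `subject` (subject index per window).
#' @export
simulate_regime_windows <- function(covariances, n_subjects = 100L,
                                    windows_per_subject = 209L,
                                    occupancy = NULL, window_length = 22L,
                                    seed = 1L, epsilon = 1e-7) {
  k <- length(covariances)
  if (is.null(occupancy)) occupancy <- rep(1 / k, k)
  stopifnot(length(occupancy) == k, all(occupancy > 0))
  occupancy <- occupancy / sum(occupancy)
  n_nodes <- ncol(covariances[[1]])
  chols <- lapply(covariances, chol)
  set.seed(seed)
  n_win <- n_subjects * windows_per_subject
  labels <- integer(n_win)
  subject <- rep(seq_len(n_subjects), each = windows_per_subject)
  features <- matrix(NA_real_, n_win, n_nodes * (n_nodes - 1) / 2)
  lower <- lower.tri(diag(n_nodes))
  row <- 0L
  for (i in seq_len(n_subjects)) {
    labs <- rep(seq_len(k),
                as.vector(stats::rmultinom(1, windows_per_subject, occupancy)))
    for (s in labs) {
      x <- matrix(stats::rnorm(window_length * n_nodes),
                  ncol = n_nodes) %*% chols[[s]]
      r <- t(stats::cor(x))
      row <- row + 1L
      labels[row] <- s
      features[row, ] <- fisher_z(r[lower], epsilon)
    }
  }
  list(features = features, labels = labels, subject = subject)
}

#' Simulate a full multisite case-control cohort
#'
#' Generates subjects with group-specific Markov regime dynamics, per-site
#' feature-level connectivity offsets/scales (via site-transformed regime
#' correlation matrices), and demographic covariates, together with a
#' planted-truth table per subject. All randomness derives from `seed`.
#'
#' @param n_control,n_patient Subjects per group.
#' @param dynamics A [group_dynamics()].
#' @param spec A [regime_spec()].
#' @param sites A [site_model()] (or `NULL` for a single neutral site).
#' @param n_time Time points per subject.
#' @param n_nodes Nodes per subject.
#' @param window_length Window length used for regime calibration.
#' @param tr_seconds Repetition time.
#' @param seed Master seed.
#' @param mc_windows Monte-Carlo windows for regime calibration.
#' @param covariances Optional pre-built base covariances (skips calibration;
#'   as returned by [build_regime_covariances()]).
#' @param out_dir Optional directory: when given, writes per-subject
#'   time-series TSVs, `metadata.tsv` and `truth_table.tsv` there.
#' @return List with `timeseries` (list of `subject_timeseries`), `cohort`
#'   (`cohort_table`), `truth` (data.frame with planted per-subject regime
#'   occupancies, transition count and path), `paths` (list of regime paths),
#'   `covariances` (base regime matrices), `out_dir`.
#' @export
simulate_cohort <- function(n_control = 100L, n_patient = 100L,
                            dynamics = group_dynamics(), spec = regime_spec(),
                            sites = site_model(), n_time = 230L,
                            n_nodes = 21L, window_length = 22L,
                            tr_seconds = 2, seed = 1L, mc_windows = 10000L,
                            covariances = NULL, out_dir = NULL) {
  stopifnot(n_control >= 1, n_patient >= 1)
  k <- length(spec$target_mean_z)
  if (is.null(covariances)) {
    covariances <- build_regime_covariances(spec, n_nodes, window_length,
                                            seed = seed,
                                            mc_windows = mc_windows)
  }
  if (is.null(sites)) sites <- site_model(offsets = 0, scales = 1)
  # site-specific regime matrices: plant offset/scale on the z features
  site_cov <- lapply(seq_len(sites$n_sites), function(s) {
    lapply(covariances, function(sig) {
      z <- atanh(sig * (1 - 1e-12))
      diag(z) <- 0
      m <- tanh(sites$scales[s] * (z + sites$offsets[s]))
      diag(m) <- 1
      .make_pd_correlation(m)
    })
  })
  n_total <- n_control + n_patient
  groups <- c(rep("control", n_control), rep("patient", n_patient))
  set.seed(seed)
  site_of <- as.integer(sample(rep_len(
    rep(seq_len(sites$n_sites),
        times = pmax(1, round(sites$allocation * n_total))), n_total)))
  subject_seeds <- sample.int(.Machine$integer.max, n_total)
  age <- pmin(pmax(round(stats::rnorm(n_total, 36, 13)), 18), 65)
  sex <- ifelse(stats::runif(n_total) < 0.37, "M", "F")
  mean_fd <- pmin(exp(stats::rnorm(n_total, log(0.08), 0.45)), 0.2)
  hamd <- ifelse(groups == "patient",
                 round(pmax(stats::rnorm(n_total, 21.2, 5.8), 8)), NA)
  illness <- ifelse(groups == "patient",
                    round(pmin(exp(stats::rnorm(n_total, 3.5, 1.0)), 400)), NA)
  medication <- ifelse(groups == "patient",
                       ifelse(stats::runif(n_total) < 0.30, NA,
                              ifelse(stats::runif(n_total) < 0.47,
                                     "medicated", "unmedicated")), NA)
  episode <- ifelse(groups == "patient",
                    ifelse(stats::runif(n_total) < 0.30, NA,
                           ifelse(stats::runif(n_total) < 0.78,
                                  "first", "recurrent")), NA)
  ids <- sprintf("sub%04d", seq_len(n_total))
  ts_list <- vector("list", n_total)
  paths <- vector("list", n_total)
  truth_rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    g <- groups[i]
    res <- simulate_subject(
      transition = dynamics[[g]],
      covariances = site_cov[[site_of[i]]],
      n_time = n_time, initial = dynamics$initial[[g]],
      min_segment = dynamics$min_segment, noise_sd = spec$noise_sd,
      seed = subject_seeds[i], subject_id = ids[i],
      tr_seconds = tr_seconds)
    ts_list[[i]] <- res$ts
    paths[[i]] <- res$path
    occ <- tabulate(res$path, nbins = k) / n_time
    row <- data.frame(subject_id = ids[i],
                      planted_transitions = sum(diff(res$path) != 0))
    for (s in seq_len(k)) row[[paste0("planted_occupancy_s", s)]] <- occ[s]
    truth_rows[[i]] <- row
  }
  cohort <- as_cohort_table(data.frame(
    subject_id = ids, group = groups, site = paste0("site", site_of),
    age = age, sex = sex, mean_fd = mean_fd, hamd = hamd,
    illness_duration_months = illness, medication = medication,
    episode = episode, stringsAsFactors = FALSE))
  truth <- do.call(rbind, truth_rows)
  truth$path <- vapply(paths, paste, character(1), collapse = ",")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (ts in ts_list) {
      write_timeseries(ts, file.path(out_dir,
                                     paste0(ts$subject_id, ".tsv")))
    }
    write_table(as.data.frame(cohort), file.path(out_dir, "metadata.tsv"))
    write_table(truth, file.path(out_dir, "truth_table.tsv"))
  }
  list(timeseries = ts_list, cohort = cohort, truth = truth, paths = paths,
       covariances = covariances, out_dir = out_dir)
}
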