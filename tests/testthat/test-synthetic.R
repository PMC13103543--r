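test_that("regime calibration hits its windowed mean-z targets", {
  # near-zero target gives a near-identity covariance
  spec0 <- regime_spec(target_mean_z = 0, jitter_sd = 0.02)
  cov0 <- build_regime_covariances(spec0, 8, seed = 2, mc_windows = 2000)
  expect_lte(abs(attr(cov0, "realized_mean_z")), 0.02)
  off_diag <- cov0[[1]][lower.tri(cov0[[1]])]
  expect_lt(max(abs(off_diag)), 0.2)

  # the three defaults are met and strictly ordered 2 < 1 < 3
  cov <- tiny_regimes()
  realized <- attr(cov, "realized_mean_z")
  expect_equal(realized, c(0.198, 0.106, 0.288), tolerance = 0.02)
  expect_true(realized[2] < realized[1] && realized[1] < realized[3])
  for (m in cov) {
    expect_true(all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > 0))
    expect_equal(diag(m), rep(1, 8))
  }

  expect_error(build_regime_covariances(
    regime_spec(target_mean_z = 5), 8, mc_windows = 500), "infeasible")
})

test_that("subject simulation is seed-deterministic and regime-faithful", {
  cov <- tiny_regimes()
  dyn <- group_dynamics()
  a <- simulate_subject(dyn$control, cov, n_time = 100, seed = 7)
  b <- simulate_subject(dyn$control, cov, n_time = 100, seed = 7)
  expect_identical(a$ts$data, b$ts$data)
  expect_identical(a$path, b$path)
  c_ <- simulate_subject(dyn$control, cov, n_time = 100, seed = 8)
  expect_false(identical(a$ts$data, c_$ts$data))

  # absorbing regime 2: constant path, zero transitions downstream
  p_abs <- diag(3)
  res <- simulate_subject(p_abs, cov, n_time = 80, initial = c(0, 1, 0),
                          seed = 3)
  expect_true(all(res$path == 2))
  expect_equal(count_transitions(res$path), 0)
})

test_that("minimum segment length is respected", {
  cov <- tiny_regimes()
  # fast-switching chain would produce short runs without the floor
  p_fast <- matrix(1 / 3, 3, 3)
  res <- simulate_subject(p_fast, cov, n_time = 300, min_segment = 10,
                          seed = 5)
  runs <- rle(res$path)
  expect_true(all(runs$lengths[-length(runs$lengths)] >= 10))
})

test_that("an equal-occupancy chain spends a third of time in each regime", {
  cov <- tiny_regimes()
  p_eq <- matrix(1 / 3, 3, 3)
  occ <- rowMeans(vapply(1:40, function(i)
    tabulate(simulate_subject(p_eq, cov, n_time = 230, min_segment = 1,
                              seed = 100 + i)$path, 3) / 230,
    numeric(3)))
  expect_equal(occ, rep(1 / 3, 3), tolerance = 0.03)
})

test_that("planted window labels follow the majority with purity marking", {
  path <- c(rep(1, 30), rep(2, 30))
  lab <- planted_window_labels(path, window_length = 10, step = 1)
  expect_equal(lab[1], 1)
  expect_equal(lab[length(lab)], 2)
  # boundary window 26..35 has 5/5 split; majority tie resolved at center
  lab2 <- planted_window_labels(path, window_length = 10, step = 1,
                                min_purity = 0.7)
  expect_true(anyNA(lab2))
  expect_equal(lab2[1], 1)
})

test_that("cohort simulation writes valid artifacts and a truth table", {
  out <- withr::local_tempdir()
  cohort <- simulate_cohort(n_control = 2, n_patient = 2, n_time = 60,
                            n_nodes = 8, covariances = tiny_regimes(),
                            sites = site_model(offsets = c(-0.03, 0.03),
                                               scales = c(1, 1)),
                            seed = 31, out_dir = out)
  expect_length(cohort$timeseries, 4)
  expect_equal(sum(cohort$cohort$group == "control"), 2)
  expect_equal(sum(cohort$cohort$group == "patient"), 2)
  md <- read_metadata(file.path(out, "metadata.tsv"))
  expect_equal(nrow(md), 4)
  truth <- read_table(file.path(out, "truth_table.tsv"))
  expect_true(all(c("planted_transitions", "planted_occupancy_s1") %in%
                    colnames(truth)))
  occ_cols <- paste0("planted_occupancy_s", 1:3)
  expect_equal(rowSums(truth[, occ_cols]), rep(1, 4), tolerance = 1e-12)
  ts <- read_timeseries(file.path(out, paste0(md$subject_id[1], ".tsv")))
  expect_equal(dim(ts$data), c(60, 8))

  # determinism of the whole cohort
  cohort2 <- simulate_cohort(n_control = 2, n_patient = 2, n_time = 60,
                             n_nodes = 8, covariances = tiny_regimes(),
                             sites = site_model(offsets = c(-0.03, 0.03),
                                                scales = c(1, 1)),
                             seed = 31)
  expect_identical(cohort$timeseries[[1]]$data, cohort2$timeseries[[1]]$data)
  expect_identical(cohort$truth$planted_transitions,
                   cohort2$truth$planted_transitions)
})

test_that("site transforms plant offsets on the windowed z features", {
  cov <- tiny_regimes()
  sm <- site_model(offsets = c(-0.06, 0.06), scales = c(1, 1))
  # rebuild the site-specific matrices the cohort generator uses
  z <- atanh(cov[[1]] * (1 - 1e-12)); diag(z) <- 0
  lo <- tanh(z - 0.06); hi <- tanh(z + 0.06)
  mean_off <- function(m) mean(atanh(m[lower.tri(m)]))
  expect_equal(mean_off(hi) - mean_off(lo), 0.12, tolerance = 1e-6)
})

test_that("pure regime windows carry their planted structure", {
  cov <- tiny_regimes()
  sim <- simulate_regime_windows(cov, n_subjects = 4,
                                 windows_per_subject = 30,
                                 occupancy = c(0.2, 0.5, 0.3),
                                 window_length = 22, seed = 17)
  expect_equal(dim(sim$features), c(120, 28))
  expect_equal(length(sim$labels), 120)
  expect_true(all(is.finite(sim$features)))
  # hypoconnected regime has the lowest mean z
  mz <- tapply(rowMeans(sim$features), sim$labels, mean)
  expect_true(mz["2"] < mz["1"] && mz["1"] < mz["3"])
})
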