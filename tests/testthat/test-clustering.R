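test_that("strict local maxima with endpoint exclusion and fallback", {
  expect_equal(local_maxima(c(1, 3, 2, 5, 4)), c(2, 4))
  expect_equal(local_maxima(c(1, 2, 3, 4, 5)), 5)  # monotone: global argmax
  expect_equal(local_maxima(rep(2, 6)), 1)         # constant: first argmax
  expect_equal(local_maxima(c(5, 1, 1)), 1)        # endpoint max, no interior
})

test_that("exemplar selection needs 3 valid windows and uses edge variance", {
  edges <- rbind(c(0, 0, 0), c(1, 2, 3), c(0.1, 0.1, 0.1),
                 c(2, 4, 6), c(0, 1, 0))
  series <- make_series(edges, node_labels = c("a", "b", "c"))
  # per-window across-edge variance: 0, high, ~0, higher, mid -> maxima at 2, 4
  expect_equal(exemplar_windows(series), c(2, 4))

  series_small <- make_series(edges[1:2, ], node_labels = c("a", "b", "c"))
  expect_error(exemplar_windows(series_small), "degenerate series")
})

test_that("two-stage k-means recovers well-separated blobs exactly", {
  blobs <- make_blobs(n_per = 60, e = 10, sep = 10, seed = 14)
  model <- kmeans_two_stage(blobs$x, blobs$x, k = 3, replicates = 20,
                            seed = 3)
  m <- match_labels(blobs$labels, model$assignment, 3)
  expect_equal(m$agreement, 1.0)
  expect_equal(mclust::adjustedRandIndex(blobs$labels, model$assignment), 1.0)

  # independent oracle: Lloyd k-means from stats finds the same optimum
  km <- stats::kmeans(blobs$x, centers = 3, nstart = 20, iter.max = 100,
                      algorithm = "Lloyd")
  expect_equal(model$wcss, km$tot.withinss, tolerance = 1e-8)
})

test_that("k = 1 yields the grand mean and total sum of squares", {
  set.seed(4)
  x <- matrix(rnorm(200), 40, 5)
  model <- kmeans_two_stage(x, x, k = 1, replicates = 3, seed = 2)
  expect_equal(as.numeric(model$centroids), colMeans(x), tolerance = 1e-12)
  expect_equal(model$wcss, sum(sweep(x, 2, colMeans(x))^2), tolerance = 1e-9)
})

test_that("stage 2 never increases WCSS over applying stage-1 centroids", {
  set.seed(6)
  exemplars <- matrix(rnorm(40 * 6), 40, 6)
  all_w <- rbind(exemplars, matrix(rnorm(160 * 6), 160, 6))
  model <- kmeans_two_stage(exemplars, all_w, k = 4, replicates = 10,
                            seed = 7)
  stage1 <- kmeans_two_stage(exemplars, exemplars, k = 4, replicates = 10,
                             seed = 7)
  # WCSS of stage-1 centroids applied to all windows
  d <- as.matrix(dist(rbind(stage1$centroids, all_w)))[1:4, -(1:4)]
  wcss_applied <- sum(apply(d^2, 2, min))
  expect_lte(model$wcss, wcss_applied + 1e-9)
})

test_that("clustering is deterministic given the seed", {
  set.seed(10)
  x <- matrix(rnorm(300 * 8), 300, 8)
  m1 <- kmeans_two_stage(x, x, k = 3, replicates = 15, seed = 42)
  m2 <- kmeans_two_stage(x, x, k = 3, replicates = 15, seed = 42)
  expect_identical(m1$assignment, m2$assignment)
  expect_equal(m1$centroids, m2$centroids, tolerance = 1e-15)
})

test_that("infeasible k and empty-cluster reseeding are handled", {
  set.seed(1)
  x <- matrix(rnorm(20), 10, 2)
  expect_error(kmeans_two_stage(x[1:2, ], x, k = 3, replicates = 2, seed = 1),
               "infeasible")
  # force an empty cluster: one initial center far from all points
  centers <- rbind(x[1, ], x[2, ], c(100, 100))
  fit <- dfcstates:::.lloyd(x, centers, max_iter = 50)
  expect_setequal(unique(fit$assignment), 1:3)  # reseeded, not abandoned
})

test_that("nearest-centroid assignment breaks ties to the lowest state id", {
  centroids <- rbind(c(0, 0), c(5, 5), c(2, 0))  # state 1 and 3 equidistant
  model <- make_model(centroids)
  series <- make_series(rbind(c(1, 0), c(5, 5), c(2, 0)),
                        node_labels = c("a", "b"))
  seq <- assign_states(series, model)
  expect_equal(seq$labels, c(1L, 2L, 3L))  # (1,0) is midway between 1 and 3

  series_bad <- make_series(matrix(0, 3, 3), node_labels = c("a", "b", "c"))
  expect_error(assign_states(series_bad, model), "dimension mismatch")
})

test_that("invalid windows are omitted from the state sequence", {
  series <- make_series(rbind(c(0, 0), c(NA, NA), c(5, 5)),
                        node_labels = c("a", "b"),
                        valid = c(TRUE, FALSE, TRUE))
  model <- make_model(rbind(c(0, 0), c(5, 5)))
  seq <- assign_states(series, model)
  expect_equal(seq$window_index, c(1L, 3L))
  expect_equal(seq$labels, c(1L, 2L))
})

test_that("elbow curve is monotone and finds the blob count", {
  blobs <- make_blobs(n_per = 60, e = 8, sep = 12, seed = 20)
  el <- elbow_curve(blobs$x, k_range = 1:6, replicates = 10, seed = 4)
  expect_true(all(diff(el$curve$wcss) <= 1e-9))
  expect_equal(el$knee, 3)

  # k = number of distinct points drives WCSS to zero
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1), 4, 2, byrow = TRUE)
  x <- pts[rep(1:4, each = 5), ]
  el2 <- elbow_curve(x, k_range = 1:4, replicates = 10, seed = 2)
  expect_equal(el2$curve$wcss[4], 0, tolerance = 1e-12)
})

test_that("best-of-replicates WCSS is non-increasing in replicate count", {
  set.seed(31)
  x <- matrix(rnorm(120 * 5), 120, 5)
  w <- vapply(c(1, 3, 10, 25), function(r)
    kmeans_two_stage(x, x, k = 4, replicates = r, seed = 9)$stage1_wcss,
    numeric(1))
  expect_true(all(diff(w) <= 1e-9))
})

test_that("state relabeling maps ascending mean z to the reporting order", {
  centroids <- rbind(c(0.1, 0.1), c(0.5, 0.5), c(0.9, 0.9))
  model <- make_model(centroids)
  model$assignment <- c(1L, 2L, 3L, 1L)
  out <- relabel_states(model)
  # lowest-mean centroid becomes state 2 (hypoconnected), middle 1, top 3
  expect_equal(out$state_map, c(2L, 1L, 3L))
  expect_equal(out$assignment, c(2L, 1L, 3L, 2L))
  expect_equal(out$centroids[1, ], c(0.5, 0.5))  # new state 1 = moderate
  expect_equal(out$centroids[2, ], c(0.1, 0.1))  # new state 2 = hypo
  expect_equal(rowMeans(out$centroids)[c(2, 1, 3)],
               sort(rowMeans(out$centroids)))
})

test_that("label matching finds the planted permutation", {
  set.seed(3)
  a <- sample(1:3, 500, replace = TRUE)
  perm <- c(3L, 1L, 2L)
  b <- perm[a]
  m <- match_labels(a, b, 3)
  expect_equal(m$agreement, 1.0)
  expect_equal(m$map, perm)
})
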