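test_that("Welch t matches the reference implementation on raw samples", {
  set.seed(15)
  for (i in 1:50) {
    x <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    mine <- welch_t(x, y)
    ref <- t.test(x, y)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch t sign flips and p is invariant under group swap", {
  a <- welch_t_summary(10, 2, 30, 12, 3, 40)
  b <- welch_t_summary(12, 3, 40, 10, 2, 30)
  expect_equal(a$t, -b$t)
  expect_equal(a$p, b$p)
  expect_equal(a$df, b$df)

  same <- welch_t_summary(5, 1, 20, 5, 1, 20)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  expect_error(welch_t_summary(1, 0, 10, 2, 0, 10), "both group variances")
})

test_that("BH step-up agrees with a brute-force min-over-suffix oracle", {
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    q <- numeric(m)
    for (i in seq_len(m)) {
      q[i] <- min(1, min(ps[i:m] * m / (i:m)))
    }
    out <- numeric(m)
    out[o] <- q
    out
  }
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  set.seed(22)
  for (i in 1:200) {
    p <- runif(sample(1:12, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm])
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("Hedges g magnitude, zero case and degenerate case", {
  expect_equal(hedges_g_summary(5, 2, 30, 5, 3, 40), 0)
  g <- hedges_g_summary(10, 2, 30, 12, 3, 40)
  expect_gt(g, 0)
  # magnitude regardless of direction
  expect_equal(g, hedges_g_summary(12, 3, 40, 10, 2, 30))
  expect_error(hedges_g_summary(1, 0, 10, 2, 0, 10), "pooled SD")
  # correction factor shrinks the raw d
  d <- abs(10 - 12) / sqrt((29 * 4 + 39 * 9) / 68)
  expect_equal(hedges_g_summary(10, 2, 30, 12, 3, 40),
               d * (1 - 3 / (4 * 70 - 9)))
})

test_that("chi-square matches the hand formula with and without Yates", {
  chisq_oracle <- function(tab, yates) {
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    dev <- abs(tab - e)
    if (yates) dev <- pmax(dev - 0.5, 0)
    sum(dev^2 / e)
  }
  expect_equal(chisq_2x2(matrix(c(10, 0, 0, 10), 2), yates = FALSE)$chi2, 20)
  prop <- matrix(c(20, 40, 10, 20), 2)  # proportional: no association
  expect_equal(chisq_2x2(prop, yates = FALSE)$chi2, 0)
  set.seed(12)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    for (y in c(TRUE, FALSE)) {
      expect_equal(chisq_2x2(tab, yates = y)$chi2, chisq_oracle(tab, y),
                   tolerance = 1e-12)
    }
  }
  expect_error(chisq_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate margins")
})

test_that("GG repeated-measures ANOVA matches the mlm reference", {
  set.seed(33)
  n <- 60; k <- 4
  # correlated conditions with unequal variances (sphericity violated)
  subj <- rnorm(n, sd = 1.2)
  y <- sapply(1:k, function(j) subj + rnorm(n, sd = 0.4 * j)) +
    matrix(rnorm(n * k, sd = 0.3), n, k)
  y[, 2] <- y[, 2] + 0.5
  mine <- rm_anova_gg(y)
  mlm <- lm(y ~ 1)
  ref <- anova(mlm, X = ~1, idata = data.frame(cond = factor(1:k)),
               test = "Spherical")
  expect_equal(mine$F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$p, ref[1, "G-G Pr"], tolerance = 1e-8)
  # epsilon via the eigenvalue identity of the double-centered covariance
  s <- cov(y)
  cm <- diag(k) - 1 / k
  lambda <- eigen(cm %*% s %*% cm, symmetric = TRUE)$values
  lambda <- lambda[lambda > 1e-12]
  expect_equal(mine$epsilon, sum(lambda)^2 / ((k - 1) * sum(lambda^2)),
               tolerance = 1e-10)
})

test_that("GG epsilon is near 1 under compound symmetry and bounded always", {
  set.seed(44)
  n <- 400; k <- 3
  y <- matrix(rnorm(n), n, k) + matrix(rnorm(n * k, sd = 1), n, k)
  res <- rm_anova_gg(y)
  expect_gt(res$epsilon, 0.95)
  # F close to the classical within-subject ANOVA
  df_long <- data.frame(y = as.vector(y),
                        cond = factor(rep(1:k, each = n)),
                        subj = factor(rep(1:n, k)))
  av <- summary(aov(y ~ cond + Error(subj/cond), data = df_long))
  f_ref <- av[["Error: subj:cond"]][[1]]["cond", "F value"]
  expect_equal(res$F, f_ref, tolerance = 1e-8)

  for (i in 1:30) {
    k2 <- sample(3:5, 1)
    y2 <- matrix(rnorm(20 * k2), 20, k2) %*%
      matrix(rnorm(k2 * k2, sd = 0.7), k2)
    eps <- rm_anova_gg(y2)$epsilon
    expect_gte(eps, 1 / (k2 - 1) - 1e-10)
    expect_lte(eps, 1 + 1e-10)
  }

  # identical columns: no condition effect at all
  y3 <- matrix(rnorm(30), 30, 3)
  expect_equal(rm_anova_gg(y3)$F, 0)
})

test_that("paired post-hocs equal one-sample tests on differences", {
  set.seed(55)
  y <- cbind(rnorm(40), rnorm(40, 0.5), rnorm(40, 1))
  res <- paired_posthoc(y)
  expect_equal(nrow(res), 3)
  d <- y[, 1] - y[, 2]
  ref <- t.test(d)
  expect_equal(res$t[res$pair == "s1_vs_s2"], unname(ref$statistic))
  expect_equal(res$p[res$pair == "s1_vs_s2"], ref$p.value)
  expect_equal(res$q, bh_fdr(res$p))

  # identical columns give p = 1 for that pair
  y2 <- cbind(a = rnorm(20), b = rnorm(20))
  y2 <- cbind(y2, b2 = y2[, 2])
  res2 <- paired_posthoc(y2)
  expect_equal(res2$p[res2$pair == "s2_vs_s3"], 1)

  # a planted ordering mu2 < mu1 < mu3 is detected in every pair
  set.seed(56)
  n <- 500
  base <- rnorm(n, sd = 0.04)
  y3 <- cbind(base + rnorm(n, 0.198, 0.02), base + rnorm(n, 0.106, 0.02),
              base + rnorm(n, 0.288, 0.02))
  res3 <- paired_posthoc(y3)
  expect_true(all(res3$q < 0.001))
})

test_that("adjusted group effect reduces to the mean difference when
           covariates are balanced", {
  n <- 60
  covs <- data.frame(age = rnorm(n / 2, 35, 10),
                     sex = sample(c("M", "F"), n / 2, replace = TRUE),
                     mean_fd = runif(n / 2, 0.02, 0.15),
                     site = sample(c("A", "B"), n / 2, replace = TRUE))
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("control", "patient"), each = n / 2),
    rbind(covs, covs)))  # identical covariates in both groups
  set.seed(66)
  y <- rnorm(n) + 2 * (cohort$group == "patient")
  eff <- adjusted_group_effect(y, cohort)
  raw_diff <- mean(y[cohort$group == "patient"]) -
    mean(y[cohort$group == "control"])
  expect_equal(eff$beta, raw_diff, tolerance = 1e-10)
  expect_true(eff$ci[1] < eff$beta && eff$beta < eff$ci[2])
})

test_that("rank-deficient adjusted designs fail naming the collinear column", {
  n <- 40
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("control", "patient"), each = n / 2),
    site = "A", age = rnorm(n, 35, 10),
    sex = sample(c("M", "F"), n, replace = TRUE),
    mean_fd = NA))
  cohort$mean_fd <- cohort$age  # exact collinearity
  expect_error(adjusted_group_effect(rnorm(n), cohort),
               "collinear.*mean_fd")
})

test_that("adjusted model recovers a planted effect under site confounding", {
  set.seed(70)
  hits <- 0
  reps <- 120
  for (r in seq_len(reps)) {
    n <- 150
    site <- sample(c("A", "B", "C"), n, replace = TRUE,
                   prob = c(0.5, 0.3, 0.2))
    # patients over-represented at site C, which also shifts the metric
    p_pat <- c(A = 0.35, B = 0.5, C = 0.7)[site]
    group <- ifelse(runif(n) < p_pat, "patient", "control")
    site_eff <- c(A = 0, B = 1, C = 2.5)[site]
    age <- rnorm(n, 36, 12)
    y <- site_eff + 0.05 * age - 2.0 * (group == "patient") + rnorm(n, sd = 2)
    cohort <- as_cohort_table(data.frame(
      subject_id = sprintf("s%03d", 1:n), group = group, site = site,
      age = age, sex = sample(c("M", "F"), n, replace = TRUE),
      mean_fd = runif(n, 0.02, 0.15)))
    eff <- adjusted_group_effect(y, cohort)
    if (eff$ci[1] <= -2.0 && -2.0 <= eff$ci[2]) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.88)  # nominal 95% coverage
})

test_that("group battery builds the declared family with BH inside it", {
  set.seed(81)
  n <- 80
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("s%02d", 1:n),
    group = rep(c("control", "patient"), each = n / 2),
    site = sample(c("A", "B"), n, replace = TRUE),
    age = rnorm(n, 36, 10), sex = sample(c("M", "F"), n, replace = TRUE),
    mean_fd = runif(n, 0.02, 0.15)))
  metrics <- data.frame(subject_id = cohort$subject_id,
                        m1 = rnorm(n) + 1.2 * (cohort$group == "patient"),
                        m2 = rnorm(n))
  out <- group_battery(metrics, cohort, c("m1", "m2"))
  expect_equal(out$q, bh_fdr(out$p))
  expect_equal(out$n_control, c(40, 40))
  # sign convention: control minus patient
  expect_lt(out$t[1], 0)
  expect_true(out$significant[1])
  ref <- welch_t(metrics$m1[cohort$group == "control"],
                 metrics$m1[cohort$group == "patient"])
  expect_equal(out$t[1], ref$t)
})

test_that("stratified comparisons find effects only where planted and
           reduce to the primary analysis for a single stratum", {
  set.seed(90)
  n_c <- 60; n_p <- 60
  cohort <- as_cohort_table(data.frame(
    subject_id = sprintf("s%03d", 1:(n_c + n_p)),
    group = rep(c("control", "patient"), c(n_c, n_p)),
    site = sample(c("A", "B"), n_c + n_p, replace = TRUE),
    age = rnorm(n_c + n_p, 36, 10),
    sex = sample(c("M", "F"), n_c + n_p, replace = TRUE),
    mean_fd = runif(n_c + n_p, 0.02, 0.15),
    medication = c(rep(NA, n_c),
                   sample(c("medicated", "unmedicated", NA), n_p,
                          replace = TRUE, prob = c(0.4, 0.4, 0.2)))))
  eff <- ifelse(cohort$group == "patient" &
                  !is.na(cohort$medication) &
                  cohort$medication == "unmedicated", 1.5, 0)
  metrics <- data.frame(subject_id = cohort$subject_id,
                        m1 = rnorm(n_c + n_p, sd = 0.8) + eff)
  res <- stratified_compare(metrics, cohort, "medication", "m1")
  expect_setequal(unique(res$stratum), c("medicated", "unmedicated"))
  expect_true(res$q[res$stratum == "unmedicated"] < 0.05)
  expect_false(res$q[res$stratum == "medicated"] < 0.05)
  # patients with missing status are excluded from strata
  n_strat <- sum(res$n_patient)
  expect_equal(n_strat, sum(!is.na(cohort$medication)))

  # a single all-patient stratum reproduces the primary comparison
  cohort2 <- cohort
  cohort2$medication[cohort2$group == "patient"] <- "medicated"
  res2 <- stratified_compare(metrics, cohort2, "medication", "m1")
  prim <- group_battery(metrics, cohort2, "m1")
  expect_equal(res2$t, prim$t)
  expect_equal(res2$q, prim$q)
})

test_that("summary battery reproduces its own raw-data equivalents", {
  set.seed(95)
  x <- rnorm(50, 10, 2); y <- rnorm(60, 9, 3)
  summ <- data.frame(metric = "m", mean_hc = mean(x), sd_hc = sd(x),
                     n_hc = 50, mean_mdd = mean(y), sd_mdd = sd(y),
                     n_mdd = 60)
  out <- summary_battery(summ)
  ref <- t.test(x, y)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(out$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(out$g, hedges_g(x, y))
  expect_equal(out$q, out$p)  # single-member family
})
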