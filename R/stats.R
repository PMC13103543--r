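#' Welch two-sample t-test from group summaries
#'
#' The unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, computed directly from per-group mean, SD and n so that published
#' summary tables can be re-analyzed without raw data. Sign convention: first
#' group minus second group.
#'
#' @param mean_a,sd_a,n_a First group summary (n >= 2, sd >= 0).
#' @param mean_b,sd_b,n_b Second group summary.
#' @return List with `t`, `df` (non-integer), `p` (two-sided, from the t
#'   distribution at the Satterthwaite df).
#' @export
welch_t_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (va + vb == 0) stop("undefined statistic: both group variances are zero")
  t <- (mean_a - mean_b) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Welch t-test on raw samples
#'
#' @param x,y Numeric vectors (NAs dropped).
#' @return As [welch_t_summary()].
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  welch_t_summary(mean(x), stats::sd(x), length(x),
                  mean(y), stats::sd(y), length(y))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Adjusted q-values for one declared family of tests, via
#' `stats::p.adjust(method = "BH")` after validating the inputs.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Hedges g from group summaries
#'
#' Pooled-SD standardized mean difference with the small-sample bias
#' correction J = 1 - 3/(4N - 9); reported as a magnitude (direction is
#' carried by the sign of the t statistic).
#'
#' @inheritParams welch_t_summary
#' @return Non-negative effect size.
#' @export
hedges_g_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2)
  pooled <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2))
  if (pooled == 0) stop("undefined effect size: pooled SD is zero")
  d <- abs(mean_a - mean_b) / pooled
  d * (1 - 3 / (4 * (n_a + n_b) - 9))
}

#' Hedges g on raw samples
#' @inheritParams welch_t
#' @return Non-negative effect size.
#' @export
hedges_g <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  hedges_g_summary(mean(x), stats::sd(x), length(x),
                   mean(y), stats::sd(y), length(y))
}

#' Chi-square test for a 2 x 2 contingency table
#'
#' Pearson chi-square with optional Yates continuity correction (the default,
#' standard for 2 x 2 sex-by-group tables).
#'
#' @param counts 2 x 2 matrix of non-negative counts.
#' @param yates Apply the continuity correction.
#' @return List with `chi2`, `df` (= 1) and `p`.
#' @export
chisq_2x2 <- function(counts, yates = TRUE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("degenerate margins in contingency table")
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject ANOVA on a subjects x conditions matrix (subjects with any
#' missing condition are dropped listwise). Sphericity is not assumed: the
#' Greenhouse-Geisser epsilon is estimated from the sample covariance of the
#' conditions and shrinks both degrees of freedom before the p-value is taken
#' from the F distribution.
#'
#' @param values Numeric matrix, subjects x k conditions (k >= 2).
#' @return List with `F`, `df1`, `df2` (GG-corrected), `p`, `epsilon`,
#'   `n` (complete subjects), `k`.
#' @export
rm_anova_gg <- function(values) {
  values <- as.matrix(values)
  k <- ncol(values)
  if (k < 2) stop("need at least 2 within-subject conditions")
  values <- values[stats::complete.cases(values), , drop = FALSE]
  n <- nrow(values)
  if (n < 3) stop("need at least 3 complete subjects")
  grand <- mean(values)
  col_m <- colMeans(values)
  row_m <- rowMeans(values)
  ss_cond <- n * sum((col_m - grand)^2)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  f_stat <- if (ss_cond == 0) 0
            else (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  s <- stats::cov(values)
  cm <- diag(k) - matrix(1 / k, k, k)
  dc <- cm %*% s %*% cm
  eps <- if (sum(dc^2) < .Machine$double.xmin) 1
         else sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
  df1 <- eps * (k - 1)
  df2 <- eps * (k - 1) * (n - 1)
  list(F = f_stat, df1 = df1, df2 = df2,
       p = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
       epsilon = eps, n = n, k = k)
}

#' Paired post-hoc t-tests over all condition pairs
#'
#' All k(k-1)/2 two-sided paired t-tests on pairwise-complete subjects,
#' BH-FDR corrected as one family.
#'
#' @param values Numeric matrix, subjects x k conditions.
#' @param names Optional condition names (defaults to `s1..sk`).
#' @return data.frame: `pair`, `n`, `mean_diff`, `t`, `df`, `p`, `q`.
#' @export
paired_posthoc <- function(values, names = NULL) {
  values <- as.matrix(values)
  k <- ncol(values)
  stopifnot(k >= 2)
  if (is.null(names)) names <- paste0("s", seq_len(k))
  rows <- list()
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      ok <- stats::complete.cases(values[, c(a, b)])
      if (sum(ok) < 2) stop("fewer than 2 complete pairs for ",
                            names[a], " vs ", names[b])
      d <- values[ok, a] - values[ok, b]
      if (stats::sd(d) == 0) {
        tt <- list(statistic = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                   parameter = sum(ok) - 1,
                   p.value = if (mean(d) == 0) 1 else 0)
      } else {
        tt <- stats::t.test(values[ok, a], values[ok, b], paired = TRUE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        pair = paste0(names[a], "_vs_", names[b]), n = sum(ok),
        mean_diff = mean(d), t = unname(tt$statistic),
        df = unname(tt$parameter), p = tt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out
}

#' Covariate-adjusted group effect for one metric
#'
#' Ordinary least squares of the metric on the group indicator plus age, sex,
#' mean framewise displacement and site dummies (reference = largest site).
#' The group coefficient is patient minus control.
#'
#' @param values Numeric vector, one entry per cohort row.
#' @param cohort A `cohort_table` aligned to `values`.
#' @return List with `beta`, `ci` (length-2), `se`, `p`, `n`.
#' @export
adjusted_group_effect <- function(values, cohort) {
  df <- data.frame(y = values,
                   group = cohort$group,
                   age = cohort$age,
                   sex = factor(cohort$sex, levels = .sex_levels),
                   mean_fd = cohort$mean_fd,
                   site = factor(cohort$site))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  site_n <- table(df$site)
  df$site <- stats::relevel(droplevels(df$site),
                            ref = names(which.max(site_n)))
  if (any(table(droplevels(df$site)) < 2)) {
    stop("every included site needs at least 2 subjects")
  }
  terms <- c("group", "age", "sex", "mean_fd",
             if (nlevels(df$site) > 1) "site")
  form <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  mm <- stats::model.matrix(form, df)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    drop_cols <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  fit <- stats::lm(form, df)
  co <- summary(fit)$coefficients
  row <- grep("^grouppatient$", rownames(co))
  ci <- stats::confint(fit, "grouppatient", level = 0.95)
  list(beta = co[row, "Estimate"], ci = as.numeric(ci),
       se = co[row, "Std. Error"], p = co[row, "Pr(>|t|)"], n = nrow(df))
}

#' Case-control battery over a family of temporal metrics
#'
#' For each metric column: group summaries (control first), Welch t with
#' Satterthwaite df, Hedges g, then BH-FDR across the family. Optionally the
#' covariate-adjusted linear-model effect per metric with its own BH family.
#'
#' @param metrics data.frame with `subject_id` and metric columns.
#' @param cohort A `cohort_table`.
#' @param columns Character vector naming the metric columns forming one FDR
#'   family.
#' @param adjusted Also fit [adjusted_group_effect()] per metric.
#' @return data.frame, one row per metric: group summaries, `t`, `df`, `p`,
#'   `q`, `g`, `significant`, and (if `adjusted`) `beta`, `ci_low`, `ci_high`,
#'   `p_adjusted_model`, `q_adjusted_model`.
#' @export
group_battery <- function(metrics, cohort, columns, adjusted = FALSE) {
  merged <- merge(metrics, as.data.frame(cohort), by = "subject_id",
                  sort = FALSE)
  rows <- lapply(columns, function(col) {
    v <- merged[[col]]
    a <- v[merged$group == "control"]
    b <- v[merged$group == "patient"]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    wt <- tryCatch(
      welch_t_summary(mean(a), stats::sd(a), length(a),
                      mean(b), stats::sd(b), length(b)),
      error = function(e) list(t = NA_real_, df = NA_real_, p = NA_real_))
    g <- tryCatch(
      hedges_g_summary(mean(a), stats::sd(a), length(a),
                       mean(b), stats::sd(b), length(b)),
      error = function(e) NA_real_)
    data.frame(metric = col,
               n_control = length(a), mean_control = mean(a),
               sd_control = stats::sd(a),
               n_patient = length(b), mean_patient = mean(b),
               sd_patient = stats::sd(b),
               t = wt$t, df = wt$df, p = wt$p, g = g)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < 0.05
  if (adjusted) {
    adj <- lapply(columns, function(col) {
      eff <- tryCatch(adjusted_group_effect(merged[[col]], merged),
                      error = function(e) list(beta = NA_real_,
                                               ci = c(NA_real_, NA_real_),
                                               p = NA_real_))
      data.frame(beta = eff$beta, ci_low = eff$ci[1], ci_high = eff$ci[2],
                 p_adjusted_model = eff$p)
    })
    out <- cbind(out, do.call(rbind, adj))
    out$q_adjusted_model <- bh_fdr(out$p_adjusted_model)
  }
  out
}

#' Stratified subgroup comparisons
#'
#' Splits patients by a clinical stratum (e.g. medication or episode status)
#' and compares each stratum against the full control group, unadjusted
#' (Welch t + Hedges g) and optionally covariate-adjusted, with BH-FDR applied
#' across metrics within each stratified family. Patients with a missing
#' stratum label are excluded from the stratified runs only.
#'
#' @param metrics data.frame with `subject_id` and metric columns.
#' @param cohort A `cohort_table` containing the stratum column.
#' @param stratum_col Name of the stratum column (e.g. `"medication"`).
#' @param columns Metric columns forming each family.
#' @param adjusted Also fit adjusted models.
#' @return data.frame stacking one [group_battery()] result per stratum with a
#'   leading `stratum` column; empty strata are skipped with a warning.
#' @export
stratified_compare <- function(metrics, cohort, stratum_col, columns,
                               adjusted = FALSE) {
  stopifnot(stratum_col %in% colnames(cohort))
  levels_present <- sort(unique(stats::na.omit(
    cohort[[stratum_col]][cohort$group == "patient"])))
  out <- list()
  for (lev in levels_present) {
    keep <- cohort$group == "control" |
      (cohort$group == "patient" & !is.na(cohort[[stratum_col]]) &
         cohort[[stratum_col]] == lev)
    sub_cohort <- cohort[keep, , drop = FALSE]
    if (sum(sub_cohort$group == "patient") == 0) {
      warning("empty stratum: ", lev)
      next
    }
    res <- group_battery(metrics, sub_cohort, columns, adjusted = adjusted)
    res <- cbind(stratum = lev, res)
    out[[lev]] <- res
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Recompute the inferential battery from a published summary table
#'
#' Takes a table of per-group summaries (as produced by
#' [reference_summaries()]) and recomputes Welch t, Satterthwaite df,
#' two-sided p, Hedges g, and BH-FDR q treating the rows as one family.
#'
#' @param summaries data.frame with columns `mean_hc`, `sd_hc`, `n_hc`,
#'   `mean_mdd`, `sd_mdd`, `n_mdd` and a leading identifier column.
#' @return The input with `t`, `df`, `p`, `g`, `q` columns appended
#'   (control-minus-patient sign convention).
#' @export
summary_battery <- function(summaries) {
  res <- lapply(seq_len(nrow(summaries)), function(i) {
    r <- summaries[i, ]
    wt <- welch_t_summary(r$mean_hc, r$sd_hc, r$n_hc,
                          r$mean_mdd, r$sd_mdd, r$n_mdd)
    g <- hedges_g_summary(r$mean_hc, r$sd_hc, r$n_hc,
                          r$mean_mdd, r$sd_mdd, r$n_mdd)
    data.frame(t = wt$t, df = wt$df, p = wt$p, g = g)
  })
  out <- cbind(summaries, do.call(rbind, res))
  out$q <- bh_fdr(out$p)
  out
}
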