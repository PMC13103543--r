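#' Empirical-Bayes multisite harmonization of connectivity features
#'
#' Removes additive and multiplicative site (batch) effects from a feature
#' matrix while preserving the effects of biological covariates (age, sex),
#' using the parametric empirical-Bayes location/scale model popularized for
#' multi-batch genomics and multisite imaging (ComBat). The EB core is
#' delegated to \code{sva::ComBat}; this wrapper fixes the observation
#' orientation (rows = observations, columns = features), builds the covariate
#' design (age standardized to zero mean / unit variance, sex coded 0/1), and
#' adds the degenerate-input contract: a single batch returns the input
#' unchanged with a warning, and features with (near-)zero variance inside
#' some batch are adjusted location-only.
#'
#' @param features Numeric matrix, observations x features. When harmonizing
#'   windowed connectivity, each windowed edge vector is one observation
#'   carrying its subject's site label.
#' @param batch Site label per observation (character or factor).
#' @param covariates Optional data.frame aligned to observations with columns
#'   `age` (numeric) and `sex` (`"M"`/`"F"` or 0/1); effects of these columns
#'   are preserved, not removed.
#' @param parametric Use parametric EB priors (the only implemented variant;
#'   kept as an argument for interface stability).
#' @return List with `adjusted` (same shape and ordering as `features`) and
#'   `batch_report` (data.frame per site: observation count, mean location
#'   shift removed, mean scale ratio applied).
#' @export
combat_adjust <- function(features, batch, covariates = NULL,
                          parametric = TRUE) {
  features <- as.matrix(features)
  stopifnot(is.numeric(features), all(is.finite(features)),
            length(batch) == nrow(features))
  if (!parametric) stop("only the parametric EB variant is implemented")
  batch <- factor(as.character(batch))
  if (nlevels(batch) < 2) {
    warning("single batch: returning features unchanged")
    return(list(adjusted = features,
                batch_report = data.frame(site = levels(batch),
                                          n = length(batch),
                                          location_shift = 0,
                                          scale_ratio = 1)))
  }
  if (any(table(batch) < 2)) {
    stop("every batch needs at least 2 observations")
  }
  mod <- .covariate_design(covariates, nrow(features))

  # Features whose within-batch variance (nearly) vanishes break the EB scale
  # model; adjust those location-only.
  batch_var_min <- apply(features, 2, function(v)
    min(tapply(v, batch, stats::var)))
  degenerate <- batch_var_min < 1e-12
  adjusted <- features
  run_combat <- function(cols, mean_only) {
    dat <- t(features[, cols, drop = FALSE])
    out <- sva::ComBat(dat = dat, batch = batch, mod = mod,
                       par.prior = TRUE, mean.only = mean_only,
                       prior.plots = FALSE)
    t(out)
  }
  if (any(!degenerate)) {
    adjusted[, !degenerate] <- run_combat(which(!degenerate), FALSE)
  }
  if (any(degenerate)) {
    message(sum(degenerate),
            " feature(s) with zero within-batch variance: location-only adjustment")
    nb <- as.vector(table(batch))
    bd <- stats::model.matrix(~ 0 + batch)
    x_design <- if (is.null(mod)) bd else cbind(bd, mod[, -1, drop = FALSE])
    for (j in which(degenerate)) {
      fit <- stats::lm.fit(x_design, features[, j])
      gamma <- fit$coefficients[seq_len(nlevels(batch))]
      gamma[is.na(gamma)] <- 0
      grand <- sum(gamma * nb) / length(batch)
      adjusted[, j] <- features[, j] - (gamma[as.integer(batch)] - grand)
    }
  }
  report <- do.call(rbind, lapply(levels(batch), function(s) {
    rows <- batch == s
    pre <- features[rows, , drop = FALSE]
    post <- adjusted[rows, , drop = FALSE]
    pre_sd <- apply(pre, 2, stats::sd)
    post_sd <- apply(post, 2, stats::sd)
    ok <- pre_sd > 1e-12
    data.frame(site = s, n = sum(rows),
               location_shift = mean(colMeans(pre) - colMeans(post)),
               scale_ratio = if (any(ok)) mean(post_sd[ok] / pre_sd[ok]) else 1)
  }))
  list(adjusted = adjusted, batch_report = report)
}

.covariate_design <- function(covariates, n_obs) {
  if (is.null(covariates)) return(NULL)
  stopifnot(nrow(covariates) == n_obs)
  cols <- list()
  if ("age" %in% colnames(covariates)) {
    age <- as.numeric(covariates$age)
    stopifnot(all(is.finite(age)))
    cols$age <- if (stats::sd(age) > 0) as.numeric(scale(age)) else NULL
  }
  if ("sex" %in% colnames(covariates)) {
    sex <- covariates$sex
    if (!is.numeric(sex)) sex <- as.integer(sex == "M")
    if (length(unique(sex)) > 1) cols$sex <- sex
  }
  cols <- Filter(Negate(is.null), cols)
  if (length(cols) == 0) return(NULL)
  mm <- stats::model.matrix(~ ., data = as.data.frame(cols))
  if (qr(mm)$rank < ncol(mm)) stop("covariate design is rank deficient")
  mm
}

#' Per-feature one-way site F statistics
#'
#' The diagnostic used to quantify residual site effects: for each feature, a
#' one-way ANOVA F statistic of the feature on the site factor (covariates can
#' first be residualized out). Harmonization should shrink these toward 1.
#'
#' @param features Observations x features matrix.
#' @param batch Site label per observation.
#' @param covariates Optional data.frame (`age`, `sex`) residualized out of
#'   every feature before the ANOVA.
#' @return Numeric vector of F statistics, one per feature.
#' @export
site_f_statistics <- function(features, batch, covariates = NULL) {
  features <- as.matrix(features)
  batch <- factor(as.character(batch))
  if (!is.null(covariates)) {
    mm <- .covariate_design(covariates, nrow(features))
    if (!is.null(mm)) {
      features <- stats::lm.fit(mm, features)$residuals
    }
  }
  n <- nrow(features)
  g <- nlevels(batch)
  grand <- colMeans(features)
  ss_tot <- colSums(sweep(features, 2, grand)^2)
  group_means <- rowsum(features, batch) / as.vector(table(batch))
  ss_between <- colSums(sweep(group_means, 2, grand)^2 *
                          as.vector(table(batch)))
  ss_within <- ss_tot - ss_between
  (ss_between / (g - 1)) / (ss_within / (n - g))
}
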