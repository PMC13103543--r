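#' Run the full dFC state pipeline on in-memory data
#'
#' Executes windowed connectivity -> (optional) multisite harmonization ->
#' exemplar-seeded two-stage k-means -> state relabeling to the reporting
#' convention -> per-subject temporal metrics -> the group statistical
#' battery, and (when `output_dir` is given) writes every tabular artifact.
#'
#' @param ts_list List of `subject_timeseries`.
#' @param cohort A `cohort_table` with one row per series.
#' @param cfg A [dfc_config()].
#' @param output_dir Optional directory for the TSV artifacts.
#' @param compute_elbow Trace the elbow curve (always done when
#'   `cfg$k == "auto"`).
#' @return List of class `dfc_run`: `model` (relabeled `state_model`),
#'   `series` (harmonized `dfc_window_series` per subject), `sequences`
#'   (`state_sequence` per subject), `metrics` (per-subject data.frame),
#'   `stats` (list of result tables), `elbow`, `batch_report`, `manifest`.
#' @export
run_pipeline_data <- function(ts_list, cohort, cfg = dfc_config(),
                              output_dir = NULL, compute_elbow = TRUE) {
  t_start <- proc.time()[["elapsed"]]
  stopifnot(length(ts_list) >= 1, nrow(cohort) == length(ts_list))
  ids <- vapply(ts_list, `[[`, character(1), "subject_id")
  if (!setequal(ids, cohort$subject_id)) {
    stop("metadata and time series subject ids do not match")
  }
  cohort <- cohort[match(ids, cohort$subject_id), , drop = FALSE]

  timings <- c()
  tick <- function(name) {
    now <- proc.time()[["elapsed"]]
    timings[[name]] <<- round(now - t_start, 2)
    t_start <<- now
  }

  # --- windowed connectivity ------------------------------------------------
  series <- lapply(ts_list, build_dfc_series, cfg = cfg)
  n_valid <- vapply(series, function(s) length(valid_windows(s)), integer(1))
  usable <- n_valid >= 3
  dropped <- ids[!usable]
  if (length(dropped) > 0) {
    message("dropping ", length(dropped),
            " subject(s) with < 3 valid windows: ",
            paste(dropped, collapse = ", "))
    series <- series[usable]
    cohort <- cohort[usable, , drop = FALSE]
    ids <- ids[usable]
  }
  if (length(series) == 0) stop("no usable subjects after window QC")
  pooled <- do.call(rbind, lapply(series, function(s)
    s$edges[valid_windows(s), , drop = FALSE]))
  subj_of_row <- rep(seq_along(series),
                     vapply(series, function(s) length(valid_windows(s)),
                            integer(1)))
  tick("dfc")

  # --- harmonization --------------------------------------------------------
  batch_report <- NULL
  if (cfg$harmonize != "none" && length(unique(cohort$site)) > 1) {
    covars <- data.frame(age = cohort$age, sex = cohort$sex)
    if (cfg$harmonize == "window") {
      adj <- combat_adjust(pooled, batch = cohort$site[subj_of_row],
                           covariates = covars[subj_of_row, , drop = FALSE])
      pooled <- adj$adjusted
    } else {
      subj_means <- rowsum(pooled, subj_of_row) /
        as.vector(table(subj_of_row))
      adj <- combat_adjust(subj_means, batch = cohort$site,
                           covariates = covars)
      pooled <- pooled + (adj$adjusted - subj_means)[subj_of_row, ,
                                                     drop = FALSE]
    }
    batch_report <- adj$batch_report
  } else if (cfg$harmonize != "none") {
    message("single site: harmonization skipped")
  }
  for (i in seq_along(series)) {
    series[[i]]$edges[valid_windows(series[[i]]), ] <-
      pooled[subj_of_row == i, , drop = FALSE]
  }
  tick("harmonize")

  # --- exemplars and clustering --------------------------------------------
  exemplar_rows <- unlist(lapply(seq_along(series), function(i) {
    pos <- exemplar_windows(series[[i]], cfg$exemplar_variance)
    which(subj_of_row == i)[pos]
  }))
  exemplars <- pooled[exemplar_rows, , drop = FALSE]
  elbow <- NULL
  if (compute_elbow || identical(cfg$k, "auto")) {
    elbow <- elbow_curve(exemplars, cfg$k_range, cfg$elbow_replicates,
                         cfg$max_iter, cfg$seed)
  }
  k <- if (identical(cfg$k, "auto")) elbow$knee else as.integer(cfg$k)
  model <- kmeans_two_stage(exemplars, pooled, k, cfg$replicates,
                            cfg$max_iter, cfg$seed)
  model <- relabel_states(model)
  tick("cluster")

  # --- state sequences and temporal metrics ---------------------------------
  sequences <- lapply(seq_along(series), function(i) {
    vw <- valid_windows(series[[i]])
    structure(list(subject_id = series[[i]]$subject_id,
                   window_index = series[[i]]$windows$index[vw],
                   labels = model$assignment[subj_of_row == i]),
              class = "state_sequence")
  })
  metrics <- do.call(rbind, lapply(seq_along(series), function(i) {
    temporal_metrics(series[[i]], sequences[[i]], k, cfg$node_subsets)
  }))
  tick("metrics")

  # --- statistics -----------------------------------------------------------
  two_groups <- length(unique(cohort$group)) == 2
  temporal_cols <- c("transitions",
                     paste0("occupancy_s", seq_len(k)),
                     paste0("dwell_s", seq_len(k)))
  pair_cols <- as.vector(t(outer(seq_len(k), seq_len(k), function(a, b)
    paste0("t_", a, "to", b))))
  pair_cols <- intersect(pair_cols, colnames(metrics))
  fc_cols <- paste0("fc_s", seq_len(k))
  stats_out <- list()
  if (two_groups) {
    multi_site <- length(unique(cohort$site)) > 1 ||
      nlevels(factor(cohort$site)) > 1
    stats_out$temporal <- group_battery(metrics, cohort, temporal_cols,
                                        adjusted = TRUE)
    stats_out$transitions <- group_battery(metrics, cohort, pair_cols)
    for (strat in intersect(c("medication", "episode"), colnames(cohort))) {
      if (any(!is.na(cohort[[strat]]))) {
        stats_out[[paste0("stratified_", strat)]] <-
          stratified_compare(metrics, cohort, strat, temporal_cols,
                             adjusted = TRUE)
      }
    }
  }
  fc_mat <- as.matrix(metrics[, fc_cols, drop = FALSE])
  stats_out$state_fc_anova <- tryCatch(
    as.data.frame(rm_anova_gg(fc_mat)),
    error = function(e) {
      message("state FC ANOVA not computed: ", conditionMessage(e))
      data.frame(F = NA_real_, df1 = NA_real_, df2 = NA_real_, p = NA_real_,
                 epsilon = NA_real_, n = sum(stats::complete.cases(fc_mat)),
                 k = k)
    })
  stats_out$state_fc_posthoc <- tryCatch(
    paired_posthoc(fc_mat, names = fc_cols),
    error = function(e) {
      message("state FC post-hocs not computed: ", conditionMessage(e))
      NULL
    })
  tick("stats")

  manifest <- list(
    n_subjects = length(series),
    n_control = sum(cohort$group == "control"),
    n_patient = sum(cohort$group == "patient"),
    n_sites = length(unique(cohort$site)),
    k = k, seed = cfg$seed, replicates = cfg$replicates,
    harmonize = if (!is.null(batch_report)) cfg$harmonize else "none",
    window_length_tr = cfg$window_length_tr, step_tr = cfg$step_tr,
    windows_per_subject = paste(range(n_valid[usable]), collapse = "-"),
    invalid_windows = sum(vapply(series, function(s)
      sum(!s$windows$valid), integer(1))),
    dropped_subjects = paste(dropped, collapse = ","),
    stage1_exemplars = model$stage1_exemplar_count,
    wcss = model$wcss,
    timings_s = paste(names(timings), unlist(timings), sep = "=",
                      collapse = ";"))

  run <- structure(list(model = model, series = series,
                        sequences = sequences, metrics = metrics,
                        cohort = cohort, stats = stats_out, elbow = elbow,
                        batch_report = batch_report, manifest = manifest,
                        config = cfg),
                   class = "dfc_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

#' Run the pipeline from an input directory
#'
#' Expects `metadata.tsv` plus one `<subject_id>.tsv` time-series file per
#' metadata row (the layout written by [simulate_cohort()]).
#'
#' @param input_dir Directory of inputs.
#' @param output_dir Directory for artifacts.
#' @param cfg A [dfc_config()].
#' @param expected_nodes Optional node-count contract for the readers.
#' @return A `dfc_run` (see [run_pipeline_data()]).
#' @export
run_pipeline <- function(input_dir, output_dir, cfg = dfc_config(),
                         expected_nodes = NULL) {
  cohort <- read_metadata(file.path(input_dir, "metadata.tsv"))
  ts_list <- lapply(cohort$subject_id, function(id) {
    read_timeseries(file.path(input_dir, paste0(id, ".tsv")),
                    expected_nodes = expected_nodes, subject_id = id)
  })
  run <- run_pipeline_data(ts_list, cohort, cfg, output_dir = output_dir)
  run$manifest$input_md5 <- paste(
    substr(tools::md5sum(file.path(input_dir, "metadata.tsv")), 1, 8),
    collapse = ",")
  if (!is.null(output_dir)) .write_manifest(run$manifest, output_dir)
  run
}

#' Write all artifacts of a pipeline run
#'
#' @param run A `dfc_run`.
#' @param output_dir Target directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_config(run$config, file.path(output_dir, "config.tsv"))
  k <- run$model$k
  cent <- as.data.frame(run$model$centroids, check.names = FALSE)
  cent <- cbind(data.frame(state = seq_len(k)), cent)
  write_table(cent, file.path(output_dir, "centroids_edges.tsv"))
  labels <- run$series[[1]]$node_labels
  n <- length(labels)
  for (s in seq_len(k)) {
    m <- edge_to_matrix(run$model$centroids[s, ], n, labels)
    write_table(as.data.frame(m, check.names = FALSE),
                file.path(output_dir, sprintf("centroid_state%d_matrix.tsv", s)))
  }
  seq_df <- do.call(rbind, lapply(run$sequences, function(sq)
    data.frame(subject_id = sq$subject_id, window_index = sq$window_index,
               state = sq$labels)))
  write_table(seq_df, file.path(output_dir, "state_sequences.tsv"))
  write_table(run$metrics, file.path(output_dir, "metrics.tsv"))
  if (!is.null(run$elbow)) {
    write_table(run$elbow$curve, file.path(output_dir, "elbow.tsv"))
  }
  if (!is.null(run$batch_report)) {
    write_table(run$batch_report, file.path(output_dir, "batch_report.tsv"))
  }
  for (nm in names(run$stats)) {
    if (!is.null(run$stats[[nm]])) {
      write_table(run$stats[[nm]],
                  file.path(output_dir, paste0("stats_", nm, ".tsv")))
    }
  }
  .write_manifest(run$manifest, output_dir)
  invisible(output_dir)
}

.write_manifest <- function(manifest, output_dir) {
  writeLines(paste(names(manifest),
                   vapply(manifest, function(v) paste(as.character(v),
                                                      collapse = ","),
                          character(1)), sep = "\t"),
             file.path(output_dir, "manifest.tsv"))
}

#' Render a human-readable report from a run's artifacts
#'
#' Reads only the written TSVs (no recomputation of statistics) and renders
#' the group-comparison tables, the transition table, per-group
#' state-engagement counts, the elbow curve, and centroid heatmaps.
#'
#' @param output_dir Directory containing the artifacts of a completed run.
#' @param plots Also write `report.pdf` with centroid heatmaps and the elbow
#'   curve.
#' @return Character vector of report lines (also written to `report.txt`),
#'   invisibly.
#' @export
make_report <- function(output_dir, plots = TRUE) {
  need <- function(name) {
    path <- file.path(output_dir, name)
    if (!file.exists(path)) stop("missing artifact: ", name)
    path
  }
  manifest <- utils::read.delim(need("manifest.tsv"), header = FALSE,
                                sep = "\t", col.names = c("key", "value"),
                                colClasses = "character")
  metrics <- read_table(need("metrics.tsv"))
  centroids <- read_table(need("centroids_edges.tsv"))
  k <- nrow(centroids)
  lines <- c("dFC state pipeline report",
             strrep("=", 60),
             paste0(manifest$key, ": ", manifest$value), "")
  harmonize <- manifest$value[manifest$key == "harmonize"]
  if (identical(harmonize, "none")) {
    lines <- c(lines, "NOTE: features are UNHARMONIZED (no site adjustment).",
               "")
  }
  fmt_table <- function(df, digits = 3) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(v) signif(v, digits))
    c(paste(colnames(df), collapse = "\t"),
      apply(df, 1, paste, collapse = "\t"))
  }
  for (nm in c("temporal", "transitions")) {
    path <- file.path(output_dir, paste0("stats_", nm, ".tsv"))
    if (file.exists(path)) {
      lines <- c(lines, paste0("Group comparisons: ", nm),
                 fmt_table(read_table(path)), "")
    }
  }
  for (nm in c("state_fc_anova", "state_fc_posthoc")) {
    path <- file.path(output_dir, paste0("stats_", nm, ".tsv"))
    if (file.exists(path)) {
      lines <- c(lines, paste0("Within-subject state FC: ", nm),
                 fmt_table(read_table(path)), "")
    }
  }
  # engagement: subjects occupying each state at least once, per group
  seq_path <- file.path(output_dir, "metrics.tsv")
  meta_path <- file.path(output_dir, "stats_temporal.tsv")
  occ_cols <- grep("^occupancy_s", colnames(metrics), value = TRUE)
  engagement <- vapply(occ_cols, function(col) sum(metrics[[col]] > 0),
                       integer(1))
  lines <- c(lines, "State engagement (subjects occupying state >= once):",
             paste0("  ", occ_cols, ": ", engagement), "")
  elbow_path <- file.path(output_dir, "elbow.tsv")
  if (file.exists(elbow_path)) {
    elbow <- read_table(elbow_path)
    lines <- c(lines, "Elbow curve (k, WCSS):",
               paste0("  k=", elbow$k, "  wcss=", signif(elbow$wcss, 6)), "")
  }
  writeLines(lines, file.path(output_dir, "report.txt"))
  if (plots) {
    grDevices::pdf(file.path(output_dir, "report.pdf"), width = 7, height = 7)
    on.exit(grDevices::dev.off(), add = TRUE)
    n_nodes <- (1 + sqrt(1 + 8 * (ncol(centroids) - 1))) / 2
    for (s in seq_len(k)) {
      m <- edge_to_matrix(as.numeric(centroids[s, -1]), n_nodes)
      graphics::image(m[, rev(seq_len(n_nodes))], axes = FALSE,
                      main = paste("State", centroids$state[s], "centroid"),
                      col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                      zlim = c(-max(abs(m)), max(abs(m))))
    }
    if (file.exists(elbow_path)) {
      elbow <- read_table(elbow_path)
      graphics::plot(elbow$k, elbow$wcss, type = "b", xlab = "k",
                     ylab = "WCSS", main = "Elbow curve")
    }
  }
  invisible(lines)
}
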