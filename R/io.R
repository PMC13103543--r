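#' Pipeline configuration
#'
#' Builds the configuration list consumed by [run_pipeline()] and the individual
#' stage functions. Defaults follow the common large-cohort sliding-window dFC
#' setup: 22-TR windows advanced 1 TR at a time, k = 3 states fit with 500
#' replicate initializations and up to 500 Lloyd iterations, boundary epsilon
#' 1e-7 before the Fisher r-to-z transform, and FDR alpha 0.05.
#'
#' @param window_length_tr Window length in TRs (>= 2).
#' @param step_tr Window step in TRs (>= 1).
#' @param k Number of connectivity states, or `"auto"` to take the elbow
#'   suggestion from [elbow_curve()].
#' @param k_range Integer vector of k values scanned when building the elbow
#'   curve.
#' @param replicates Random initializations for stage-1 k-means.
#' @param elbow_replicates Random initializations per k when tracing the elbow
#'   curve (the curve is additionally warm-started from the previous k, which
#'   keeps it monotone at much lower replicate counts than the final fit).
#' @param max_iter Maximum Lloyd iterations per k-means run.
#' @param seed Master seed for all stochastic stages.
#' @param fisher_epsilon Clamp half-width applied to correlations at the +-1
#'   boundary before `atanh` (in (0, 1e-3]).
#' @param fdr_alpha Benjamini-Hochberg significance level.
#' @param node_subsets Named list of character vectors of node labels used for
#'   state-conditioned mean-connectivity summaries (e.g. a within-network set).
#' @param harmonize One of `"window"` (each windowed edge vector is one ComBat
#'   observation carrying its subject's site), `"subject"` (subject-mean
#'   vectors are harmonized and window-level features receive their subject's
#'   adjustment), or `"none"`.
#' @param exemplar_variance `"across_edges"` (the variance over the E edge
#'   values within each window; default) or `"over_time"` (per-edge temporal
#'   variance in a centered rolling sense, summed over edges) -- two readings
#'   of "temporal variance of connectivity across ROI pairs".
#'
#' @return A list of class `"dfc_config"`.
#' @export
dfc_config <- function(window_length_tr = 22L, step_tr = 1L, k = 3L,
                       k_range = 1:6, replicates = 500L,
                       elbow_replicates = 50L, max_iter = 500L, seed = 1L,
                       fisher_epsilon = 1e-7, fdr_alpha = 0.05,
                       node_subsets = list(), harmonize = "window",
                       exemplar_variance = "across_edges") {
  stopifnot(window_length_tr >= 2, step_tr >= 1, replicates >= 1,
            max_iter >= 1, fisher_epsilon > 0, fisher_epsilon <= 1e-3,
            fdr_alpha > 0, fdr_alpha < 1)
  if (!identical(k, "auto")) stopifnot(k >= 1)
  harmonize <- match.arg(harmonize, c("window", "subject", "none"))
  exemplar_variance <- match.arg(exemplar_variance,
                                 c("across_edges", "over_time"))
  structure(list(window_length_tr = as.integer(window_length_tr),
                 step_tr = as.integer(step_tr), k = k,
                 k_range = as.integer(k_range),
                 replicates = as.integer(replicates),
                 elbow_replicates = as.integer(elbow_replicates),
                 max_iter = as.integer(max_iter), seed = as.integer(seed),
                 fisher_epsilon = fisher_epsilon, fdr_alpha = fdr_alpha,
                 node_subsets = node_subsets, harmonize = harmonize,
                 exemplar_variance = exemplar_variance),
            class = "dfc_config")
}

#' Read one subject's ROI time-series matrix
#'
#' Reads a tab-separated table with one header row of node labels and a numeric
#' body (rows = time points, columns = ROI nodes). The reader validates rather
#' than repairs: a non-numeric cell or a node-count mismatch is an error, and
#' row/column order is preserved exactly as on disk.
#'
#' @param path Path to a TSV file.
#' @param expected_nodes Optional integer; error if the column count differs.
#' @param tr_seconds Repetition time in seconds attached to the result.
#' @param subject_id Subject identifier; defaults to the file name without
#'   extension.
#' @return A `subject_timeseries` object: list with `subject_id`, `data`
#'   (T x N numeric matrix), `node_labels`, `tr_seconds`.
#' @export
read_timeseries <- function(path, expected_nodes = NULL, tr_seconds = 2,
                            subject_id = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("time-series file must have at least 2 node columns: ", path)
  if (!is.null(expected_nodes) && ncol(df) != expected_nodes) {
    stop(sprintf("node count mismatch in %s: found %d columns, expected %d",
                 path, ncol(df), expected_nodes))
  }
  mat <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) & !(trimws(df[[j]]) %in% c("NA", "NaN")))
    if (length(bad) > 0) {
      stop(sprintf("non-numeric value '%s' at row %d, column '%s' of %s",
                   df[[j]][bad[1]], bad[1], colnames(df)[j], path))
    }
    mat[, j] <- v
  }
  subject_timeseries(mat, tr_seconds = tr_seconds,
                     subject_id = if (is.null(subject_id))
                       sub("\\.[^.]+$", "", basename(path)) else subject_id)
}

#' Construct a subject time-series object
#'
#' @param data Numeric T x N matrix (time points x nodes); column names are
#'   used as node labels when present.
#' @param tr_seconds Repetition time in seconds.
#' @param subject_id Identifier string.
#' @param node_labels Optional character vector overriding column names.
#' @return A `subject_timeseries` object.
#' @export
subject_timeseries <- function(data, tr_seconds = 2, subject_id = "subject",
                               node_labels = NULL) {
  data <- as.matrix(data)
  if (is.null(node_labels)) {
    node_labels <- colnames(data)
    if (is.null(node_labels)) node_labels <- paste0("node", seq_len(ncol(data)))
  }
  stopifnot(ncol(data) >= 2, length(node_labels) == ncol(data),
            !anyDuplicated(node_labels), tr_seconds > 0)
  colnames(data) <- node_labels
  structure(list(subject_id = subject_id, data = data,
                 node_labels = node_labels, tr_seconds = tr_seconds),
            class = "subject_timeseries")
}

#' Write a subject time-series matrix to TSV
#'
#' @param ts A `subject_timeseries` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "subject_timeseries"))
  write_table(as.data.frame(ts$data, check.names = FALSE), path)
}

.group_levels <- c("control", "patient")
.sex_levels <- c("M", "F")

#' Read the cohort metadata table
#'
#' Required columns: `subject_id`, `group` (`control`/`patient`), `site`,
#' `age`, `sex` (`M`/`F`), `mean_fd`. Optional columns (`hamd`,
#' `illness_duration_months`, `medication`, `episode`) are parsed when present;
#' empty cells become `NA`, never zero. Duplicate subject ids and unknown
#' categorical labels are errors.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of class `cohort_table`, one row per subject.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          na.strings = c("", "NA"))
  as_cohort_table(df)
}

#' Validate a data.frame as a cohort table
#'
#' @param df A data.frame with the columns described in [read_metadata()].
#' @return The validated data.frame with class `cohort_table` prepended.
#' @export
as_cohort_table <- function(df) {
  required <- c("subject_id", "group", "site", "age", "sex", "mean_fd")
  missing <- setdiff(required, colnames(df))
  if (length(missing) > 0) {
    stop("metadata is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0) {
    stop("duplicate subject_id in metadata: ", paste(unique(dup), collapse = ", "))
  }
  bad_group <- setdiff(unique(df$group), .group_levels)
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         " (allowed: ", paste(.group_levels, collapse = ", "), ")")
  }
  bad_sex <- setdiff(stats::na.omit(unique(df$sex)), .sex_levels)
  if (length(bad_sex) > 0) {
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "))
  }
  df$group <- factor(df$group, levels = .group_levels)
  df$site <- as.character(df$site)
  df$age <- as.numeric(df$age)
  df$mean_fd <- as.numeric(df$mean_fd)
  for (opt in c("hamd", "illness_duration_months")) {
    if (opt %in% colnames(df)) df[[opt]] <- as.numeric(df[[opt]])
  }
  for (opt in c("medication", "episode")) {
    if (opt %in% colnames(df)) {
      v <- as.character(df[[opt]])
      v[v %in% c("missing")] <- NA_character_
      allowed <- if (opt == "medication") c("medicated", "unmedicated")
                 else c("first", "recurrent")
      bad <- setdiff(stats::na.omit(unique(v)), allowed)
      if (length(bad) > 0) stop("unknown ", opt, " label(s): ",
                                paste(bad, collapse = ", "))
      df[[opt]] <- v
    }
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a tabular artifact to TSV
#'
#' Plain tab-separated output with one header row, no quoting and no row
#' names; numeric columns are written at full double precision so that
#' write-then-read round-trips are exact to representation error.
#'
#' @param records A data.frame (or matrix) to write; may have zero rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    v <- df[[j]]
    out <- vapply(v, function(x) {
      if (is.na(x)) NA_character_
      else if (is.integer(v) || x == round(x) && abs(x) < 1e15)
        format(x, scientific = FALSE)
      else sprintf("%.17g", x)
    }, character(1))
    df[[j]] <- out
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "")
  invisible(path)
}

#' Read a generic TSV artifact written by [write_table()]
#'
#' @param path Input path.
#' @return A data.frame with columns type-converted; empty cells are `NA`.
#' @export
read_table <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    na.strings = c("", "NA"))
}

#' Write / read a pipeline configuration
#'
#' The configuration is stored as a flat `key<TAB>value` file mirroring the
#' [dfc_config()] field names; vector fields are comma-separated and the named
#' `node_subsets` entries are stored as `node_subsets.<name>` keys.
#'
#' @param cfg A `dfc_config` object.
#' @param path File path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   `dfc_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "dfc_config"))
  flat <- cfg
  subsets <- flat$node_subsets
  flat$node_subsets <- NULL
  keys <- names(flat)
  vals <- vapply(flat, function(v) paste(as.character(v), collapse = ","),
                 character(1))
  if (length(subsets) > 0) {
    keys <- c(keys, paste0("node_subsets.", names(subsets)))
    vals <- c(vals, vapply(subsets, paste, character(1), collapse = ","))
  }
  writeLines(paste(keys, vals, sep = "\t"), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1))
  named <- stats::setNames(as.list(vals), keys)
  is_subset <- startsWith(keys, "node_subsets.")
  subsets <- lapply(named[is_subset], function(v) strsplit(v, ",")[[1]])
  names(subsets) <- sub("^node_subsets\\.", "", keys[is_subset])
  named <- named[!is_subset]
  num <- function(x) as.numeric(strsplit(x, ",")[[1]])
  dfc_config(
    window_length_tr = num(named$window_length_tr),
    step_tr = num(named$step_tr),
    k = if (identical(named$k, "auto")) "auto" else num(named$k),
    k_range = num(named$k_range),
    replicates = num(named$replicates),
    elbow_replicates = num(named$elbow_replicates),
    max_iter = num(named$max_iter),
    seed = num(named$seed),
    fisher_epsilon = num(named$fisher_epsilon),
    fdr_alpha = num(named$fdr_alpha),
    node_subsets = subsets,
    harmonize = named$harmonize,
    exemplar_variance = named$exemplar_variance)
}

#' Published reference summary statistics
#'
#' Returns the printed group-level summary statistics (per-group n, mean, SD)
#' from a large multisite case-control resting-state study of frontoparietal
#' dFC (445 controls, 442 patients), shipped with the package as plain TSV.
#' These tables serve two purposes: they are the worked-example inputs for the
#' summary-statistic battery ([welch_t_summary()], [hedges_g_summary()],
#' [bh_fdr()]) and they anchor the simulator's default regime targets.
#'
#' @param which One of `"temporal"` (7 temporal dFC metrics), `"transitions"`
#'   (6 directed state-pair transition counts), `"state_fc"` (per-state mean
#'   FC strength with per-state n), `"demographics"` (age summaries and the
#'   sex contingency counts).
#' @return A data.frame.
#' @export
reference_summaries <- function(which = c("temporal", "transitions",
                                          "state_fc", "demographics")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".tsv"),
                      package = "dfcstates", mustWork = TRUE)
  read_table(path)
}
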