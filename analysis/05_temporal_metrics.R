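#!/usr/bin/env Rscript
# Stage 5: per-subject temporal metrics.
#
# From each subject's state sequence: fractional occupancy, mean dwell time
# (window units; NA where a state is never visited), total and pairwise
# directed transition counts, and state-conditioned mean FC strength over the
# full node set. The identities (occupancies sum to 1, pairwise counts sum to
# total transitions, runs x dwell = windows) are asserted per subject inside
# temporal_metrics().

suppressMessages(library(dfcstates))

features <- read_table("results/dfc/window_features_harmonized.tsv")
seqs <- read_table("results/states/state_sequences.tsv")
edge_cols <- setdiff(colnames(features),
                     c("subject_id", "window_index", "start", "valid"))
node_labels <- unique(unlist(strsplit(edge_cols, "__", fixed = TRUE)))

metrics <- do.call(rbind, lapply(split(seqs, seqs$subject_id), function(sq) {
  rows <- features$subject_id == sq$subject_id[1]
  series <- structure(list(
    subject_id = sq$subject_id[1], node_labels = node_labels,
    windows = data.frame(index = features$window_index[rows],
                         start = features$start[rows],
                         valid = features$valid[rows]),
    edges = as.matrix(features[rows, edge_cols])),
    class = "dfc_window_series")
  seq_obj <- structure(list(subject_id = sq$subject_id[1],
                            window_index = sq$window_index,
                            labels = sq$state),
                       class = "state_sequence")
  temporal_metrics(series, seq_obj, k = 3)
}))
write_table(metrics, "results/metrics.tsv")

cat(sprintf("Metrics for %d subjects\n", nrow(metrics)))
cat(sprintf("Mean occupancy (s1 s2 s3): %s\n",
            paste(round(colMeans(metrics[, paste0("occupancy_s", 1:3)]), 3),
                  collapse = " ")))
cat(sprintf("Mean state FC (s1 s2 s3): %s  (targets 0.198 0.106 0.288)\n",
            paste(round(colMeans(metrics[, paste0("fc_s", 1:3)], na.rm = TRUE), 3),
                  collapse = " ")))
cat(sprintf("Mean transitions: %.1f\n", mean(metrics$transitions)))
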