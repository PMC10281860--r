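# Shared protocol for the planted-structure recovery study: simulate the
# standard fixture at one seed, run the sequence-window selection, the
# per-sample histone-window selection, clustering and voting, and report
# what was recovered against the planted truth.
recover_planted_structure <- function(seed) {
  cfg <- sim_config(seed = seed)
  truth <- simulate_truth(cfg)
  regions <- simulate_sequences(cfg)
  tracks <- simulate_tracks(cfg, truth, regions)
  dataset <- assemble_dataset(regions, tracks, seed = seed)
  split <- split_train_test(dataset, seed = seed)
  layout <- build_layout(cfg$seq_length, cfg$LF)
  rc <- default_run_config()
  rc$seed <- seed

  scorer <- fit_window_scorer(split$train, layout, rc)
  curve_records <- split$train[split$train$label == "eRNA", , drop = FALSE]
  if (nrow(curve_records) > rc$score_records)
    curve_records <- curve_records[seq_len(rc$score_records), , drop = FALSE]
  curve <- score_windows(scorer, curve_records, layout)
  seq_window <- select_optimal_sequence_window(curve, layout$center_index)

  erna_train <- split$train[split$train$label == "eRNA", , drop = FALSE]
  all_regions <- rbind(split$train, split$test)
  labels_all <- stats::setNames(all_regions$label, all_regions$name)
  pos_marks <- names(MARK_POLARITY)[MARK_POLARITY == "positive"]
  cand <- list()
  pos_mark_center <- logical(0)
  for (s in names(tracks)) {
    ow <- histone_optimal_windows(erna_train, tracks[[s]],
                                  S = cfg$seq_length, LF = cfg$LF)
    pos_mark_center <- c(pos_mark_center, vapply(
      ow[pos_marks], function(o) o$index == o$layout$center_index,
      logical(1)))
    fm <- histone_feature_matrix(all_regions, ow, tracks[[s]])
    cl <- cluster_sample(fm, seed = seed)
    cand[[s]] <- label_candidate_cluster(cl, labels_all, s)
  }
  assignment <- vote_re(cand, labels_all)
  called <- names(assignment$flag)[assignment$flag == "RE"]
  true_re <- names(truth$class)[truth$class == "RE"]
  list(
    seq_window = seq_window,
    center_index = layout$center_index,
    pos_mark_center = pos_mark_center,
    recall = mean(true_re %in% called),
    precision = if (length(called)) mean(called %in% true_re) else 0,
    re_prop = re_proportion(assignment))
}

# Fixture for the feature-contribution study: labels are driven only by
# the histone channel (no planted sequence signal: motif-free, uniform
# composition), short regions so the sequence model trains quickly, and
# a high RE fraction so nearly every positive carries the consistent
# histone enrichment that defines the channel's signal.
histone_only_config <- function(seed) {
  sim_config(seed = seed, n_ernas = 60L, n_nes = 60L,
             seq_length = 1001L, LF = 100L, n_samples = 2L,
             re_fraction = 0.8, motif_prob = 0, gc_center = 0.5)
}

# Train fused and sequence-only models on one histone-only fixture and
# return their test AUCs.
fused_vs_sequence_auc <- function(seed) {
  cfg <- histone_only_config(seed)
  truth <- simulate_truth(cfg)
  regions <- simulate_sequences(cfg)
  tracks <- simulate_tracks(cfg, truth, regions)
  rc <- default_run_config()
  rc$seed <- seed
  rc$LF <- cfg$LF
  rc$scorer <- utils::modifyList(rc$scorer,
                                 list(hidden = 8L, embed_dim = 8L))
  rc$scorer_train_regions <- 32L
  rc$scorer_restarts <- 1L
  rc$grid <- list(hidden = 8L, epochs = 60L, batch_size = 16L,
                  lr = 5e-3)
  rc$folds <- 3L
  res <- run_pipeline(regions, tracks, rc)
  seq_model <- train_fusion(NULL, res$seq_features$train,
                            as.numeric(res$split$train$label == "eRNA"),
                            list(hidden = 8L, epochs = 60L,
                                 batch_size = 16L, lr = 5e-3,
                                 variant = "sequence_only"),
                            seed = seed)
  p_seq <- fusion_forward(seq_model, NULL, res$seq_features$test)
  c(fused = res$metrics[["AUC"]],
    seq_only = roc_auc(res$labels_test, p_seq)$auc)
}
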