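# End-to-end orchestration: dataset assembly and split, window-scorer
# training and optimal-window selection, per-sample histone features and
# optimal windows, clustering + voting, fusion-model training with CV
# grid search, prediction and evaluation.  The CLI wraps these stages
# with on-disk artifacts; run_pipeline() performs them in memory.

#' Default run configuration
#'
#' The single source of truth for a pipeline run: simulation overrides,
#' window sizes, scorer and fusion hyperparameters, the CV grid, seeds
#' and flags.  Values can be overridden by a YAML config file
#' ([load_run_config()]) and by CLI flags.
#'
#' @return A named list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    sim = list(),               # sim_config() overrides
    LF = 300L,
    k = 2L,
    ratio = c(4, 1),
    scorer = list(hidden = 16L, embed_dim = 16L, layers = 1L,
                  epochs = 2L, batch_size = 64L, lr = 1e-3,
                  dropout = 0.1),   # desk-scale scorer settings
    scorer_train_regions = 48L, # stratified subsample for scorer training
    scorer_restarts = 3L,       # max re-initialisations of the scorer
    scorer_min_prominence = 0.06, # gate-curve peak height that ends the
                                  # restart loop early (about 4 standard
                                  # errors of a 64-record window mean)
    scorer_gate_records = 64L,  # eRNA records scored for the gate curve
    score_records = 128L,       # eRNA records used for the score curve
    grid = list(hidden = c(16L, 32L), epochs = 20L,
                batch_size = 16L, lr = 1e-3, dropout = 0.3),
    folds = 5L,
    cv_metric = "ACC",
    chosen_sample = 1L,
    signal_weighted = FALSE,
    threshold = 0.5)
}

#' Load a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_run_config()].
#'
#' @param path Path to a YAML file (NULL for pure defaults).
#' @return The merged configuration list, with attribute `hash` (the MD5
#'   of the effective configuration, embedded in every artifact).
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    over <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, over)
  }
  attr(cfg, "hash") <- config_hash(cfg)
  cfg
}

# Label-stratified subsample of dataset rows (seeded); returns the full
# set when n is NULL or not smaller than the dataset.
stratified_subsample <- function(dataset, n, seed) {
  if (is.null(n) || n >= nrow(dataset)) return(dataset)
  set.seed(as.integer(seed) + 7L)
  idx <- integer(0)
  labs <- unique(dataset$label)
  per <- max(1L, n %/% length(labs))
  for (lab in labs) {
    rows <- which(dataset$label == lab)
    idx <- c(idx, sample(rows, min(per, length(rows))))
  }
  dataset[sort(idx), , drop = FALSE]
}

#' Train the window scorer for a dataset split
#'
#' Shared sequence-channel stage: trains the scorer on the pooled
#' windows of a stratified subsample of training regions, with up to
#' `scorer_restarts` re-initialisations.  Each candidate is judged by
#' the peak prominence (maximum minus median) of its per-window score
#' curve over the subsample's eRNA records -- an initialisation whose
#' curve is flat has not picked up window-level signal, exactly as a
#' poor k-means start is judged by its inertia -- and the restart loop
#' stops as soon as the prominence reaches `scorer_min_prominence`.
#'
#' @param train Training dataset (data.frame with `sequence`, `label`).
#' @param layout The [build_layout()] for these regions.
#' @param config Run configuration (see [default_run_config()]).
#' @return The selected `window_scorer`.
#' @export
fit_window_scorer <- function(train, layout, config = default_run_config()) {
  sub <- stratified_subsample(train, config$scorer_train_regions,
                              config$seed)
  w <- unlist(lapply(sub$sequence, region_windows, layout = layout),
              use.names = FALSE)
  y <- rep(as.numeric(sub$label == "eRNA"), each = nrow(layout$windows))
  hp <- utils::modifyList(list(k = config$k), config$scorer)
  gate <- train[train$label == "eRNA", , drop = FALSE]
  n_gate <- config$scorer_gate_records
  if (!is.null(n_gate) && nrow(gate) > n_gate)
    gate <- gate[seq_len(n_gate), , drop = FALSE]
  best <- NULL
  for (r in seq_len(max(1L, config$scorer_restarts))) {
    sc <- train_window_scorer(w, y, hp,
                              seed = config$seed + 1000L * (r - 1L))
    curve <- score_windows(sc, gate, layout)
    prom <- max(curve) - stats::median(curve)
    if (is.null(best) || prom > best$prom)
      best <- list(scorer = sc, prom = prom)
    if (best$prom >= config$scorer_min_prominence) break
  }
  best$scorer
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full identification pipeline in memory
#'
#' Stages: balanced dataset assembly; stratified train/test split;
#' window-scorer training on the pooled training windows; per-window
#' score curve and optimal sequence window; sequence features; per-sample
#' histone optimal windows (from training eRNAs) and feature matrices;
#' per-sample clustering and cross-sample voting; 6D matrix of the chosen
#' sample; CV grid search + final fusion model; test-set prediction and
#' metrics.
#'
#' @param regions Region data.frame with sequences (e.g.
#'   [simulate_sequences()] output or a region table joined to a FASTA).
#' @param tracks A `track_set` (per-sample named lists of
#'   [sample_track()]s).
#' @param config A run configuration ([default_run_config()] merged with
#'   overrides).
#' @return A list with the dataset split, scorer, score curve, selected
#'   windows, feature matrices, RE assignment, model, predictions and
#'   metrics.
#' @export
run_pipeline <- function(regions, tracks, config = default_run_config()) {
  dataset <- assemble_dataset(regions, tracks, seed = config$seed)
  split <- split_train_test(dataset, ratio = config$ratio,
                            seed = config$seed)
  S <- unique(nchar(dataset$sequence))
  layout <- build_layout(S, config$LF)

  # ---- sequence channel ---------------------------------------------------
  scorer <- fit_window_scorer(split$train, layout, config)
  curve_records <- split$train[split$train$label == "eRNA", , drop = FALSE]
  if (!is.null(config$score_records) &&
      nrow(curve_records) > config$score_records)
    curve_records <- curve_records[seq_len(config$score_records), ,
                                   drop = FALSE]
  score_curve <- score_windows(scorer, curve_records, layout)
  opt_window <- select_optimal_sequence_window(score_curve,
                                               layout$center_index)
  seq_train <- extract_sequence_features(scorer, split$train$sequence,
                                         layout, opt_window)
  seq_test <- extract_sequence_features(scorer, split$test$sequence,
                                        layout, opt_window)
  rownames(seq_train) <- split$train$name
  rownames(seq_test) <- split$test$name

  # ---- histone channel ----------------------------------------------------
  all_regions <- rbind(split$train, split$test)
  erna_train <- split$train[split$train$label == "eRNA", , drop = FALSE]
  labels_all <- stats::setNames(all_regions$label, all_regions$name)
  opt_windows <- list()
  feats <- list()
  candidate_sets <- list()
  for (s in names(tracks)) {
    ow <- histone_optimal_windows(erna_train, tracks[[s]], S = S,
                                  LF = config$LF)
    fm <- histone_feature_matrix(all_regions, ow, tracks[[s]],
                                 config$signal_weighted)
    cl <- cluster_sample(fm, seed = config$seed)
    candidate_sets[[s]] <- label_candidate_cluster(cl, labels_all, s)
    opt_windows[[s]] <- ow
    feats[[s]] <- fm
  }
  assignment <- vote_re(candidate_sets, labels_all)

  chosen <- if (is.character(config$chosen_sample)) config$chosen_sample
            else names(tracks)[config$chosen_sample]
  if (is.na(chosen) || !chosen %in% names(tracks))
    stop("config error: chosen_sample not among the track samples")
  six_d <- build_6d_features(feats[[chosen]], assignment)
  x6_train <- six_d[split$train$name, , drop = FALSE]
  x6_test <- six_d[split$test$name, , drop = FALSE]
  y_train <- as.numeric(split$train$label == "eRNA")
  y_test <- as.numeric(split$test$label == "eRNA")

  # ---- fusion classifier --------------------------------------------------
  cv <- grid_search_cv(x6_train, seq_train, y_train, config$grid,
                       folds = config$folds, metric = config$cv_metric,
                       seed = config$seed)
  pred <- predict(cv$model, x6_test, seq_test,
                  threshold = config$threshold)
  m <- metrics(confusion(y_test, pred$prob, config$threshold))
  roc <- roc_auc(y_test, pred$prob)

  list(dataset = dataset, split = split, layout = layout,
       scorer = scorer, score_curve = score_curve,
       optimal_window = opt_window,
       seq_features = list(train = seq_train, test = seq_test),
       histone_windows = opt_windows, histone_features = feats,
       candidate_sets = candidate_sets, assignment = assignment,
       six_d = six_d, cv = cv, model = cv$model,
       predictions = data.frame(name = split$test$name, pred),
       metrics = c(m, AUC = roc$auc), roc = roc,
       labels_test = y_test)
}

#' Save / load a scorer or model checkpoint
#'
#' Single-file container (R serialization) embedding the full parameter
#' set and configuration.
#'
#' @param object A `window_scorer` or `fusion_model`.
#' @param path Checkpoint path.
#' @return `path` invisibly ([save_checkpoint()]); the restored object
#'   ([load_checkpoint()]).
#' @export
save_checkpoint <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  readRDS(path)
}
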