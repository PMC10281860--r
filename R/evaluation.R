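# Evaluation: confusion-matrix metrics (sensitivity, specificity,
# accuracy, Matthews correlation coefficient), ROC/AUC by trapezoidal
# integration (equal to the Mann-Whitney pairwise concordance statistic
# with ties counted one half), and the fused-vs-sequence-only ablation
# protocol.

#' Confusion counts at a threshold
#'
#' A record is predicted positive iff its probability is `>= threshold`.
#'
#' @param labels 0/1 vector.
#' @param probabilities Numeric vector, same length.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return A list of class `confusion_counts` with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities))
    stop("shape error: labels and probabilities differ in length")
  if (threshold <= 0 || threshold >= 1)
    stop("confusion: threshold must be in (0, 1)")
  pred <- probabilities >= threshold
  y <- labels == 1
  structure(list(TP = sum(pred & y), TN = sum(!pred & !y),
                 FP = sum(pred & !y), FN = sum(!pred & y)),
            class = "confusion_counts")
}

#' Confusion-matrix metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/N` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.  A metric
#' whose denominator is zero is returned as `NA` with its name recorded
#' in the `undefined` attribute; a zero MCC denominator yields 0 by
#' convention (also flagged).
#'
#' @param counts A [confusion()] result (or list with `TP`, `TN`, `FP`,
#'   `FN`).
#' @return Named numeric vector `SN`, `SP`, `ACC`, `MCC` with attribute
#'   `undefined` (character vector of flagged metrics).
#' @export
metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  undefined <- character(0)
  sn <- if (TP + FN == 0) { undefined <- c(undefined, "SN"); NA_real_ }
        else TP / (TP + FN)
  sp <- if (TN + FP == 0) { undefined <- c(undefined, "SP"); NA_real_ }
        else TN / (TN + FP)
  n <- TP + TN + FP + FN
  acc <- if (n == 0) { undefined <- c(undefined, "ACC"); NA_real_ }
         else (TP + TN) / n
  denom <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  mcc <- if (denom == 0) { undefined <- c(undefined, "MCC"); 0 }
         else (as.numeric(TP) * TN - as.numeric(FP) * FN) / denom
  structure(c(SN = sn, SP = sp, ACC = acc, MCC = mcc),
            undefined = undefined)
}

#' ROC curve and AUC
#'
#' The ROC curve over all score thresholds and its area by trapezoidal
#' integration, which equals the pairwise concordance statistic
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param labels 0/1 vector with both classes present.
#' @param probabilities Numeric score vector.
#' @return A list with `curve` (data.frame `fpr`, `tpr`, `threshold`)
#'   and `auc`.
#' @export
roc_auc <- function(labels, probabilities) {
  if (length(labels) != length(probabilities))
    stop("shape error: labels and probabilities differ in length")
  y <- labels == 1
  if (!any(y) || all(y))
    stop("undefined-AUC error: both classes must be present")
  ord <- order(probabilities, decreasing = TRUE)
  y_ord <- y[ord]
  s_ord <- probabilities[ord]
  # collapse tied scores so ties contribute a single ROC vertex
  last_of_run <- c(s_ord[-1] != s_ord[-length(s_ord)], TRUE)
  tp <- cumsum(y_ord)[last_of_run]
  fp <- cumsum(!y_ord)[last_of_run]
  P <- sum(y); N <- sum(!y)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(fpr = fpr, tpr = tpr,
                          threshold = c(Inf, s_ord[last_of_run])),
       auc = auc)
}

#' Ablation: fused versus sequence-only models
#'
#' Trains the fused model and the sequence-only model on each supplied
#' dataset (e.g. one per tissue or fold), evaluates both on the matching
#' test set, and reports the per-dataset metric sets, the paired
#' differences, and a two-sample t-test p-value per metric across
#' datasets.
#'
#' @param datasets A list; each element is a list with `train` and
#'   `test`, each holding `six_d` (matrix), `seq_features` (matrix) and
#'   `labels` (0/1).
#' @param hyperparams Passed to [train_fusion()] for both variants.
#' @param seed Integer seed.
#' @return A list with `table` (one row per dataset per variant:
#'   `dataset variant SN SP ACC MCC AUC`), `differences` (fused minus
#'   sequence-only per dataset) and `p_values` (per metric; `NA` when
#'   fewer than two datasets).
#' @export
ablation_compare <- function(datasets, hyperparams = list(), seed = 1L) {
  stopifnot(length(datasets) >= 1L)
  rows <- list()
  for (d in seq_along(datasets)) {
    ds <- datasets[[d]]
    for (variant in c("fused", "sequence_only")) {
      hp <- utils::modifyList(hyperparams, list(variant = variant))
      model <- train_fusion(ds$train$six_d, ds$train$seq_features,
                            ds$train$labels, hp, seed = seed + d)
      p <- fusion_forward(model, ds$test$six_d, ds$test$seq_features)
      m <- metrics(confusion(ds$test$labels, p))
      rows[[length(rows) + 1L]] <- data.frame(
        dataset = d, variant = variant,
        SN = m[["SN"]], SP = m[["SP"]], ACC = m[["ACC"]],
        MCC = m[["MCC"]],
        AUC = roc_auc(ds$test$labels, p)$auc)
    }
  }
  tab <- do.call(rbind, rows)
  met_cols <- c("SN", "SP", "ACC", "MCC", "AUC")
  fus <- tab[tab$variant == "fused", met_cols, drop = FALSE]
  seqo <- tab[tab$variant == "sequence_only", met_cols, drop = FALSE]
  diffs <- fus - seqo
  diffs$dataset <- unique(tab$dataset)
  p_values <- vapply(met_cols, function(mc) {
    if (nrow(fus) < 2L) return(NA_real_)
    tryCatch(stats::t.test(fus[[mc]], seqo[[mc]])$p.value,
             error = function(e) NA_real_)
  }, numeric(1))
  list(table = tab, differences = diffs, p_values = p_values)
}

#' Write a metrics table as TSV
#'
#' Columns `dataset variant SN SP ACC MCC AUC`.
#'
#' @param table Data.frame as produced by [ablation_compare()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
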