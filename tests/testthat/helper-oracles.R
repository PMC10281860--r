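# Independent oracles used across the suite.

# Brute-force center-out tiling: marks every offset of [0, S) with a
# window id by placing the center window around the central base and
# walking outward one window at a time.  Returns a data.frame of window
# start/end offsets sorted left to right.
oracle_tiling <- function(S, L) {
  mid <- S %/% 2
  half <- L %/% 2
  bounds <- c(mid - half, mid + half + 1)    # center window, half-open
  lo <- bounds[1]
  while (lo > 0) {
    lo2 <- max(0, lo - L)
    bounds <- c(lo2, bounds)
    lo <- lo2
  }
  hi <- bounds[length(bounds)]
  while (hi < S) {
    hi2 <- min(S, hi + L)
    bounds <- c(bounds, hi2)
    hi <- hi2
  }
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

# Pairwise-concordance AUC: P(score_pos > score_neg) + 0.5 P(tie).
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Direct formula evaluation of the confusion metrics.
oracle_metrics <- function(tp, tn, fp, fn) {
  c(SN = tp / (tp + fn), SP = tn / (tn + fp),
    ACC = (tp + tn) / (tp + tn + fp + fn),
    MCC = (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
}

# Closed-form voting rule straight from the stated thresholds.
oracle_vote <- function(m, n) {
  if (n %% 2 == 0) m >= n / 2 else m > n / 2
}

random_dna_str <- function(len, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}

# A small planted-motif window set: half the windows carry the motif at
# a random position, labels follow motif presence.
motif_windows <- function(n, len, motif, seed = 1) {
  set.seed(seed)
  y <- rep(c(1, 0), length.out = n)
  w <- vapply(y == 1, function(has) {
    s <- random_dna_str(len)
    if (has) {
      pos <- sample(len - nchar(motif), 1)
      substr(s, pos, pos + nchar(motif) - 1) <- motif
    }
    s
  }, character(1))
  list(windows = w, labels = y)
}
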