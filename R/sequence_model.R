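# The sequence channel: k-mer tokenization, a pluggable embedding backend
# (default: trainable lookup table), and a window scorer built from two
# stacked bidirectional LSTM layers with batch normalization and dropout,
# ending in a dense + sigmoid head.  The scorer is trained on all windows
# pooled, each window inheriting its parent region's label; per-window
# mean scores over eRNA records give the score curve from which the
# optimal window is selected, and the fixed-width sequence feature is the
# encoder's pooled bidirectional summary (width 2H) at the optimal window.

#' Tokenize a sequence into overlapping k-mers
#'
#' Sliding window of size `k`, step 1, order preserved; yields
#' `nchar(sequence) - k + 1` tokens.
#'
#' @param sequence A DNA string.
#' @param k k-mer size (>= 1).
#' @return A list of class `token_sequence` with elements `tokens`
#'   (character vector) and `k`.
#' @examples
#' tokenize_kmers("ACGT", 2)$tokens  # "AC" "CG" "GT"
#' @export
tokenize_kmers <- function(sequence, k) {
  k <- as.integer(k)
  if (k < 1L) stop("tokenize_kmers: k must be >= 1")
  n <- nchar(sequence)
  if (n < k)
    stop(sprintf("length error: sequence length %d < k = %d", n, k))
  tokens <- substring(sequence, 1:(n - k + 1L), k:n)
  structure(list(tokens = tokens, k = k), class = "token_sequence")
}

#' Enumerate the k-mer vocabulary
#'
#' All `4^k` k-mers over \{A, C, G, T\} in lexicographic order.
#'
#' @param k k-mer size.
#' @return Character vector of length `4^k`.
#' @export
kmer_vocab <- function(k) {
  bases <- c("A", "C", "G", "T")
  v <- bases
  if (k > 1) for (i in 2:k)
    v <- as.vector(t(outer(v, bases, paste0)))
  sort(v)
}

#' Construct an embedding backend
#'
#' The default backend is a trainable lookup table over the `4^k` k-mer
#' vocabulary, trained jointly with the window scorer.  The interface is
#' pluggable so a pretrained contextual DNA language model can be dropped
#' in by supplying an object with the same fields and an `embed` method.
#'
#' @param k k-mer size (vocabulary `4^k`).
#' @param dim Embedding width.
#' @param seed Seed for the initial table.
#' @param init `"glorot"` (default) or `"identity"` (requires
#'   `dim == 4^k`; token i maps to unit vector e_i, useful for testing).
#' @return A list of class `embedding_backend` with fields `name`, `k`,
#'   `dim`, `vocab` (k-mer -> index map) and `E` (the lookup table).
#' @export
embedding_backend <- function(k = 2, dim = 32, seed = 1L,
                              init = c("glorot", "identity")) {
  init <- match.arg(init)
  vocab <- kmer_vocab(k)
  V <- length(vocab)
  if (init == "identity") {
    if (dim != V) stop("identity init requires dim == 4^k")
    E <- diag(V)
  } else {
    set.seed(as.integer(seed))
    E <- glorot(V, dim)
  }
  rownames(E) <- vocab
  structure(
    list(name = "trainable-lookup", k = k, dim = as.integer(dim),
         vocab = stats::setNames(seq_len(V), vocab), E = E),
    class = "embedding_backend")
}

#' Embed a token sequence
#'
#' @param tokens A `token_sequence` (or character vector of k-mers).
#' @param backend An [embedding_backend()].
#' @return A numeric matrix of shape `(num_tokens, dim)`.
#' @export
embed <- function(tokens, backend) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  idx <- backend$vocab[tokens]
  if (anyNA(idx))
    stop(sprintf("vocabulary error: unknown token '%s'",
                 tokens[which(is.na(idx))[1]]))
  backend$E[idx, , drop = FALSE]
}

# ---- fast integer tokenization -------------------------------------------

# Map a DNA string to 1-based k-mer ids matching kmer_vocab() order;
# k-mers containing anything outside A/C/G/T get the pad id (0 here,
# remapped to the pad row later).
base_lookup <- local({
  tab <- rep(NA_integer_, 256)
  tab[utf8ToInt("A")] <- 0L; tab[utf8ToInt("C")] <- 1L
  tab[utf8ToInt("G")] <- 2L; tab[utf8ToInt("T")] <- 3L
  tab
})

kmer_ids <- function(sequence, k) {
  b <- base_lookup[utf8ToInt(sequence)]
  n <- length(b)
  if (n < k) return(integer(0))
  ids <- rep(1L, n - k + 1L)
  for (j in seq_len(k)) {
    seg <- b[j:(n - k + j)]
    ids <- ids + seg * 4L^(k - j)
  }
  ids[is.na(ids)] <- 0L
  as.integer(ids)
}

# Split a region sequence into its layout windows (character vector).
region_windows <- function(sequence, layout) {
  w <- layout$windows
  substring(sequence, w$start + 1L, w$end)
}

n_fraction <- function(windows) {
  1 - nchar(gsub("N", "", windows, fixed = TRUE)) / nchar(windows)
}

# ---- scorer construction --------------------------------------------------

scorer_defaults <- function() {
  list(k = 2L, embed_dim = 32L, hidden = 64L, layers = 2L,
       dropout = 0.3, epochs = 5L, batch_size = 64L, lr = 1e-3,
       clip_norm = 5, mil_temp = 1, head_refit = TRUE,
       max_n_fraction = 0.1)
}

scorer_config <- function(hyperparams = list()) {
  cfg <- utils::modifyList(scorer_defaults(), hyperparams)
  stopifnot(cfg$k >= 1, cfg$embed_dim > 0, cfg$hidden > 0,
            cfg$layers >= 1, cfg$dropout >= 0, cfg$dropout < 1)
  cfg
}

new_scorer_params <- function(cfg) {
  V <- 4L^cfg$k
  H <- cfg$hidden
  E <- rbind(glorot(V, cfg$embed_dim), 0)  # last row = pad, held at zero
  p <- list(E = E)
  in_dim <- cfg$embed_dim
  for (l in seq_len(cfg$layers)) {
    for (dir in c("f", "b")) {
      lp <- lstm_init(in_dim, H)
      p[[sprintf("l%d%s.W", l, dir)]] <- lp$W
      p[[sprintf("l%d%s.U", l, dir)]] <- lp$U
      p[[sprintf("l%d%s.b", l, dir)]] <- lp$b
    }
    in_dim <- 2L * H
  }
  p$bn.gamma <- rep(1, 2 * H)
  p$bn.beta <- rep(0, 2 * H)
  p$head.W <- glorot(2L * H, 1L)
  p$head.b <- 0
  p
}

# Pack window sequences into an id matrix [N, T] plus lengths; pad id is
# V + 1 (the zero embedding row).
pack_windows <- function(windows, k) {
  V <- 4L^k
  ids <- lapply(windows, kmer_ids, k = k)
  lens <- lengths(ids)
  T_ <- max(lens)
  mat <- matrix(V + 1L, length(windows), T_)
  for (i in seq_along(ids)) {
    v <- ids[[i]]
    v[v == 0L] <- V + 1L   # ambiguous k-mers get the zero pad embedding
    if (lens[i] > 0L) mat[i, seq_len(lens[i])] <- v
  }
  list(mat = mat, lens = lens)
}

layer_par <- function(params, l, dir) {
  list(W = params[[sprintf("l%d%s.W", l, dir)]],
       U = params[[sprintf("l%d%s.U", l, dir)]],
       b = params[[sprintf("l%d%s.b", l, dir)]])
}

# Time pooling of the encoder outputs within each row's valid length.
# The summary of feature f for row i is the average of the max and the
# mean of out[i, t, f] over valid t: the max part is position-invariant
# (a discriminative subsequence anywhere in the window contributes
# directly) while the mean part reads compositional signal.  Width stays
# 2H.
time_max_pool <- function(out, lens) {
  d <- dim(out); N <- d[1]; T_ <- d[2]; F_ <- d[3]
  masked <- any(lens < T_)
  if (masked) {
    maskv <- rep(ifelse(outer(lens, seq_len(T_), ">="), 0, -Inf), F_)
    m <- matrix(aperm(out + array(maskv, d), c(1L, 3L, 2L)), N * F_, T_)
  } else {
    m <- matrix(aperm(out, c(1L, 3L, 2L)), N * F_, T_)
  }
  amax <- max.col(m, ties.method = "first")
  Smax <- matrix(m[cbind(seq_len(N * F_), amax)], N, F_)
  # mean over valid timesteps (pad positions hold h constant; exclude them)
  if (masked) {
    outm <- out * array(rep(outer(lens, seq_len(T_), ">="), F_), d)
    mv <- matrix(aperm(outm, c(1L, 3L, 2L)), N * F_, T_)
    Smean <- matrix(rowSums(mv), N, F_) / lens
  } else {
    Smean <- matrix(rowSums(m), N, F_) / T_
  }
  list(S = 0.5 * (Smax + Smean), amax = amax, dims = d, lens = lens)
}

time_max_unpool <- function(dS, pool) {
  d <- pool$dims; N <- d[1]; T_ <- d[2]; F_ <- d[3]
  j <- seq_len(N * F_)
  i <- (j - 1L) %% N + 1L
  f <- (j - 1L) %/% N + 1L
  idx <- i + (pool$amax - 1L) * N + (f - 1L) * N * T_
  dOut <- numeric(N * T_ * F_)
  dOut[idx] <- 0.5 * as.vector(dS)
  dOut <- array(dOut, d)
  # mean part: spread dS[i, f] / (2 len_i) over each row's valid timesteps
  valid <- outer(pool$lens, seq_len(T_), ">=")
  dmean <- aperm(array(rep(0.5 * dS / pool$lens, T_), c(N, F_, T_)),
                 c(1L, 3L, 2L))
  dOut + dmean * array(rep(valid, F_), d)
}

# Full scorer forward pass on an id matrix; returns probabilities, the
# summary features, caches for backprop and updated batch-norm state.
scorer_forward <- function(params, cfg, mat, lens, bn_state, training) {
  N <- nrow(mat); T_ <- ncol(mat)
  d <- cfg$embed_dim
  A <- array(params$E[mat, ], c(N, T_, d))
  caches <- list(mat = mat, lens = lens)
  drop_masks <- vector("list", cfg$layers)
  bi_list <- vector("list", cfg$layers)
  bn_cache <- NULL
  for (l in seq_len(cfg$layers)) {
    bi <- bilstm_forward(A, lens, layer_par(params, l, "f"),
                         layer_par(params, l, "b"), want_cache = training)
    bi_list[[l]] <- bi
    if (l < cfg$layers) {
      # batch norm + dropout between the stacked recurrent layers
      H2 <- dim(bi$out)[3]
      flat <- matrix(bi$out, N * T_, H2)
      bn <- bn_forward(flat, params$bn.gamma, params$bn.beta,
                       bn_state$mean, bn_state$var, training)
      bn_state$mean <- bn$running_mean
      bn_state$var <- bn$running_var
      bn_cache <- bn$cache
      dp <- dropout_forward(bn$out, cfg$dropout, training)
      drop_masks[[l]] <- dp$mask
      A <- array(dp$out, c(N, T_, H2))
    }
  }
  pool <- time_max_pool(bi_list[[cfg$layers]]$out, lens)
  S <- pool$S                                 # N x 2H summary (Sfeature)
  dpS <- dropout_forward(S, cfg$dropout, training)
  z <- dense_forward(dpS$out, params$head.W, params$head.b)
  p <- sigmoid(z)
  list(p = as.vector(p), z = as.vector(z), S = S, pool = pool, bi = bi_list,
       bn_cache = bn_cache, drop_masks = drop_masks,
       dropS_mask = dpS$mask, Sdrop = dpS$out,
       caches = caches, bn_state = bn_state)
}

# Backward pass; dlogit is dLoss/dz at the sigmoid head (length N).
scorer_backward <- function(params, cfg, fw, dlogit) {
  N <- length(dlogit)
  grads <- list()
  dz <- matrix(dlogit, N, 1)
  dd <- dense_backward(dz, fw$Sdrop, params$head.W)
  grads$head.W <- dd$dW
  grads$head.b <- dd$db
  dS <- dropout_backward(dd$dX, fw$dropS_mask)
  dA_next <- time_max_unpool(dS, fw$pool)
  for (l in rev(seq_len(cfg$layers))) {
    bi <- fw$bi[[l]]
    bb <- bilstm_backward(
      bi, layer_par(params, l, "f"), layer_par(params, l, "b"),
      dOut = dA_next)
    grads[[sprintf("l%df.W", l)]] <- bb$fwd$dW
    grads[[sprintf("l%df.U", l)]] <- bb$fwd$dU
    grads[[sprintf("l%df.b", l)]] <- bb$fwd$db
    grads[[sprintf("l%db.W", l)]] <- bb$bwd$dW
    grads[[sprintf("l%db.U", l)]] <- bb$bwd$dU
    grads[[sprintf("l%db.b", l)]] <- bb$bwd$db
    if (l > 1L) {
      T_ <- dim(bb$dA)[2]
      H2 <- dim(bb$dA)[3]
      dflat <- dropout_backward(matrix(bb$dA, nrow(fw$caches$mat) * T_, H2),
                                fw$drop_masks[[l - 1L]])
      bnb <- bn_backward(dflat, fw$bn_cache)
      grads$bn.gamma <- bnb$dgamma
      grads$bn.beta <- bnb$dbeta
      dA_next <- array(bnb$dX, dim(bb$dA))
    } else {
      dX <- bb$dA
    }
  }
  # embedding gradient: scatter-add per token id; pad row stays zero
  d <- cfg$embed_dim
  Tk <- as.vector(fw$caches$mat)
  dXmat <- matrix(dX, length(Tk), d)
  agg <- rowsum(dXmat, group = Tk)
  dE <- array(0, dim(params$E))
  dE[as.integer(rownames(agg)), ] <- agg
  dE[nrow(dE), ] <- 0
  grads$E <- dE
  grads
}

#' Train the window scorer
#'
#' Trains the bidirectional LSTM scorer with the Adam optimizer on binary
#' cross-entropy.  Two supervision modes are supported.  In window mode
#' (`groups = NULL`) every window is an independent training example with
#' its own label (each window inherits its parent region's label:
#' eRNA = 1, NE = 0).  In region-grouped mode, `groups` names the parent
#' region of each window and the objective is multiple-instance: a
#' region's predicted probability is the maximum over its window scores,
#' so a region is called eRNA when at least one of its windows looks like
#' eRNA sequence.  Grouped supervision concentrates the positive gradient
#' on the informative window instead of pulling every flank window of an
#' eRNA toward the positive class, and is the mode the pipeline uses.
#' Windows whose N fraction exceeds `max_n_fraction` (default 10%) are
#' excluded from training.
#'
#' @param train_windows Character vector of window sequences.
#' @param labels Numeric 0/1 vector, one per window (constant within a
#'   group in grouped mode).
#' @param hyperparams Named list overriding the defaults `k = 2`,
#'   `embed_dim = 32`, `hidden = 64`, `layers = 2`, `dropout = 0.3`,
#'   `epochs = 5`, `batch_size = 64`, `lr = 1e-3`, `max_n_fraction = 0.1`.
#'   In grouped mode `batch_size` counts regions, not windows.
#' @param seed Integer seed governing initialisation, shuffling and
#'   dropout; the same seed and data give identical parameters.
#' @param groups Optional vector (same length as `train_windows`) of
#'   parent-region identifiers enabling the multiple-instance objective.
#' @return An object of class `window_scorer` with the trained parameters,
#'   configuration, batch-norm state and per-epoch `loss_log`.
#' @export
train_window_scorer <- function(train_windows, labels, hyperparams = list(),
                                seed = 1L, groups = NULL) {
  cfg <- scorer_config(hyperparams)
  if (length(train_windows) != length(labels))
    stop("shape error: windows and labels differ in length")
  if (!is.null(groups) && length(groups) != length(train_windows))
    stop("shape error: groups and windows differ in length")
  keep <- n_fraction(train_windows) <= cfg$max_n_fraction
  train_windows <- train_windows[keep]
  labels <- as.numeric(labels[keep])
  if (!is.null(groups)) groups <- groups[keep]
  if (length(train_windows) > 0 && length(unique(labels)) < 2L &&
      cfg$epochs > 0L)
    stop("degenerate-training error: labels contain a single class")
  set.seed(as.integer(seed))
  params <- new_scorer_params(cfg)
  bn_state <- list(mean = rep(0, 2 * cfg$hidden),
                   var = rep(1, 2 * cfg$hidden))
  opt <- adam_init(params)
  loss_log <- numeric(0)
  if (cfg$epochs > 0L) {
    packed <- pack_windows(train_windows, cfg$k)
    if (is.null(groups)) {
      unit_idx <- as.list(seq_len(nrow(packed$mat)))
      unit_y <- labels
    } else {
      gid <- factor(groups, levels = unique(groups))
      unit_idx <- split(seq_len(nrow(packed$mat)), gid)
      unit_y <- vapply(unit_idx, function(ii) labels[ii[1]], numeric(1))
    }
    for (epoch in seq_len(cfg$epochs)) {
      batches <- make_batches(length(unit_idx), cfg$batch_size)
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        units <- batches[[bi]]
        idx <- unlist(unit_idx[units], use.names = FALSE)
        mat <- packed$mat[idx, , drop = FALSE]
        lens <- packed$lens[idx]
        fw <- scorer_forward(params, cfg, mat, lens, bn_state,
                             training = TRUE)
        bn_state <- fw$bn_state
        if (is.null(groups)) {
          y <- unit_y[units]
          losses[bi] <- bce_loss(fw$p, y)
          dlogit <- (fw$p - y) / length(y)
        } else {
          # multiple-instance: region logit = smoothed max (log-mean-exp
          # at temperature mil_temp) of its window logits.  Early in
          # training this behaves like mean pooling, so the shared
          # discriminative window accumulates gradient across regions;
          # as scores separate it anneals toward the max.
          sizes <- lengths(unit_idx[units])
          gfac <- rep(seq_along(units), sizes)
          Tm <- cfg$mil_temp
          y <- unit_y[units]
          dlogit <- numeric(length(idx))
          q <- numeric(length(units))
          for (u in seq_along(units)) {
            ii <- which(gfac == u)
            zg <- fw$z[ii]
            mz <- max(zg)
            e <- exp((zg - mz) / Tm)
            zeta <- mz + Tm * (log(sum(e)) - log(length(zg)))
            q[u] <- sigmoid(zeta)
            dlogit[ii] <- (q[u] - y[u]) * (e / sum(e)) / length(units)
          }
          losses[bi] <- bce_loss(q, y)
        }
        grads <- scorer_backward(params, cfg, fw, dlogit)
        grads <- clip_gradients(grads, cfg$clip_norm)
        st <- adam_step(params, grads, opt, lr = cfg$lr)
        params <- st$params
        opt <- st$state
        params$E[nrow(params$E), ] <- 0   # keep the pad embedding at zero
      }
      loss_log <- c(loss_log, mean(losses))
    }
    if (isTRUE(cfg$head_refit)) {
      # The head (dense + sigmoid on the pooled summary) is a convex
      # logistic problem given the encoder; fit it to convergence.
      tmp <- structure(
        list(params = params, cfg = cfg, bn_state = bn_state,
             trained = TRUE),
        class = "window_scorer")
      S <- scorer_infer(tmp, train_windows)$S
      beta <- ridge_logistic(S, labels)
      params$head.b <- beta[1]
      params$head.W <- matrix(beta[-1], ncol = 1L)
    }
  }
  structure(
    list(params = params, cfg = cfg, bn_state = bn_state,
         loss_log = loss_log, trained = cfg$epochs > 0L, seed = seed),
    class = "window_scorer")
}

#' @export
print.window_scorer <- function(x, ...) {
  cat(sprintf(
    "window_scorer: k=%d, embed_dim=%d, hidden=%d x %d BiLSTM layers%s\n",
    x$cfg$k, x$cfg$embed_dim, x$cfg$hidden, x$cfg$layers,
    if (x$trained)
      sprintf(", trained %d epochs (final loss %.4f)",
              length(x$loss_log), utils::tail(x$loss_log, 1))
    else " (untrained)"))
  invisible(x)
}

# Reverse each row of an id matrix within its valid length (pads stay).
reverse_ids <- function(mat, lens) {
  out <- mat
  for (i in seq_len(nrow(mat))) {
    l <- lens[i]
    if (l > 1L) out[i, 1:l] <- mat[i, l:1]
  }
  out
}

# Single-layer inference without output reversal: the mean/max time
# pooling is permutation-invariant within each row's valid length, so
# the backward direction can be pooled directly on the reversed-input
# pass.  Exactly equivalent to the generic path for layers == 1.
scorer_infer_fast1 <- function(params, cfg, mat, lens) {
  N <- nrow(mat); T_ <- ncol(mat)
  d <- cfg$embed_dim
  X <- array(params$E[mat, ], c(N, T_, d))
  fwd <- lstm_forward(X, lens, layer_par(params, 1L, "f"),
                      want_cache = FALSE)
  Xr <- array(params$E[reverse_ids(mat, lens), ], c(N, T_, d))
  bwd <- lstm_forward(Xr, lens, layer_par(params, 1L, "b"),
                      want_cache = FALSE)
  S <- cbind(time_max_pool(fwd$H, lens)$S,
             time_max_pool(bwd$H, lens)$S)
  z <- dense_forward(S, params$head.W, params$head.b)
  list(p = as.vector(sigmoid(z)), S = S)
}

# Batched inference: probabilities and summary features for raw windows.
scorer_infer <- function(scorer, windows, chunk = 256L) {
  packed <- pack_windows(windows, scorer$cfg$k)
  n <- nrow(packed$mat)
  p <- numeric(n)
  S <- matrix(0, n, 2L * scorer$cfg$hidden)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- if (scorer$cfg$layers == 1L)
      scorer_infer_fast1(scorer$params, scorer$cfg,
                         packed$mat[idx, , drop = FALSE],
                         packed$lens[idx])
    else
      scorer_forward(scorer$params, scorer$cfg,
                     packed$mat[idx, , drop = FALSE],
                     packed$lens[idx], scorer$bn_state,
                     training = FALSE)
    p[idx] <- fw$p
    S[idx, ] <- fw$S
  }
  list(p = p, S = S)
}

#' Score every window of the eRNA records
#'
#' Splits each eRNA record of the dataset into its layout windows, scores
#' every window with the scorer, and returns the mean score per window
#' index over the eRNA records -- the per-window score curve from which
#' the optimal sequence window is chosen.
#'
#' @param scorer A [train_window_scorer()] result.
#' @param dataset A dataset data.frame with `sequence` and `label`.
#' @param layout The [build_layout()] used for these regions.
#' @return Numeric vector of length `nrow(layout$windows)` of mean scores
#'   (names are window indices).
#' @export
score_windows <- function(scorer, dataset, layout) {
  stopifnot(inherits(scorer, "window_scorer"),
            inherits(layout, "window_layout"))
  seqs <- dataset$sequence[dataset$label == "eRNA"]
  if (length(seqs) == 0L) stop("score_windows: no eRNA records")
  W <- nrow(layout$windows)
  windows <- unlist(lapply(seqs, region_windows, layout = layout),
                    use.names = FALSE)
  p <- scorer_infer(scorer, windows)$p
  scores <- rowMeans(matrix(p, W, length(seqs)))
  stats::setNames(scores, layout$windows$index)
}

#' Select the optimal sequence window
#'
#' Argmax of the per-window scores; ties are broken toward the window
#' nearest the center, then toward the smaller index.
#'
#' @param per_window_scores Numeric vector of scores (window order).
#' @param center_index Center window index; defaults to the middle of the
#'   vector (layouts are mirror-symmetric so the count is odd).
#' @return The selected window index (integer).
#' @export
select_optimal_sequence_window <- function(per_window_scores,
                                           center_index = NULL) {
  n <- length(per_window_scores)
  if (n == 0L) stop("input error: empty score list")
  if (is.null(center_index)) center_index <- (n + 1L) %/% 2L
  best <- which(unname(per_window_scores) == max(per_window_scores))
  as.integer(best[order(abs(best - center_index), best)][1L])
}

#' Extract the sequence feature from the optimal window
#'
#' The fixed-width sequence representation of a record is the scorer's
#' pooled bidirectional summary (width `2 * hidden`) for the record's optimal
#' window, computed with dropout disabled.
#'
#' @param scorer A trained [train_window_scorer()] result.
#' @param record A single dataset row (or any list with `$sequence`).
#' @param layout The [build_layout()] for these regions.
#' @param optimal_index Window index selected by
#'   [select_optimal_sequence_window()].
#' @return A list of class `sequence_feature` with `vector` (length `2H`)
#'   and `window_index`.
#' @export
extract_sequence_feature <- function(scorer, record, layout, optimal_index) {
  v <- extract_sequence_features(scorer, record$sequence, layout,
                                 optimal_index)
  structure(list(vector = v[1, ], window_index = as.integer(optimal_index)),
            class = "sequence_feature")
}

#' Extract sequence features for many records
#'
#' Vectorised form of [extract_sequence_feature()].
#'
#' @param scorer A trained window scorer.
#' @param sequences Character vector of full region sequences.
#' @param layout The window layout.
#' @param optimal_index The selected window index.
#' @return Numeric matrix `length(sequences) x 2H`.
#' @export
extract_sequence_features <- function(scorer, sequences, layout,
                                      optimal_index) {
  stopifnot(inherits(scorer, "window_scorer"))
  if (!isTRUE(scorer$trained))
    stop("state error: scorer is untrained")
  w <- layout$windows[as.integer(optimal_index), ]
  if (is.na(w$start))
    stop("index error: optimal_index outside the layout")
  windows <- substring(sequences, w$start + 1L, w$end)
  scorer_infer(scorer, windows)$S
}
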