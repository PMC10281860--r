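# The feature-fusion classifier: two ReLU dense layers over the 6D
# histone row (5 marks + RE flag), dropout, batch normalization, then
# concatenation with the sequence feature and a dense + sigmoid head
# giving P(eRNA).  Trained with Adam on binary cross-entropy;
# hyperparameters selected by stratified k-fold cross-validation over a
# grid, with the final model retrained on the full training set.  A
# sequence-only variant (same trunk applied to the sequence feature, no
# histone input) supports the ablation protocol.

fusion_defaults <- function() {
  list(hidden = 16L, epochs = 20L, batch_size = 16L, lr = 1e-3,
       dropout = 0.3, variant = "fused")
}

fusion_config <- function(hyperparams = list()) {
  cfg <- utils::modifyList(fusion_defaults(), hyperparams)
  stopifnot(cfg$hidden > 0, cfg$epochs >= 0, cfg$batch_size > 0,
            cfg$lr >= 0, cfg$dropout >= 0, cfg$dropout < 1,
            cfg$variant %in% c("fused", "sequence_only"))
  cfg
}

new_fusion_params <- function(cfg, input_dim, d_seq) {
  h <- cfg$hidden
  concat_dim <- h + if (cfg$variant == "fused") d_seq else 0L
  list(W1 = glorot(input_dim, h), b1 = rep(0, h),
       W2 = glorot(h, h), b2 = rep(0, h),
       bn.gamma = rep(1, h), bn.beta = rep(0, h),
       out.W = glorot(concat_dim, 1L), out.b = 0)
}

# Forward pass; returns probabilities plus caches for backprop.
fusion_pass <- function(params, cfg, X, S, bn_state, training) {
  z1 <- dense_forward(X, params$W1, params$b1)
  a1 <- relu(z1)
  z2 <- dense_forward(a1, params$W2, params$b2)
  a2 <- relu(z2)
  dp <- dropout_forward(a2, cfg$dropout, training)
  bn <- bn_forward(dp$out, params$bn.gamma, params$bn.beta,
                   bn_state$mean, bn_state$var, training)
  bn_state$mean <- bn$running_mean
  bn_state$var <- bn$running_var
  concat <- if (cfg$variant == "fused") cbind(bn$out, S) else bn$out
  z <- dense_forward(concat, params$out.W, params$out.b)
  list(p = as.vector(sigmoid(z)),
       cache = list(X = X, z1 = z1, a1 = a1, z2 = z2, a2 = a2,
                    drop_mask = dp$mask, bn_cache = bn$cache,
                    concat = concat),
       bn_state = bn_state)
}

fusion_grads <- function(params, cfg, fw, dlogit) {
  ca <- fw$cache
  N <- length(dlogit)
  h <- length(params$b1)
  dz <- matrix(dlogit, N, 1)
  dd <- dense_backward(dz, ca$concat, params$out.W)
  grads <- list(out.W = dd$dW, out.b = dd$db)
  dbn_out <- dd$dX[, seq_len(h), drop = FALSE]
  bnb <- bn_backward(dbn_out, ca$bn_cache)
  grads$bn.gamma <- bnb$dgamma
  grads$bn.beta <- bnb$dbeta
  da2 <- dropout_backward(bnb$dX, ca$drop_mask)
  dz2 <- da2 * (ca$z2 > 0)
  d2 <- dense_backward(dz2, ca$a1, params$W2)
  grads$W2 <- d2$dW
  grads$b2 <- d2$db
  dz1 <- d2$dX * (ca$z1 > 0)
  d1 <- dense_backward(dz1, ca$X, params$W1)
  grads$W1 <- d1$dW
  grads$b1 <- d1$db
  grads
}

as_feature_matrix <- function(x, what) {
  if (is.null(x)) return(NULL)
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x)) x <- as.matrix(x)
  if (any(!is.finite(x))) stop(sprintf("%s must be finite", what))
  dimnames(x) <- NULL   # keep names out of gradient/parameter arithmetic
  x
}

#' Forward pass of the fusion model
#'
#' Computes P(eRNA) for one or more records: two ReLU dense layers over
#' the 6D histone row, batch normalization (inference statistics),
#' concatenation with the sequence feature, dense + sigmoid head.
#'
#' @param model A [train_fusion()] result (or parameter list of the same
#'   shape).
#' @param six_d Numeric vector of length 6 or matrix `N x 6` (ignored by
#'   the sequence-only variant).
#' @param sequence_feature Numeric vector of width `D_seq` or matrix
#'   `N x D_seq` (ignored by... required by the fused variant).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
fusion_forward <- function(model, six_d, sequence_feature = NULL) {
  cfg <- model$cfg
  X <- if (cfg$variant == "fused")
    as_feature_matrix(six_d, "six_d") else
      as_feature_matrix(sequence_feature, "sequence_feature")
  S <- as_feature_matrix(sequence_feature, "sequence_feature")
  if (cfg$variant == "fused") {
    if (ncol(X) != nrow(model$params$W1))
      stop(sprintf("shape error: six_d has width %d, expected %d",
                   ncol(X), nrow(model$params$W1)))
    if (ncol(S) != model$d_seq)
      stop(sprintf("shape error: sequence feature width %d, expected %d",
                   ncol(S), model$d_seq))
  }
  fusion_pass(model$params, cfg, X, S, model$bn_state,
              training = FALSE)$p
}

#' Train the fusion classifier
#'
#' Adam on binary cross-entropy over mini-batches; per-epoch mean loss is
#' logged.  With a fixed seed, repeated training yields identical
#' parameters.
#'
#' @param six_d 6D histone matrix, `N x 6` (ignored with
#'   `variant = "sequence_only"`).
#' @param sequence_features `N x D_seq` matrix of sequence features.
#' @param labels 0/1 vector (eRNA = 1).
#' @param hyperparams Named list overriding `hidden = 16`, `epochs = 20`,
#'   `batch_size = 16`, `lr = 1e-3`, `dropout = 0.3`,
#'   `variant = "fused"`.
#' @param seed Integer seed.
#' @return An object of class `fusion_model`.
#' @export
train_fusion <- function(six_d, sequence_features, labels,
                         hyperparams = list(), seed = 1L) {
  cfg <- fusion_config(hyperparams)
  S <- as_feature_matrix(sequence_features, "sequence_features")
  X <- if (cfg$variant == "fused")
    as_feature_matrix(six_d, "six_d") else S
  y <- as.numeric(labels)
  if (length(unique(y)) < 2L)
    stop("degenerate-training error: labels contain a single class")
  if (nrow(X) != length(y))
    stop("shape error: feature rows and labels differ in length")
  set.seed(as.integer(seed))
  params <- new_fusion_params(cfg, ncol(X),
                              if (is.null(S)) 0L else ncol(S))
  bn_state <- list(mean = rep(0, cfg$hidden), var = rep(1, cfg$hidden))
  opt <- adam_init(params)
  loss_log <- numeric(0)
  for (epoch in seq_len(cfg$epochs)) {
    batches <- make_batches(nrow(X), cfg$batch_size)
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      idx <- batches[[bi]]
      fw <- fusion_pass(params, cfg, X[idx, , drop = FALSE],
                        S[idx, , drop = FALSE], bn_state,
                        training = TRUE)
      bn_state <- fw$bn_state
      losses[bi] <- bce_loss(fw$p, y[idx])
      dlogit <- (fw$p - y[idx]) / length(idx)
      grads <- fusion_grads(params, cfg, fw, dlogit)
      st <- adam_step(params, grads, opt, lr = cfg$lr)
      params <- st$params
      opt <- st$state
    }
    loss_log <- c(loss_log, mean(losses))
  }
  structure(
    list(params = params, cfg = cfg, bn_state = bn_state,
         d_seq = if (is.null(S)) 0L else ncol(S),
         loss_log = loss_log, seed = seed),
    class = "fusion_model")
}

#' @export
print.fusion_model <- function(x, ...) {
  cat(sprintf(
    "fusion_model (%s): hidden=%d, D_seq=%d%s\n",
    x$cfg$variant, x$cfg$hidden, x$d_seq,
    if (length(x$loss_log))
      sprintf(", %d epochs (final loss %.4f)",
              length(x$loss_log), utils::tail(x$loss_log, 1)) else ""))
  invisible(x)
}

#' Predict eRNA probabilities
#'
#' @param object A [train_fusion()] model.
#' @param six_d 6D histone matrix.
#' @param sequence_features Sequence feature matrix.
#' @param threshold Classification threshold (default 0.5; a probability
#'   at the threshold is called positive).
#' @param ... Unused.
#' @return Data.frame with `prob` and `label_pred` (1 = eRNA).
#' @export
predict.fusion_model <- function(object, six_d, sequence_features,
                                 threshold = 0.5, ...) {
  p <- fusion_forward(object, six_d, sequence_features)
  data.frame(prob = p, label_pred = as.integer(p >= threshold))
}

#' Stratified cross-validation folds
#'
#' Equal-size, disjoint folds stratified by label; their union is the
#' full index set.
#'
#' @param labels 0/1 (or factor) vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per record.
#' @export
make_cv_folds <- function(labels, k, seed = 1L) {
  if (k < 2L) stop("config error: folds must be >= 2")
  n <- length(labels)
  if (n < k) stop("config error: fewer records than folds")
  set.seed(as.integer(seed))
  fold <- integer(n)
  for (lab in unique(labels)) {
    idx <- sample(which(labels == lab))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Hyperparameter selection by k-fold cross-validation and grid search
#'
#' For every grid point, trains on k-1 folds and evaluates on the held
#' out fold; the mean validation metric over folds scores the point and
#' the argmax is selected.  The final model is then retrained on the full
#' training set with the winning hyperparameters.
#'
#' @param six_d 6D histone matrix.
#' @param sequence_features Sequence feature matrix.
#' @param labels 0/1 vector.
#' @param grid Either a data.frame (one row per grid point) or a named
#'   list of value vectors expanded by [expand.grid()]; columns must be
#'   [train_fusion()] hyperparameter names.
#' @param folds Number of CV folds (default 5).
#' @param metric `"ACC"` (default) or `"AUC"`.
#' @param seed Integer seed.
#' @param variant Model variant passed through to [train_fusion()].
#' @return A list with `best` (winning hyperparameters), `cv_table`
#'   (grid with mean validation metric per point) and `model` (the final
#'   model retrained on all data).
#' @export
grid_search_cv <- function(six_d, sequence_features, labels, grid,
                           folds = 5L, metric = c("ACC", "AUC"),
                           seed = 1L, variant = "fused") {
  metric <- match.arg(metric)
  if (is.data.frame(grid)) gridf <- grid
  else if (is.list(grid) && length(grid) > 0)
    gridf <- expand.grid(grid, stringsAsFactors = FALSE)
  else stop("config error: grid must be a nonempty list or data.frame")
  if (nrow(gridf) == 0L) stop("config error: empty grid")
  valid <- c("hidden", "epochs", "batch_size", "lr", "dropout")
  bad <- setdiff(names(gridf), valid)
  if (length(bad) > 0L)
    stop(sprintf("config error: unknown grid hyperparameter '%s'", bad[1]))
  y <- as.numeric(labels)
  fold <- make_cv_folds(y, folds, seed)
  S <- as_feature_matrix(sequence_features, "sequence_features")
  X6 <- if (variant == "fused") as_feature_matrix(six_d, "six_d") else NULL
  score <- numeric(nrow(gridf))
  for (g in seq_len(nrow(gridf))) {
    hp <- c(as.list(gridf[g, , drop = FALSE]), variant = variant)
    vals <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      model <- train_fusion(
        if (is.null(X6)) NULL else X6[tr, , drop = FALSE],
        S[tr, , drop = FALSE], y[tr], hp,
        seed = seed + f)
      p <- fusion_forward(model,
                          if (is.null(X6)) NULL else
                            X6[!tr, , drop = FALSE],
                          S[!tr, , drop = FALSE])
      vals[f] <- if (metric == "ACC") mean((p >= 0.5) == y[!tr])
                 else roc_auc(y[!tr], p)$auc
    }
    score[g] <- mean(vals)
  }
  best_idx <- which.max(score)
  best <- c(as.list(gridf[best_idx, , drop = FALSE]), variant = variant)
  cv_table <- cbind(gridf, cv_metric = score)
  model <- train_fusion(six_d, sequence_features, y, best, seed = seed)
  list(best = best, cv_table = cv_table, model = model, metric = metric)
}
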