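make_fusion_data <- function(n, d_seq = 4, seed = 1, seq_signal = FALSE) {
  set.seed(seed)
  y <- rep(c(1, 0), n / 2)
  X6 <- cbind(matrix(runif(n * 4, 0, 0.3), n) + y * 0.5,
              runif(n, 0, 0.5), y)
  S <- matrix(rnorm(n * d_seq), n)
  if (seq_signal) S[, 1] <- S[, 1] + 2 * y
  list(X6 = X6, S = S, y = y)
}

test_that("a zero network outputs probability one half", {
  cfg <- ernafuse:::fusion_config(list(hidden = 2, dropout = 0))
  params <- list(W1 = matrix(0, 6, 2), b1 = rep(0, 2),
                 W2 = matrix(0, 2, 2), b2 = rep(0, 2),
                 bn.gamma = rep(1, 2), bn.beta = rep(0, 2),
                 out.W = matrix(0, 6, 1), out.b = 0)
  model <- structure(list(params = params, cfg = cfg,
                          bn_state = list(mean = rep(0, 2),
                                          var = rep(1, 2)),
                          d_seq = 4L),
                     class = "fusion_model")
  p <- fusion_forward(model, rep(0.3, 6), rep(0.1, 4))
  expect_equal(p, 0.5)
})

test_that("a hand-set two-unit network matches pencil-and-paper", {
  cfg <- ernafuse:::fusion_config(list(hidden = 2, dropout = 0))
  params <- list(W1 = matrix(c(1, 0, 0, 0, 0, 0,
                               0, 1, 0, 0, 0, 0), 6, 2), b1 = c(0.5, -2),
                 W2 = diag(2), b2 = c(0, 0),
                 bn.gamma = rep(1, 2), bn.beta = rep(0, 2),
                 out.W = matrix(c(1, 1, 2), 3, 1), out.b = -1)
  model <- structure(list(params = params, cfg = cfg,
                          bn_state = list(mean = rep(0, 2),
                                          var = rep(1, 2)),
                          d_seq = 1L),
                     class = "fusion_model")
  x <- c(1, -3, 0, 0, 0, 0)
  s <- 0.25
  # a1 = relu(c(1*1+0.5, 1*(-3)-2)) = c(1.5, 0); a2 = relu(a1) = c(1.5, 0)
  # bn(inference, mean 0, var 1, eps 1e-5): c(1.5/sqrt(1+1e-5), 0)
  # logit = 1.5/sqrt(1+1e-5) + 1*0 + 2*0.25 - 1; p = sigmoid(logit)
  expect_equal(fusion_forward(model, x, s),
               1 / (1 + exp(-(1.5 / sqrt(1 + 1e-5) + 0.5 - 1))),
               tolerance = 1e-10)
  # ReLU zeroes negative pre-activations
  expect_equal(ernafuse:::relu(c(-3, 0, 2)), c(0, 0, 2))
})

test_that("binary cross-entropy matches closed forms and is nonnegative", {
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2))
  expect_lt(bce_loss(1 - 1e-7, 1), 1e-6)
  set.seed(2)
  p <- runif(100); y <- rbinom(100, 1, 0.5)
  expect_gte(bce_loss(p, y), 0)
  expect_error(bce_loss(c(0.5), c(1, 0)), "shape error")
})

test_that("fusion gradients match finite differences on a 2-unit net", {
  cfg <- ernafuse:::fusion_config(list(hidden = 2, dropout = 0))
  set.seed(7)
  params <- ernafuse:::new_fusion_params(cfg, 6L, 3L)
  # nonzero biases keep every ReLU unit active for part of the batch, so
  # no batch-norm column degenerates and finite differences stay valid
  params$b1 <- c(0.4, 0.3)
  params$b2 <- c(0.35, 0.25)
  bn_state <- list(mean = rep(0, 2), var = rep(1, 2))
  X <- matrix(rnorm(5 * 6), 5)
  S <- matrix(rnorm(5 * 3), 5)
  y <- c(1, 0, 1, 1, 0)
  loss_fn <- function(p) {
    fw <- ernafuse:::fusion_pass(p, cfg, X, S, bn_state, TRUE)
    bce_loss(fw$p, y)
  }
  fw <- ernafuse:::fusion_pass(params, cfg, X, S, bn_state, TRUE)
  grads <- ernafuse:::fusion_grads(params, cfg, fw, (fw$p - y) / 5)
  eps <- 1e-6
  for (nm in names(params)) {
    p0 <- params[[nm]]
    g_num <- array(0, dim(as.array(p0)))
    for (j in seq_along(p0)) {
      pp <- params; pp[[nm]][j] <- p0[j] + eps
      pm <- params; pm[[nm]][j] <- p0[j] - eps
      g_num[j] <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    }
    expect_lt(max(abs(as.array(grads[[nm]]) - g_num)), 1e-4)
  }
})

test_that("training drives the loss down on separable data", {
  d <- make_fusion_data(80, seed = 3)
  model <- train_fusion(d$X6, d$S, d$y,
                        list(hidden = 8, epochs = 40, batch_size = 16,
                             lr = 5e-3, dropout = 0), seed = 1)
  expect_lt(tail(model$loss_log, 1), 0.1)
  # zero learning rate leaves parameters at initialisation
  m0 <- train_fusion(d$X6, d$S, d$y,
                     list(hidden = 8, epochs = 3, lr = 0, dropout = 0),
                     seed = 5)
  set.seed(5)
  init <- ernafuse:::new_fusion_params(
    ernafuse:::fusion_config(list(hidden = 8, epochs = 3, lr = 0,
                                  dropout = 0)), 6L, 4L)
  expect_identical(m0$params$W1, init$W1)
  expect_identical(m0$params$out.W, init$out.W)
  # determinism
  m1 <- train_fusion(d$X6, d$S, d$y, list(hidden = 4, epochs = 5), seed = 2)
  m2 <- train_fusion(d$X6, d$S, d$y, list(hidden = 4, epochs = 5), seed = 2)
  expect_identical(m1$params, m2$params)
  expect_error(train_fusion(d$X6, d$S, rep(1, 80), list()),
               "degenerate-training")
})

test_that("prediction returns calibrated shapes and bounds", {
  d <- make_fusion_data(60, seed = 4)
  model <- train_fusion(d$X6, d$S, d$y,
                        list(hidden = 16, epochs = 80, batch_size = 16,
                             lr = 5e-3, dropout = 0), seed = 1)
  pred <- predict(model, d$X6, d$S)
  expect_equal(nrow(pred), 60L)
  expect_true(all(pred$prob > 0 & pred$prob < 1))
  expect_true(all(pred$label_pred %in% 0:1))
  # an overfit model memorises its training positives
  expect_gt(mean(pred$prob[d$y == 1]), 0.9)
})

test_that("inference is batch-size invariant", {
  d <- make_fusion_data(24, seed = 5)
  model <- train_fusion(d$X6, d$S, d$y,
                        list(hidden = 4, epochs = 5, dropout = 0.4),
                        seed = 3)
  p_all <- fusion_forward(model, d$X6, d$S)
  p_one <- vapply(seq_len(24), function(i)
    fusion_forward(model, d$X6[i, ], d$S[i, ]), numeric(1))
  expect_equal(p_all, p_one, tolerance = 1e-6)
})

test_that("CV folds are an exact stratified partition", {
  y <- rep(c(1, 0), 50)
  fold <- make_cv_folds(y, 5, seed = 1)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(as.vector(table(fold)), rep(20L, 5))
  for (f in 1:5) expect_equal(sum(y[fold == f]), 10L)
  expect_error(make_cv_folds(y, 1), "config error")
  expect_error(make_cv_folds(y[1:3], 5), "config error")
})

test_that("grid search returns the singleton and finds planted optimum", {
  d <- make_fusion_data(60, seed = 6)
  g1 <- grid_search_cv(d$X6, d$S, d$y,
                       list(hidden = 4L, epochs = 5L), folds = 3,
                       seed = 1)
  expect_equal(g1$best$hidden, 4L)
  expect_s3_class(g1$model, "fusion_model")
  expect_equal(nrow(g1$cv_table), 1L)
  # a grid point with zero epochs cannot beat a trained one
  g2 <- grid_search_cv(d$X6, d$S, d$y,
                       data.frame(hidden = c(8L, 8L),
                                  epochs = c(0L, 30L)),
                       folds = 3, seed = 1)
  expect_equal(g2$best$epochs, 30L)
  expect_error(grid_search_cv(d$X6, d$S, d$y,
                              list(bogus = 1), folds = 3),
               "config error")
})

test_that("sequence-only variant ignores histone input", {
  d <- make_fusion_data(60, seed = 7, seq_signal = TRUE)
  m <- train_fusion(NULL, d$S, d$y,
                    list(hidden = 8, epochs = 30, batch_size = 16,
                         dropout = 0, variant = "sequence_only"),
                    seed = 1)
  p <- fusion_forward(m, NULL, d$S)
  expect_gt(oracle_auc(d$y, p), 0.9)
})
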