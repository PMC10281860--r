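test_that("k-mer tokenization enumerates overlapping words", {
  tk <- tokenize_kmers("ACGT", 2)
  expect_equal(tk$tokens, c("AC", "CG", "GT"))
  long <- tokenize_kmers(random_dna_str(301, rng_seed = 1), 2)
  expect_length(long$tokens, 300L)
  expect_error(tokenize_kmers("A", 2), "length error")
  # token-count identity on random windows
  set.seed(2)
  for (i in 1:50) {
    L <- sample(5:400, 1)
    k <- sample(1:4, 1)
    expect_length(tokenize_kmers(random_dna_str(L), k)$tokens, L - k + 1L)
  }
})

test_that("the 2-mer vocabulary has exactly 16 tokens", {
  v <- kmer_vocab(2)
  expect_length(v, 16L)
  expect_length(unique(v), 16L)
  expect_true(all(nchar(v) == 2))
  expect_length(kmer_vocab(3), 64L)
})

test_that("fast integer tokenization matches the character tokenizer", {
  set.seed(3)
  for (k in 1:3) {
    s <- random_dna_str(100)
    ids <- ernafuse:::kmer_ids(s, k)
    chars <- tokenize_kmers(s, k)$tokens
    expect_equal(kmer_vocab(k)[ids], chars)
  }
  # ambiguous bases map to the pad id 0
  ids_n <- ernafuse:::kmer_ids("ACNGT", 2)
  expect_equal(ids_n == 0L, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("embedding backend looks up token vectors", {
  be <- embedding_backend(k = 2, dim = 8, seed = 1)
  m <- embed(tokenize_kmers("ACGT", 2), be)
  expect_equal(dim(m), c(3L, 8L))
  m2 <- embed(c("AC", "CG", "GT"), be)
  expect_identical(m, m2)
  expect_error(embed(c("AC", "NX"), be), "vocabulary error")
  # identity-initialised lookup maps token i to unit vector e_i
  id <- embedding_backend(k = 2, dim = 16, init = "identity")
  e <- embed("AA", id)
  expect_equal(as.vector(e), c(1, rep(0, 15)))
  expect_equal(diag(id$E), rep(1, 16))
})

test_that("scorer gradients match finite differences end to end", {
  cfg <- ernafuse:::scorer_config(list(k = 2, embed_dim = 3, hidden = 2,
                                       layers = 2, dropout = 0))
  set.seed(42)
  params <- ernafuse:::new_scorer_params(cfg)
  bn_state <- list(mean = rep(0, 4), var = rep(1, 4))
  mat <- rbind(c(3, 5, 1, 16, 2, 7), c(8, 9, 10, 11, 12, 13),
               c(1, 2, 3, 4, 17, 17), c(14, 15, 16, 1, 2, 17))
  lens <- c(6L, 6L, 4L, 5L)
  y <- c(1, 0, 1, 0)
  loss_fn <- function(p) {
    fw <- ernafuse:::scorer_forward(p, cfg, mat, lens, bn_state, TRUE)
    bce_loss(fw$p, y)
  }
  fw <- ernafuse:::scorer_forward(params, cfg, mat, lens, bn_state, TRUE)
  grads <- ernafuse:::scorer_backward(params, cfg, fw, (fw$p - y) / 4)
  eps <- 1e-6
  for (nm in names(params)) {
    p0 <- params[[nm]]
    g_num <- array(0, dim(as.array(p0)))
    for (j in seq_along(p0)) {
      pp <- params; pp[[nm]][j] <- p0[j] + eps
      pm <- params; pm[[nm]][j] <- p0[j] - eps
      g_num[j] <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
    }
    if (nm == "E") g_num[nrow(g_num), ] <- 0   # pad row is pinned
    expect_lt(max(abs(as.array(grads[[nm]]) - g_num)), 1e-6)
  }
})

test_that("training learns a planted motif and is seed-deterministic", {
  d <- motif_windows(240, 81, "TGACGTCATCGATTGACGCA", seed = 7)
  hp <- list(hidden = 8, embed_dim = 8, layers = 1, epochs = 4,
             batch_size = 32, lr = 2e-2, dropout = 0.1)
  tr <- 1:160; ho <- 161:240
  sc <- train_window_scorer(d$windows[tr], d$labels[tr], hp, seed = 5)
  p <- ernafuse:::scorer_infer(sc, d$windows[ho])$p
  expect_gt(mean((p >= 0.5) == d$labels[ho]), 0.9)
  expect_true(all(p > 0 & p < 1))
  # same seed and data give identical parameters
  sc2 <- train_window_scorer(d$windows[tr], d$labels[tr], hp, seed = 5)
  expect_identical(sc$params, sc2$params)
  # single-class labels are refused
  expect_error(
    train_window_scorer(d$windows[1:4], rep(1, 4), hp, seed = 1),
    "degenerate-training")
})

test_that("an untrained scorer scores near 0.5 on average", {
  d <- motif_windows(60, 61, "TGACGTCA", seed = 2)
  sc0 <- train_window_scorer(d$windows, d$labels,
                             list(hidden = 8, embed_dim = 8, layers = 1,
                                  epochs = 0), seed = 1)
  expect_false(sc0$trained)
  sc0$trained <- TRUE   # bypass the state guard to inspect raw scores
  p <- ernafuse:::scorer_infer(sc0, d$windows)$p
  expect_lt(abs(mean(p) - 0.5), 0.15)
})

test_that("score curve peaks at the window carrying planted signal", {
  layout <- build_layout(501, 100)
  expect_equal(layout$center_index, 3L)
  set.seed(11)
  n <- 120
  motif <- "TGACGTCATCGATTGACGCA"
  cw <- layout$windows[3, ]
  seqs <- vapply(seq_len(n), function(i) random_dna_str(501), character(1))
  labs <- rep(c("eRNA", "NE"), each = n / 2)
  for (i in which(labs == "eRNA")) {
    pos <- cw$start + sample.int(cw$end - cw$start - nchar(motif), 1)
    substr(seqs[i], pos + 1, pos + nchar(motif)) <- motif
  }
  ds <- data.frame(name = sprintf("r%d", 1:n), label = labs,
                   sequence = seqs)
  w <- unlist(lapply(seqs, ernafuse:::region_windows, layout = layout))
  y <- rep(as.numeric(labs == "eRNA"), each = nrow(layout$windows))
  sc <- train_window_scorer(w, y,
                            list(hidden = 8, embed_dim = 8, layers = 1,
                                 epochs = 2, batch_size = 64, lr = 1e-3,
                                 dropout = 0.1), seed = 3)
  curve <- score_windows(sc, ds, layout)
  expect_length(curve, 5L)
  expect_true(all(curve > 0 & curve < 1))
  expect_equal(select_optimal_sequence_window(curve, 3L), 3L)
})

test_that("optimal-window selection breaks ties toward the center", {
  expect_equal(select_optimal_sequence_window(c(.1, .2, .9, .2, .1)), 3L)
  expect_equal(select_optimal_sequence_window(rep(0.5, 21)), 11L)
  # equidistant maxima resolve to the smaller index
  s <- rep(0.1, 5); s[2] <- 0.8; s[4] <- 0.8
  expect_equal(select_optimal_sequence_window(s), 2L)
  scores <- c(.1, .2, .3, .2, .9)
  expect_equal(select_optimal_sequence_window(scores), 5L)
  expect_error(select_optimal_sequence_window(numeric(0)), "input error")
})

test_that("sequence features have width 2H and are deterministic", {
  d <- motif_windows(40, 61, "TGACGTCA", seed = 4)
  layout <- build_layout(181, 60)   # 3 windows, center at index 2
  hp <- list(hidden = 8, embed_dim = 8, layers = 1, epochs = 1,
             batch_size = 16, lr = 1e-3)
  sc <- train_window_scorer(d$windows, d$labels, hp, seed = 2)
  seqs <- c(random_dna_str(181, rng_seed = 1), random_dna_str(181))
  f <- extract_sequence_features(sc, seqs, layout, layout$center_index)
  expect_equal(dim(f), c(2L, 16L))
  expect_true(all(is.finite(f)))
  # identical sequences give identical features
  f2 <- extract_sequence_features(sc, c(seqs[1], seqs[1]), layout,
                                  layout$center_index)
  expect_identical(f2[1, ], f2[2, ])
  # singular form carries the window index
  sf <- extract_sequence_feature(sc, list(sequence = seqs[1]), layout,
                                 layout$center_index)
  expect_s3_class(sf, "sequence_feature")
  expect_length(sf$vector, 16L)
  expect_equal(sf$window_index, layout$center_index)
  # untrained scorer refuses feature extraction
  sc0 <- train_window_scorer(d$windows, d$labels,
                             list(hidden = 8, embed_dim = 8,
                                  layers = 1, epochs = 0), seed = 1)
  expect_error(extract_sequence_features(sc0, seqs, layout, 2),
               "state error")
})

test_that("H = 64 yields feature width 128", {
  cfg <- ernafuse:::scorer_config(list())
  expect_equal(cfg$hidden, 64L)
  set.seed(1)
  params <- ernafuse:::new_scorer_params(cfg)
  expect_equal(dim(params$head.W), c(128L, 1L))
})

test_that("repeated inference is bit-identical with dropout disabled", {
  d <- motif_windows(30, 41, "TGACGTCA", seed = 6)
  sc <- train_window_scorer(d$windows, d$labels,
                            list(hidden = 8, embed_dim = 8, layers = 2,
                                 epochs = 1, batch_size = 16,
                                 dropout = 0.4), seed = 9)
  p1 <- ernafuse:::scorer_infer(sc, d$windows)$p
  p2 <- ernafuse:::scorer_infer(sc, d$windows)$p
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("windows with excess ambiguous bases are excluded from training", {
  d <- motif_windows(40, 50, "TGACGTCA", seed = 8)
  wN <- c(d$windows, paste(rep("N", 50), collapse = ""))
  yN <- c(d$labels, 1)
  expect_silent(
    sc <- train_window_scorer(wN, yN,
                              list(hidden = 4, embed_dim = 4, layers = 1,
                                   epochs = 1, batch_size = 16), seed = 1))
  expect_s3_class(sc, "window_scorer")
})
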