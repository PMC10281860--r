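blob_features <- function(n_high, n_low, seed = 1) {
  set.seed(seed)
  pos_marks <- names(MARK_POLARITY)[MARK_POLARITY == "positive"]
  high <- cbind(matrix(runif(n_high * 4, 0.7, 1.0), n_high),
                runif(n_high, 0, 0.2))
  low <- cbind(matrix(runif(n_low * 4, 0.0, 0.2), n_low),
               runif(n_low, 0.3, 0.7))
  m <- rbind(high, low)
  colnames(m) <- c(pos_marks, "H3K36me3")[c(1:4, 5)]
  colnames(m) <- HISTONE_MARKS
  rownames(m) <- sprintf("r%03d", seq_len(n_high + n_low))
  m
}

test_that("k-means recovers well-separated blobs deterministically", {
  m <- blob_features(20, 20)
  cl <- cluster_sample(m, seed = 3)
  expect_length(unique(cl$cluster), 2L)
  expect_length(unique(cl$cluster[1:20]), 1L)
  expect_length(unique(cl$cluster[21:40]), 1L)
  expect_false(cl$cluster[1] == cl$cluster[40])
  cl2 <- cluster_sample(m, seed = 3)
  expect_identical(cl$cluster, cl2$cluster)
  # two points fall one per cluster
  two <- m[c(1, 40), ]
  expect_setequal(unname(cluster_sample(two, seed = 1)$cluster), 1:2)
  # identical rows cannot be clustered
  same <- m[rep(1, 5), ]
  rownames(same) <- paste0("x", 1:5)
  expect_error(cluster_sample(same, seed = 1), "degenerate-clustering")
})

test_that("candidate-RE cluster is the activating-mark-high cluster", {
  m <- blob_features(15, 25, seed = 2)
  labels <- setNames(rep(c("eRNA", "NE"), c(30, 10)), rownames(m))
  cl <- cluster_sample(m, seed = 1)
  cs <- label_candidate_cluster(cl, labels, "s1")
  expect_s3_class(cs, "candidate_set")
  # the high blob rows 1..15 are all eRNA, hence all candidates
  expect_setequal(cs$candidate_re_names, rownames(m)[1:15])
  # NE members of the high cluster are excluded
  labels2 <- labels
  labels2[rownames(m)[1:5]] <- "NE"
  cs2 <- label_candidate_cluster(cl, labels2, "s1")
  expect_setequal(cs2$candidate_re_names, rownames(m)[6:15])
})

test_that("positive-mark tie breaks by the smaller H3K36me3 centroid", {
  clustering <- list(
    cluster = setNames(c(1L, 2L), c("a", "b")),
    centers = rbind(c(0.5, 0.5, 0.5, 0.5, 0.1),
                    c(0.5, 0.5, 0.5, 0.5, 0.7)))
  colnames(clustering$centers) <- HISTONE_MARKS
  labels <- c(a = "eRNA", b = "eRNA")
  cs <- label_candidate_cluster(clustering, labels, "s")
  expect_equal(cs$candidate_re_names, "a")
})

test_that("voting matches the closed-form even/odd thresholds exactly", {
  for (n in 1:8) {
    for (m in 0:n) {
      labels <- c(e1 = "eRNA", x = "NE")
      sets <- lapply(seq_len(n), function(s) {
        structure(list(sample_id = paste0("s", s),
                       candidate_re_names = if (s <= m) "e1"
                                            else character(0)),
                  class = "candidate_set")
      })
      a <- vote_re(sets, labels)
      expect_equal(unname(a$flag["e1"]),
                   if (oracle_vote(m, n)) "RE" else "AE",
                   info = sprintf("n=%d m=%d", n, m))
      expect_equal(unname(a$flag["x"]), "NE")
      expect_equal(unname(a$m["e1"]), m)
    }
  }
  expect_error(vote_re(list(), c(e = "eRNA")), "input error")
})

test_that("single-sample tissues call every candidate an RE", {
  labels <- c(e1 = "eRNA", e2 = "eRNA", x = "NE")
  sets <- list(structure(list(sample_id = "s1",
                              candidate_re_names = "e1"),
                         class = "candidate_set"))
  a <- vote_re(sets, labels)
  expect_equal(unname(a$flag), c("RE", "AE", "NE"))
})

test_that("voting is monotone: extra support never demotes an eRNA", {
  set.seed(6)
  labels <- setNames(rep("eRNA", 12), sprintf("e%02d", 1:12))
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    base_sets <- lapply(seq_len(n), function(s) {
      structure(list(sample_id = paste0("s", s),
                     candidate_re_names =
                       names(labels)[runif(12) < 0.5]),
                class = "candidate_set")
    })
    a1 <- vote_re(base_sets, labels)
    target <- sample(names(labels), 1)
    grown <- base_sets
    pick <- sample.int(n, 1)
    grown[[pick]]$candidate_re_names <-
      union(grown[[pick]]$candidate_re_names, target)
    a2 <- vote_re(grown, labels)
    if (a1$flag[target] == "RE") expect_equal(unname(a2$flag[target]), "RE")
  }
})

test_that("6D matrix appends the binary RE flag", {
  m <- blob_features(3, 3, seed = 4)
  labels <- setNames(rep(c("eRNA", "NE"), each = 3), rownames(m))
  sets <- list(structure(list(sample_id = "s1",
                              candidate_re_names = rownames(m)[1:2]),
                         class = "candidate_set"))
  a <- vote_re(sets, labels)
  six <- build_6d_features(m, a)
  expect_equal(dim(six), c(6L, 6L))
  expect_equal(unname(six[, "re_flag"]), c(1, 1, 0, 0, 0, 0))
  expect_equal(six[, 1:5], m)
  rownames(m)[1] <- "missing"
  expect_error(build_6d_features(m, a), "consistency error")
})

test_that("RE proportion is the fraction of eRNAs flagged RE", {
  labels <- setNames(rep(c("eRNA", "NE"), c(10, 4)),
                     sprintf("r%02d", 1:14))
  sets <- list(structure(list(sample_id = "s1",
                              candidate_re_names = names(labels)[1:3]),
                         class = "candidate_set"))
  a <- vote_re(sets, labels)
  expect_equal(re_proportion(a), 0.3)
  all_sets <- list(structure(list(sample_id = "s1",
                                  candidate_re_names = names(labels)[1:10]),
                             class = "candidate_set"))
  expect_equal(re_proportion(vote_re(all_sets, labels)), 1.0)
})

test_that("assignment TSV round-trips", {
  labels <- c(e1 = "eRNA", x = "NE")
  sets <- list(structure(list(sample_id = "s1",
                              candidate_re_names = "e1"),
                         class = "candidate_set"))
  a <- vote_re(sets, labels)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_re_assignment(a, path)
  back <- read.delim(path)
  expect_equal(back$flag, c("RE", "NE"))
  expect_equal(back$m, c(1L, 0L))
  expect_equal(back$n, c(1L, 1L))
})
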