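peaks_df <- function(starts, ends, chrom = "chrT", signal = 0) {
  data.frame(chrom = chrom, start = as.integer(starts),
             end = as.integer(ends), signal = signal)
}

test_that("mean peak length is the arithmetic mean of widths", {
  tr <- sample_track("s", "H3K4me1", peaks_df(c(0, 100), c(100, 400)))
  expect_equal(mean_peak_length(tr), 200)
  expect_equal(mean_peak_length(peaks_df(10, 511)), 501)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), signal = numeric(0))
  expect_error(mean_peak_length(sample_track("s", "H3K4me1", empty)),
               "empty-track")
})

test_that("simulated peak lengths match their distribution mean", {
  cfg <- sim_config(seed = 1)
  set.seed(10)
  lens <- ernafuse:::rpeak_len(1000, cfg)
  mu <- mean(pmax(cfg$peak_min,
                  round(stats::rlnorm(2e5, cfg$peak_meanlog,
                                      cfg$peak_sdlog))))
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - mu), 3 * se + 1)
})

test_that("window occupancy marks >= 1 bp overlaps only", {
  layout <- build_layout(6001, 300)
  region <- genomic_region("chrT", 10000, 16001, "r1")
  cw <- layout$windows[11, ]
  tr <- sample_track("s", "H3K27ac",
                     peaks_df(10000 + cw$start, 10000 + cw$end))
  occ <- window_occupancy(region, layout, tr)
  expect_equal(which(occ), 11L)
  none <- sample_track("s", "H3K27ac", peaks_df(1, 5))
  expect_equal(sum(window_occupancy(region, layout, none)), 0L)
  # chromosome mismatch yields all-false with a message
  other <- sample_track("s", "H3K27ac",
                        peaks_df(10000, 16000, chrom = "chrX"))
  expect_message(occ2 <- window_occupancy(region, layout, other),
                 "no peaks")
  expect_false(any(occ2))
})

test_that("occupancy matches a per-base brute-force oracle", {
  layout <- build_layout(1001, 100)
  region <- genomic_region("chrT", 500, 1501, "r")
  set.seed(4)
  for (rep in 1:20) {
    starts <- sample(300:1700, 8)
    pk <- peaks_df(starts, starts + sample(20:300, 8, TRUE))
    tr <- sample_track("s", "H3K4me3", pk)
    occ <- window_occupancy(region, layout, tr)
    covered <- rep(FALSE, 1001)
    for (j in seq_len(nrow(pk))) {
      lo <- max(pk$start[j], 500); hi <- min(pk$end[j], 1501)
      if (hi > lo) covered[(lo - 500 + 1):(hi - 500)] <- TRUE
    }
    oracle <- vapply(seq_len(nrow(layout$windows)), function(i) {
      w <- layout$windows[i, ]
      any(covered[(w$start + 1):w$end])
    }, logical(1))
    expect_equal(occ, oracle)
  }
})

test_that("occupancy and coverage are monotone in the peak set", {
  layout <- build_layout(1001, 100)
  region <- genomic_region("chrT", 0, 1001, "r")
  set.seed(5)
  starts <- sample(0:900, 6)
  pk <- peaks_df(starts, starts + 80)
  tr_small <- sample_track("s", "H3K4me1", pk[1:3, ])
  tr_big <- sample_track("s", "H3K4me1", pk)
  occ_small <- window_occupancy(region, layout, tr_small)
  occ_big <- window_occupancy(region, layout, tr_big)
  expect_true(all(occ_big >= occ_small))
  cs <- ernafuse:::coverage_fraction("chrT", 400, 600, pk[1:3, ])
  cb <- ernafuse:::coverage_fraction("chrT", 400, 600, pk)
  expect_gte(cb, cs)
})

test_that("optimal histone window follows polarity with center tie-break", {
  occ <- matrix(FALSE, 10, 5)
  occ[, 3] <- TRUE
  occ[1:3, 1] <- TRUE
  expect_equal(select_optimal_histone_window(occ, "positive"), 3L)
  # negative mark: least-occupied column wins
  expect_equal(select_optimal_histone_window(occ, "negative"), 2L)
  occ2 <- matrix(TRUE, 4, 5)
  expect_equal(select_optimal_histone_window(occ2, "negative"), 3L)
  occ2[, 5] <- FALSE
  expect_equal(select_optimal_histone_window(occ2, "negative"), 5L)
  expect_error(select_optimal_histone_window(matrix(logical(0), 0, 5),
                                             "positive"), "input error")
})

test_that("histone features are coverage fractions of the optimal window", {
  layout <- build_layout(1001, 100)
  region <- genomic_region("chrT", 0, 1001, "r1")
  cw <- layout$windows[layout$center_index, ]
  full <- peaks_df(cw$start, cw$end)
  half <- peaks_df(cw$start, cw$start + (cw$end - cw$start) / 2)
  ow <- setNames(lapply(HISTONE_MARKS, function(m)
    list(layout = layout, index = layout$center_index)), HISTONE_MARKS)
  tracks <- list(
    H3K4me1 = sample_track("s", "H3K4me1", full),
    H3K4me3 = sample_track("s", "H3K4me3", half),
    H3K9me3 = sample_track("s", "H3K9me3", peaks_df(2000, 2100)),
    H3K27ac = sample_track("s", "H3K27ac", full),
    H3K36me3 = sample_track("s", "H3K36me3", peaks_df(0, 50)))
  hf <- extract_histone_features(region, ow, tracks)
  expect_s3_class(hf, "histone_feature")
  expect_equal(unname(hf$values["H3K4me1"]), 1.0)
  expect_equal(unname(hf$values["H3K4me3"]), 0.5, tolerance = 0.01)
  expect_equal(unname(hf$values["H3K9me3"]), 0.0)
  expect_true(all(hf$values >= 0 & hf$values <= 1))
  expect_error(extract_histone_features(region, ow, tracks[1:4]),
               "missing-track")
})

test_that("vectorised feature matrix agrees with per-region extraction", {
  cfg <- sim_config(seed = 2, n_ernas = 12L, n_nes = 12L,
                    seq_length = 2001L, n_samples = 1L)
  truth <- simulate_truth(cfg)
  regions <- simulate_sequences(cfg)
  tracks <- simulate_tracks(cfg, truth, regions)[[1]]
  ow <- histone_optimal_windows(regions[regions$label == "eRNA", ],
                                tracks, S = 2001L)
  fm <- histone_feature_matrix(regions, ow, tracks)
  expect_equal(dim(fm), c(24L, 5L))
  for (i in c(1L, 13L)) {
    region <- genomic_region(regions$chrom[i], regions$start[i],
                             regions$end[i], regions$name[i])
    hf <- extract_histone_features(region, ow, tracks)
    expect_equal(unname(fm[i, ]), unname(hf$values))
  }
})

test_that("planted center enrichment selects Mw for activating marks", {
  cfg <- sim_config(seed = 3, n_ernas = 40L, n_nes = 40L,
                    n_samples = 2L)
  truth <- simulate_truth(cfg)
  regions <- simulate_sequences(cfg)
  tracks <- simulate_tracks(cfg, truth, regions)
  erna <- regions[regions$label == "eRNA", ]
  pos_marks <- names(MARK_POLARITY)[MARK_POLARITY == "positive"]
  for (s in names(tracks)) {
    ow <- histone_optimal_windows(erna, tracks[[s]])
    for (m in pos_marks) {
      expect_equal(ow[[m]]$index, ow[[m]]$layout$center_index)
      expect_equal(ow[[m]]$window_class, "Mw")
    }
    # per-sample window sizes follow that sample's mean peak length
    for (m in HISTONE_MARKS)
      expect_equal(ow[[m]]$L,
                   choose_histone_window_size(300, ow[[m]]$Lpeak))
  }
})

test_that("peak summary reports per-window statistics", {
  layout <- build_layout(1001, 100)
  regions <- data.frame(chrom = "chrT", start = 0L, end = 1001L,
                        name = "r")
  tr <- sample_track("s", "H3K27ac",
                     peaks_df(c(450, 460), c(550, 580), signal = c(5, 9)))
  summ <- peak_window_summary(regions, layout, tr)
  expect_equal(nrow(summ), nrow(layout$windows))
  center <- summ[summ$window_index == layout$center_index, ]
  expect_equal(center$n_peaks, 2L)
  expect_equal(center$mean_signal, 7)
})
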