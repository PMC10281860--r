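# The histone channel: per-sample peak statistics, per-window occupancy
# of ChIP-seq peaks over a center-out layout, polarity-aware optimal
# window selection, and the 5-value feature vector (one value per mark)
# for every region and sample.  Interval arithmetic goes through
# IRanges/GenomicRanges.

peaks_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end))
}

#' Mean peak length of a sample track
#'
#' @param track A [sample_track()] (or a peaks data.frame).
#' @return Arithmetic mean of `end - start` in bp (`Lpeak`).
#' @export
mean_peak_length <- function(track) {
  peaks <- if (inherits(track, "sample_track")) track$peaks else track
  if (nrow(peaks) == 0L) stop("empty-track error: track has no peaks")
  mean(peaks$end - peaks$start)
}

#' Per-window peak occupancy of one region
#'
#' A window is occupied iff at least 1 bp of any peak overlaps its
#' genomic interval.  A chromosome mismatch between the region and all
#' peaks yields all-FALSE (with a message).
#'
#' @param region A [genomic_region()].
#' @param layout A [build_layout()] for the region length.
#' @param track A [sample_track()].
#' @return Logical vector, one entry per window.
#' @export
window_occupancy <- function(region, layout, track) {
  stopifnot(inherits(layout, "window_layout"))
  if (layout$S != region$end - region$start)
    stop("window_occupancy: layout length does not match region span")
  peaks <- if (inherits(track, "sample_track")) track$peaks else track
  w <- layout$windows
  out <- rep(FALSE, nrow(w))
  peaks <- peaks[peaks$chrom == region$chrom, , drop = FALSE]
  if (nrow(peaks) == 0L) {
    message(sprintf("window_occupancy: no peaks on %s for region %s",
                    region$chrom, region$name))
    return(out)
  }
  win <- IRanges::IRanges(start = region$start + w$start + 1L,
                          end = region$start + w$end)
  pk <- IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  IRanges::overlapsAny(win, pk)
}

#' Select the optimal histone window for one mark
#'
#' Columns of the occupancy matrix are windows, rows are eRNA records.
#' For positive-polarity marks the window occupied in the most eRNAs is
#' selected; for the negative mark (H3K36me3) the least-occupied window.
#' Ties are broken toward the center, then toward the smaller index.
#'
#' @param occupancy Logical/numeric matrix, eRNA rows x window columns.
#' @param polarity `"positive"` or `"negative"` (see [MARK_POLARITY]).
#' @param center_index Center window index; defaults to the middle column.
#' @return Selected window index.
#' @export
select_optimal_histone_window <- function(occupancy,
                                          polarity = c("positive",
                                                       "negative"),
                                          center_index = NULL) {
  polarity <- match.arg(polarity)
  if (is.null(dim(occupancy)) || nrow(occupancy) < 1L)
    stop("input error: occupancy must be a matrix with >= 1 eRNA row")
  counts <- colSums(occupancy)
  if (polarity == "negative") counts <- -counts
  n <- length(counts)
  if (is.null(center_index)) center_index <- (n + 1L) %/% 2L
  best <- which(counts == max(counts))
  best[order(abs(best - center_index), best)][1L]
}

# Fraction of [start, end) covered by the union of a track's peaks
# (on the region's chromosome); clipped to [0, 1].  When signal_weighted,
# each base contributes the maximum signal of the peaks covering it,
# normalised by the maximum signal in the track.
coverage_fraction <- function(chrom, start, end, peaks,
                              signal_weighted = FALSE) {
  peaks <- peaks[peaks$chrom == chrom, , drop = FALSE]
  if (nrow(peaks) == 0L) return(0)
  win <- IRanges::IRanges(start = start + 1L, end = end)
  pk <- IRanges::IRanges(start = peaks$start + 1L, end = peaks$end)
  if (!signal_weighted) {
    ov <- IRanges::intersect(win, IRanges::reduce(pk))
    return(min(1, sum(IRanges::width(ov)) / (end - start)))
  }
  # each base weighted by the strongest covering peak's signal,
  # normalised by the track's maximum signal
  smax <- max(peaks$signal, 1e-12)
  base_w <- rep(0, end - start)
  hit <- which(peaks$end > start & peaks$start < end)
  for (i in hit) {
    lo <- max(peaks$start[i], start) - start + 1L
    hi <- min(peaks$end[i], end) - start
    base_w[lo:hi] <- pmax(base_w[lo:hi], peaks$signal[i] / smax)
  }
  min(1, mean(base_w))
}

#' Extract the 5-mark histone feature vector of one region
#'
#' For each of the five marks, the feature is the fraction of that mark's
#' optimal window covered by the sample's peaks for the mark (in `[0, 1]`;
#' optionally weighted by peak signal).  Each mark carries its own window
#' geometry because the window size depends on the sample's mean peak
#' length for that mark.
#'
#' @param region A [genomic_region()].
#' @param optimal_windows Named list (one entry per mark) of lists with
#'   elements `layout` (the mark's [build_layout()]) and `index` (the
#'   mark's optimal window index), as produced by
#'   [histone_optimal_windows()].
#' @param tracks Named list of this sample's [sample_track()]s, one per
#'   mark.
#' @param signal_weighted Use signal-weighted coverage (default FALSE).
#' @return A list of class `histone_feature` with fields `region`
#'   (name), `sample_id` and `values` (named 5-vector in `[0, 1]`).
#' @export
extract_histone_features <- function(region, optimal_windows, tracks,
                                     signal_weighted = FALSE) {
  miss <- setdiff(HISTONE_MARKS, names(tracks))
  if (length(miss) > 0L) {
    sid <- if (length(tracks) > 0) tracks[[1]]$sample_id else "?"
    stop(sprintf("missing-track error: sample %s lacks mark %s",
                 sid, miss[1]))
  }
  values <- vapply(HISTONE_MARKS, function(mark) {
    ow <- optimal_windows[[mark]]
    w <- ow$layout$windows[ow$index, ]
    coverage_fraction(region$chrom,
                      region$start + w$start, region$start + w$end,
                      tracks[[mark]]$peaks, signal_weighted)
  }, numeric(1))
  structure(
    list(region = region$name, sample_id = tracks[[1]]$sample_id,
         values = values),
    class = "histone_feature")
}

#' Choose per-mark optimal windows for one sample
#'
#' For each mark: the window size follows [choose_histone_window_size()]
#' from the sample's mean peak length, the layout is built for the region
#' length, occupancy is counted over the eRNA training records only, and
#' the optimal window is selected with the mark's polarity.
#'
#' @param erna_regions Data.frame of eRNA records (`chrom`, `start`,
#'   `end`, `name`).
#' @param tracks Named list of one sample's [sample_track()]s (one per
#'   mark in [HISTONE_MARKS]).
#' @param S Region length (default 6001).
#' @param LF Nominal window size (default 300).
#' @return Named list per mark: `layout`, `index`, `L`, `Lpeak`,
#'   `window_class` (`Mw` center / `Aw` adjacent / `Fw` otherwise).
#' @export
histone_optimal_windows <- function(erna_regions, tracks, S = 6001L,
                                    LF = 300L) {
  miss <- setdiff(HISTONE_MARKS, names(tracks))
  if (length(miss) > 0L)
    stop(sprintf("missing-track error: lacking mark %s", miss[1]))
  out <- list()
  for (mark in HISTONE_MARKS) {
    track <- tracks[[mark]]
    Lpeak <- mean_peak_length(track)
    L <- choose_histone_window_size(LF, Lpeak)
    layout <- build_layout(S, L)
    occ <- occupancy_matrix(erna_regions, layout, track)
    idx <- select_optimal_histone_window(
      occ, MARK_POLARITY[[mark]], layout$center_index)
    dist <- abs(idx - layout$center_index)
    out[[mark]] <- list(
      layout = layout, index = idx, L = L, Lpeak = Lpeak,
      window_class = if (dist == 0L) "Mw" else if (dist == 1L) "Aw"
                     else "Fw")
  }
  out
}

# Vectorised occupancy over many regions: one GRanges overlap query for
# all region-window pairs.  Rows = regions, columns = windows.
occupancy_matrix <- function(regions, layout, track) {
  peaks <- if (inherits(track, "sample_track")) track$peaks else track
  w <- layout$windows
  W <- nrow(w)
  n <- nrow(regions)
  starts <- rep(regions$start, each = W) + rep(w$start, n)
  ends <- rep(regions$start, each = W) + rep(w$end, n)
  chroms <- rep(regions$chrom, each = W)
  if (nrow(peaks) == 0L) return(matrix(FALSE, n, W))
  win <- GenomicRanges::GRanges(chroms,
                                IRanges::IRanges(starts + 1L, ends))
  pk <- peaks_granges(peaks)
  hits <- suppressWarnings(IRanges::overlapsAny(win, pk))
  matrix(hits, n, W, byrow = TRUE)
}

# Vectorised coverage fraction of one fixed window offset across regions.
coverage_vector <- function(regions, win_start, win_end, peaks) {
  n <- nrow(regions)
  starts <- regions$start + win_start
  ends <- regions$start + win_end
  if (nrow(peaks) == 0L) return(rep(0, n))
  win <- GenomicRanges::GRanges(regions$chrom,
                                IRanges::IRanges(starts + 1L, ends))
  pk <- suppressWarnings(IRanges::reduce(peaks_granges(peaks)))
  ov <- suppressWarnings(IRanges::findOverlaps(win, pk))
  out <- rep(0, n)
  if (length(ov) > 0L) {
    qi <- S4Vectors::queryHits(ov)
    inter_w <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(win)[qi],
      IRanges::ranges(pk)[S4Vectors::subjectHits(ov)]))
    agg <- rowsum(inter_w, qi)
    out[as.integer(rownames(agg))] <- agg[, 1]
  }
  pmin(1, out / (win_end - win_start))
}

#' Histone feature matrix for one sample
#'
#' Applies [extract_histone_features()] to every region of a dataset.
#'
#' @param dataset Dataset data.frame (`chrom`, `start`, `end`, `name`).
#' @param optimal_windows Output of [histone_optimal_windows()] for this
#'   sample.
#' @param tracks This sample's named track list.
#' @param signal_weighted Use signal-weighted coverage.
#' @return Numeric matrix, regions x 5 marks, rownames = region names.
#' @export
histone_feature_matrix <- function(dataset, optimal_windows, tracks,
                                   signal_weighted = FALSE) {
  if (signal_weighted) {
    m <- t(vapply(seq_len(nrow(dataset)), function(i) {
      region <- genomic_region(dataset$chrom[i], dataset$start[i],
                               dataset$end[i], dataset$name[i])
      extract_histone_features(region, optimal_windows, tracks,
                               signal_weighted)$values
    }, numeric(length(HISTONE_MARKS))))
  } else {
    m <- vapply(HISTONE_MARKS, function(mark) {
      ow <- optimal_windows[[mark]]
      w <- ow$layout$windows[ow$index, ]
      coverage_vector(dataset, w$start, w$end, tracks[[mark]]$peaks)
    }, numeric(nrow(dataset)))
    if (nrow(dataset) == 1L) m <- matrix(m, nrow = 1L,
                                         dimnames = list(NULL, HISTONE_MARKS))
  }
  rownames(m) <- dataset$name
  colnames(m) <- HISTONE_MARKS
  m
}

#' Peak summary statistics per window
#'
#' Reports, for each window of a layout, the number, mean height (signal)
#' and mean width of the peaks overlapping it across the supplied
#' regions -- the descriptive statistics used to sanity-check the chosen
#' window size.  Reporting only; does not gate any selection.
#'
#' @param regions Data.frame of regions.
#' @param layout A [build_layout()].
#' @param track A [sample_track()].
#' @return Data.frame `window_index n_peaks mean_width mean_signal`.
#' @export
peak_window_summary <- function(regions, layout, track) {
  peaks <- track$peaks
  w <- layout$windows
  rows <- lapply(seq_len(nrow(w)), function(j) {
    hits <- logical(nrow(peaks))
    for (i in seq_len(nrow(regions))) {
      ws <- regions$start[i] + w$start[j]
      we <- regions$start[i] + w$end[j]
      hits <- hits | (peaks$chrom == regions$chrom[i] &
                        peaks$end > ws & peaks$start < we)
    }
    p <- peaks[hits, , drop = FALSE]
    data.frame(window_index = j, n_peaks = nrow(p),
               mean_width = if (nrow(p)) mean(p$end - p$start) else NA_real_,
               mean_signal = if (nrow(p)) mean(p$signal) else NA_real_)
  })
  do.call(rbind, rows)
}
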