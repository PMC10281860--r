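#' Center-out window layout of a candidate region
#'
#' Divides a region of length `S` into non-overlapping windows working
#' outward from the central base.  The first (center) window is the
#' `+/- L/2` bp neighbourhood of the central base, so it spans `L + 1` bp;
#' successive windows of exactly `L` bp are then taken upstream and
#' downstream in turn until the region is fully tiled.  The outermost
#' window on each side is truncated to whatever remains, and truncated
#' windows are retained so that the union of windows covers every base.
#'
#' With the canonical region length `S = 6001` and the FANTOM-derived
#' nominal window size `L = 300` this produces 21 windows with the center
#' window at index 11.
#'
#' @param S Total region length in bp.  Must be odd (midpoint-extended
#'   regions have a unique central base) and at least `L`.
#' @param L Nominal window size in bp; must be an even positive integer
#'   (the center window is built as `+/- L/2` around the central base).
#'
#' @return An object of class `window_layout`: a list with elements
#'   `S`, `L`, `windows` (a data.frame with columns `index`, `start`,
#'   `end`, `is_center`, `is_truncated`; offsets are 0-based half-open
#'   relative to the region start) and `center_index`.
#'
#' @examples
#' layout <- build_layout(6001, 300)
#' nrow(layout$windows)   # 21
#' layout$center_index    # 11
#' @export
build_layout <- function(S, L) {
  S <- as.integer(S)
  L <- as.integer(L)
  if (length(S) != 1L || length(L) != 1L || is.na(S) || is.na(L))
    stop("S and L must be single integers")
  if (L < 2L) stop("config error: window size L must be >= 2")
  if (L %% 2L != 0L) stop("config error: window size L must be even")
  if (S %% 2L != 1L) stop("config error: region length S must be odd")
  if (S < L) stop("degenerate-layout error: region length S < window size L")

  mid <- S %/% 2L                       # 0-based offset of the central base
  half <- L %/% 2L
  c_start <- mid - half
  c_end <- mid + half + 1L              # half-open; center window is L + 1 bp

  # full L-sized windows outward, then a truncated terminal window per side
  left_starts <- integer(0)
  s <- c_start
  while (s - L >= 0L) {
    s <- s - L
    left_starts <- c(s, left_starts)
  }
  left <- cbind(start = left_starts, end = left_starts + L)
  if (s > 0L) left <- rbind(c(0L, s), left)

  right_starts <- integer(0)
  e <- c_end
  while (e + L <= S) {
    right_starts <- c(right_starts, e)
    e <- e + L
  }
  right <- cbind(start = right_starts, end = right_starts + L)
  if (e < S) right <- rbind(right, c(e, S))

  starts <- c(left[, 1], c_start, right[, 1])
  ends <- c(left[, 2], c_end, right[, 2])
  n <- length(starts)
  center_index <- nrow(left) + 1L
  windows <- data.frame(
    index = seq_len(n),
    start = as.integer(starts),
    end = as.integer(ends),
    is_center = seq_len(n) == center_index,
    is_truncated = (ends - starts) < L
  )
  structure(
    list(S = S, L = L, windows = windows, center_index = center_index),
    class = "window_layout"
  )
}

#' @export
print.window_layout <- function(x, ...) {
  cat(sprintf(
    "window_layout: S=%d, L=%d, %d windows (center index %d)\n",
    x$S, x$L, nrow(x$windows), x$center_index
  ))
  invisible(x)
}

#' Window size for histone-modification features
#'
#' The window size used to extract a histone mark's features from one
#' sample depends on that sample's mean peak length `Lpeak`: when the
#' peaks are no longer than the nominal enhancer length `LF` the region is
#' divided with `LF`, otherwise with `Lpeak` (floored to the nearest even
#' integer so the center window can be built symmetrically).
#'
#' @param LF Nominal window size in bp (mean FANTOM enhancer length,
#'   default 300 elsewhere in the package); must be positive and even.
#' @param Lpeak Mean ChIP-seq peak length in bp for one sample and mark;
#'   must be positive.
#' @return The window size in bp (even integer).
#' @examples
#' choose_histone_window_size(300, 250)  # 300
#' choose_histone_window_size(300, 801)  # 800
#' @export
choose_histone_window_size <- function(LF, Lpeak) {
  if (length(LF) != 1L || length(Lpeak) != 1L ||
      !is.finite(LF) || !is.finite(Lpeak) || LF <= 0 || Lpeak <= 0)
    stop("config error: LF and Lpeak must be single positive numbers")
  if (as.integer(LF) %% 2L != 0L)
    stop("config error: LF must be even")
  if (Lpeak <= LF) as.integer(LF) else 2L * (floor(Lpeak) %/% 2L)
}

#' Translate a window to genomic coordinates
#'
#' @param region A `genomic_region` (see [genomic_region()]) whose span
#'   matches the layout length.
#' @param layout A `window_layout`.
#' @param index Window index (1-based, left to right).
#' @return A `genomic_region` for the window, 0-based half-open.
#' @export
window_to_genomic <- function(region, layout, index) {
  stopifnot(inherits(layout, "window_layout"))
  index <- as.integer(index)
  if (length(index) != 1L || is.na(index) ||
      index < 1L || index > nrow(layout$windows))
    stop(sprintf("index error: window index %s out of range 1..%d",
                 as.character(index), nrow(layout$windows)))
  w <- layout$windows[index, ]
  genomic_region(region$chrom, region$start + w$start, region$start + w$end,
                 name = sprintf("%s_w%d", region$name, index))
}

#' Write a window layout as TSV
#'
#' Dumps `index start end is_center is_truncated` (offsets relative to the
#' region start) for inspection.
#'
#' @param layout A `window_layout`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(layout, path) {
  stopifnot(inherits(layout, "window_layout"))
  utils::write.table(layout$windows, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
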