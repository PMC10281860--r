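# Fully synthetic fixtures with planted ground truth: candidate-region
# sequences with a discriminative motif planted in the eRNA center
# window, and per-sample ChIP-seq peak tracks in which regularly
# expressed eRNAs (REs) carry consistent center-window enrichment of the
# four activating marks across samples, accidental eRNAs (AEs) carry it
# sporadically, and H3K36me3 is planted with inverted polarity
# (off-center for eRNAs).  Everything is deterministic given the config
# seed, and every file emitted is re-readable by the package's own I/O.

#' Simulation configuration
#'
#' Defaults define the standard fixture: 200 eRNAs + 200 NEs of 6001 bp
#' on one synthetic chromosome, 4 samples per tissue, RE fraction 0.25,
#' a 12 bp motif planted in every eRNA center window, strong (0.92)
#' center-window enrichment of the four activating marks for REs, weak
#' (0.10) for AEs and background (0.04) for NEs, inverted H3K36me3, and
#' peak lengths from a discretised log-normal with median 250 bp (sdlog
#' 0.6), so that the mean peak length falls below the 300 bp nominal
#' window for some sample/mark tracks and above it for others.
#'
#' @param ... Overrides of the defaults (see Details in the package
#'   vignette).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_ernas = 200L,
    n_nes = 200L,
    seq_length = 6001L,
    n_samples = 4L,
    re_fraction = 0.25,
    tissue = "synthetic",
    chrom = "chrS",
    gc = 0.5,
    gc_center = 0.60,
    motif = "TGACGTCATCGATTGACGCA",
    motif_prob = 1.0,
    LF = 300L,
    # P(center-window peak | class) for the four activating marks
    p_center_positive = c(RE = 0.92, AE = 0.10, NE = 0.04),
    # P(center-window peak | class) for H3K36me3 (negative polarity)
    p_center_h3k36me3 = c(RE = 0.03, AE = 0.30, NE = 0.45),
    # P(off-center peak | class) for H3K36me3
    p_flank_h3k36me3 = c(RE = 0.70, AE = 0.70, NE = 0.30),
    # P(off-center background peak) for activating marks, any class
    p_flank_positive = 0.10,
    peak_meanlog = log(250),
    peak_sdlog = 0.6,
    peak_min = 50L,
    region_gap = 2000L,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0)
    stop(sprintf("sim_config: unknown field '%s'", bad[1]))
  cfg <- utils::modifyList(cfg, over)
  probs <- c(cfg$p_center_positive, cfg$p_center_h3k36me3,
             cfg$p_flank_h3k36me3, cfg$p_flank_positive,
             cfg$motif_prob, cfg$gc, cfg$gc_center)
  if (any(probs < 0 | probs > 1))
    stop("sim_config: probabilities must be in [0, 1]")
  if (cfg$re_fraction <= 0 || cfg$re_fraction >= 1)
    stop("sim_config: re_fraction must be in (0, 1)")
  if (cfg$seq_length %% 2L != 1L)
    stop("sim_config: seq_length must be odd")
  structure(cfg, class = c("sim_config", "list"))
}

random_dna <- function(n, len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  codes <- utf8ToInt("ACGT")
  vapply(seq_len(n), function(i)
    intToUtf8(sample(codes, len, replace = TRUE, prob = p)),
    character(1))
}

#' Assign planted ground-truth classes
#'
#' Exactly `round(re_fraction * n_ernas)` eRNAs are REs (sampled without
#' replacement); the rest are AEs; NEs are NEs.
#'
#' @param config A [sim_config()].
#' @return A list of class `ground_truth` with `class` (named vector
#'   `RE`/`AE`/`NE` over region names).
#' @export
simulate_truth <- function(config) {
  set.seed(config$seed)
  erna_names <- sprintf("erna_%03d", seq_len(config$n_ernas))
  ne_names <- sprintf("ne_%03d", seq_len(config$n_nes))
  n_re <- round(config$re_fraction * config$n_ernas)
  cls <- stats::setNames(rep("AE", config$n_ernas), erna_names)
  cls[sample(config$n_ernas, n_re)] <- "RE"
  cls <- c(cls, stats::setNames(rep("NE", config$n_nes), ne_names))
  structure(list(class = cls), class = "ground_truth")
}

#' Simulate candidate-region sequences
#'
#' I.i.d. background nucleotides at the configured GC content.  The
#' center window of each eRNA carries the planted enhancer-core signal:
#' its bases are drawn at the (typically elevated) `gc_center` content,
#' emulating the compositional enrichment of real enhancer cores, and
#' the core motif is planted at a uniform position inside it with
#' probability `motif_prob`.  NEs and eRNA flanks are background
#' composition and motif-free.
#'
#' @param config A [sim_config()].
#' @return A data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `label`, `tissue`, `sequence`.
#' @export
simulate_sequences <- function(config) {
  S <- config$seq_length
  layout <- build_layout(S, config$LF)
  cw <- layout$windows[layout$center_index, ]
  mlen <- nchar(config$motif)
  cw_len <- cw$end - cw$start
  if (mlen > cw_len)
    stop("config error: motif longer than the center window")
  set.seed(config$seed + 1L)
  n <- config$n_ernas + config$n_nes
  names_ <- c(sprintf("erna_%03d", seq_len(config$n_ernas)),
              sprintf("ne_%03d", seq_len(config$n_nes)))
  labels <- rep(c("eRNA", "NE"), c(config$n_ernas, config$n_nes))
  seqs <- random_dna(n, S, config$gc)
  cores <- random_dna(config$n_ernas, cw_len, config$gc_center)
  for (i in seq_len(config$n_ernas)) {
    if (stats::runif(1) <= config$motif_prob) {
      pos <- sample.int(cw_len - mlen + 1L, 1L)
      substr(cores[i], pos, pos + mlen - 1L) <- config$motif
    }
    substr(seqs[i], cw$start + 1L, cw$end) <- cores[i]
  }
  starts <- config$region_gap +
    (seq_len(n) - 1L) * (S + config$region_gap)
  data.frame(chrom = config$chrom, start = starts, end = starts + S,
             name = names_, label = labels, tissue = config$tissue,
             sequence = seqs, stringsAsFactors = FALSE)
}

rpeak_len <- function(n, config) {
  len <- round(stats::rlnorm(n, config$peak_meanlog, config$peak_sdlog))
  pmax(config$peak_min, len)
}

# One planted peak around a genomic position, clipped to the region.
make_peak <- function(center, len, rstart, rend) {
  s <- max(rstart, round(center - len / 2))
  e <- min(rend, s + len)
  if (e <= s) e <- s + 1L
  c(s, e)
}

#' Simulate per-sample ChIP-seq peak tracks
#'
#' For each sample and each mark, every region draws peaks according to
#' its planted class: activating marks are planted in the center window
#' with probability `p_center_positive[class]` (peak midpoint jittered
#' within +/- LF/4 of the region midpoint), H3K36me3 with the inverted
#' pattern (`p_center_h3k36me3`, plus frequent off-center peaks), and
#' background off-center peaks occur at `p_flank_positive`.
#'
#' @param config A [sim_config()].
#' @param truth A [simulate_truth()] result.
#' @param regions Output of [simulate_sequences()] (coordinates are
#'   taken from it; sequences are not used).
#' @return A list of class `track_set`: one element per sample, each a
#'   named list of [sample_track()]s over [HISTONE_MARKS].
#' @export
simulate_tracks <- function(config, truth, regions) {
  set.seed(config$seed + 2L)
  S <- config$seq_length
  jit <- config$LF %/% 4L
  out <- vector("list", config$n_samples)
  names(out) <- sprintf("sample_%d", seq_len(config$n_samples))
  cls <- truth$class[regions$name]
  for (s in seq_len(config$n_samples)) {
    sample_id <- sprintf("sample_%d", s)
    tracks <- list()
    for (mark in HISTONE_MARKS) {
      ps <- pe <- integer(0)
      for (i in seq_len(nrow(regions))) {
        rs <- regions$start[i]; re_ <- regions$end[i]
        midpoint <- rs + S %/% 2L
        cl <- cls[i]
        if (mark == "H3K36me3") {
          p_c <- config$p_center_h3k36me3[[cl]]
          p_f <- config$p_flank_h3k36me3[[cl]]
        } else {
          p_c <- config$p_center_positive[[cl]]
          p_f <- config$p_flank_positive
        }
        if (stats::runif(1) <= p_c) {
          pk <- make_peak(midpoint + sample.int(2L * jit + 1L, 1L) -
                            jit - 1L,
                          rpeak_len(1L, config), rs, re_)
          ps <- c(ps, pk[1]); pe <- c(pe, pk[2])
        }
        if (stats::runif(1) <= p_f) {
          # off-center: midpoint of a flank, away from the center window
          side <- sample(c(-1L, 1L), 1L)
          offset <- sample.int(S %/% 4L, 1L) + config$LF
          pk <- make_peak(midpoint + side * offset,
                          rpeak_len(1L, config), rs, re_)
          ps <- c(ps, pk[1]); pe <- c(pe, pk[2])
        }
      }
      peaks <- data.frame(chrom = config$chrom, start = as.integer(ps),
                          end = as.integer(pe),
                          signal = round(stats::rlnorm(length(ps),
                                                       log(10), 0.5), 3),
                          stringsAsFactors = FALSE)
      tracks[[mark]] <- sample_track(sample_id, mark, peaks)
    }
    out[[s]] <- tracks
  }
  structure(out, class = c("track_set", "list"))
}

#' Write a complete end-to-end fixture to disk
#'
#' Emits `regions.tsv` (region table), `regions.fa` (FASTA),
#' `truth.tsv`, and one BED file per sample and mark
#' (`<sample>_<mark>.bed`), all re-readable by the package's readers.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return A list with `regions` (data.frame including sequences),
#'   `tracks` (the [simulate_tracks()] result), `truth` and `paths`.
#' @export
make_end_to_end_fixture <- function(config, dir) {
  if (!dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("I/O error: cannot create %s", dir))
  truth <- simulate_truth(config)
  regions <- simulate_sequences(config)
  tracks <- simulate_tracks(config, truth, regions)
  region_path <- file.path(dir, "regions.tsv")
  utils::write.table(
    regions[c("chrom", "start", "end", "name", "label", "tissue")],
    region_path, sep = "\t", quote = FALSE, row.names = FALSE)
  fasta_path <- file.path(dir, "regions.fa")
  write_fasta(regions[c("name", "sequence")], fasta_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(name = names(truth$class), class = unname(truth$class)),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  bed_paths <- character(0)
  for (s in names(tracks)) {
    for (mark in HISTONE_MARKS) {
      p <- file.path(dir, sprintf("%s_%s.bed", s, mark))
      write_bed(tracks[[s]][[mark]]$peaks, p)
      bed_paths <- c(bed_paths, p)
    }
  }
  list(regions = regions, tracks = tracks, truth = truth,
       paths = list(regions = region_path, fasta = fasta_path,
                    truth = truth_path, beds = bed_paths))
}
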