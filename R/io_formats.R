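#' The five histone modification marks used by the pipeline
#'
#' H3K4me1, H3K4me3, H3K9me3 and H3K27ac are enriched at active enhancers
#' (positive polarity); H3K36me3 is negatively correlated with enhancer
#' RNA expression (negative polarity).
#'
#' @format A named character vector mapping mark name to `"positive"` or
#'   `"negative"`.
#' @export
MARK_POLARITY <- c(
  H3K4me1 = "positive",
  H3K4me3 = "positive",
  H3K9me3 = "positive",
  H3K27ac = "positive",
  H3K36me3 = "negative"
)

#' Names of the five histone marks
#' @export
HISTONE_MARKS <- names(MARK_POLARITY)

#' Construct a genomic region
#'
#' Coordinates are 0-based half-open (BED convention) throughout the
#' package; strand is ignored (candidate regions are strandless midpoint
#' extensions).
#'
#' @param chrom Chromosome name (nonempty string).
#' @param start,end Integer coordinates, `end > start`.
#' @param name Region name.
#' @return A list of class `genomic_region`.
#' @export
genomic_region <- function(chrom, start, end, name = "") {
  start <- as.integer(start); end <- as.integer(end)
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("genomic_region: chrom must be a nonempty string")
  if (is.na(start) || is.na(end) || end <= start)
    stop("genomic_region: end must be > start")
  structure(list(chrom = chrom, start = start, end = end, name = name),
            class = "genomic_region")
}

iupac_chars <- "ACGTNRYSWKMBDHV"

#' Read a FASTA file
#'
#' Sequences are uppercased; record order is preserved.  Malformed headers
#' or non-IUPAC characters raise a format error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `name` and `sequence` (possibly
#'   zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L)
    return(data.frame(name = character(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  is_header <- startsWith(lines, ">")
  if (!is_header[nonblank[1]])
    stop(sprintf("format error: line %d: expected FASTA header '>'",
                 nonblank[1]))
  bad <- nonblank[!is_header[nonblank] &
                    grepl(sprintf("[^%s%s]", iupac_chars, tolower(iupac_chars)),
                          trimws(lines[nonblank]))]
  if (length(bad) > 0L)
    stop(sprintf("format error: line %d: non-IUPAC character in sequence",
                 bad[1]))
  empty_header <- nonblank[is_header[nonblank] &
                             !nzchar(trimws(sub("^>", "", lines[nonblank])))]
  if (length(empty_header) > 0L)
    stop(sprintf("format error: line %d: empty FASTA header", empty_header[1]))
  set <- Biostrings::readBStringSet(path)
  data.frame(
    name = sub("\\s.*$", "", names(set)),
    sequence = toupper(as.character(set)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write sequences to FASTA
#'
#' @param seqs A data.frame with columns `name` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("name", "sequence") %in% names(seqs)))
  set <- Biostrings::DNAStringSet(seqs$sequence)
  names(set) <- seqs$name
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read ChIP-seq peaks from a BED3+/narrowPeak file
#'
#' Intervals are 0-based half-open.  When the file has at least 7 columns
#' the 7th (narrowPeak `signalValue`) is mapped to `signal`; otherwise
#' `signal` is 0.  Records with `start >= end` or non-integer coordinates
#' raise an error naming the line.
#'
#' @param path Path to a tab-separated BED3 or narrowPeak file.
#' @return A data.frame of peaks with columns `chrom`, `start`, `end`,
#'   `signal`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#") &
                  !startsWith(lines, "track") & !startsWith(lines, "browser"))
  out <- data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), signal = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(keep) == 0L) return(out)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 3L))
    stop(sprintf("format error: line %d: fewer than 3 BED columns",
                 keep[which(n_fields < 3L)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  bad_int <- !grepl("^-?[0-9]+$", start_chr) | !grepl("^-?[0-9]+$", end_chr)
  if (any(bad_int))
    stop(sprintf("format error: line %d: non-integer coordinates",
                 keep[which(bad_int)[1]]))
  start <- as.integer(start_chr); end <- as.integer(end_chr)
  inv <- start >= end
  if (any(inv))
    stop(sprintf("record error: line %d: start >= end", keep[which(inv)[1]]))
  signal <- rep(0, length(keep))
  has7 <- n_fields >= 7L
  if (any(has7)) {
    sig_chr <- vapply(fields[has7], `[[`, "", 7L)
    sig <- suppressWarnings(as.numeric(sig_chr))
    sig[is.na(sig)] <- 0
    signal[has7] <- sig
  }
  data.frame(chrom = chrom, start = start, end = end, signal = signal,
             stringsAsFactors = FALSE)
}

#' Write peaks as a 7-column BED (BED6 + signalValue)
#'
#' The layout round-trips through [read_bed()]: coordinates exactly,
#' `signal` via column 7.
#'
#' @param peaks Data.frame with `chrom`, `start`, `end` and optionally
#'   `signal`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  signal <- if ("signal" %in% names(peaks)) peaks$signal else 0
  df <- data.frame(peaks$chrom, peaks$start, peaks$end,
                   ".", 0L, ".", signal)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a sample track
#'
#' One biological sample's ChIP-seq peak set for one histone mark.
#'
#' @param sample_id Sample identifier.
#' @param mark One of [HISTONE_MARKS].
#' @param peaks Peaks data.frame as returned by [read_bed()].
#' @return A list of class `sample_track`.
#' @export
sample_track <- function(sample_id, mark, peaks) {
  if (!mark %in% HISTONE_MARKS)
    stop(sprintf("unknown histone mark '%s' (expected one of %s)",
                 mark, paste(HISTONE_MARKS, collapse = ", ")))
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  if (nrow(peaks) > 0 && any(peaks$end <= peaks$start))
    stop("sample_track: peaks must satisfy end > start")
  structure(list(sample_id = sample_id, mark = mark, peaks = peaks),
            class = "sample_track")
}

#' Read a candidate-region table
#'
#' Tab-separated with header `chrom start end name label tissue`; labels
#' must be `eRNA` or `NE`.
#'
#' @param path Path to the TSV.
#' @return A data.frame with those six columns.
#' @export
read_region_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "name", "label", "tissue")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop(sprintf("format error: region table missing columns: %s",
                 paste(missing, collapse = ", ")))
  if (!all(df$label %in% c("eRNA", "NE")))
    stop("format error: region labels must be 'eRNA' or 'NE'")
  df[required]
}

#' Assemble a balanced candidate dataset
#'
#' Combines a region table with its sequences and enforces the balanced
#' design: negatives (NE) are randomly subsampled (seeded) down to the
#' number of eRNAs, and all sequences must have equal length.
#'
#' @param regions Data.frame with columns `chrom`, `start`, `end`, `name`,
#'   `label`, `tissue` and `sequence` (e.g. a region table joined with a
#'   FASTA by `name`).
#' @param tracks Optional list of [sample_track()] objects carried along
#'   as the `tracks` attribute.
#' @param seed Integer seed for the NE subsample.
#' @return A data.frame of class `erna_dataset` with equal eRNA and NE
#'   counts.
#' @export
assemble_dataset <- function(regions, tracks = NULL, seed = 1L) {
  stopifnot(is.data.frame(regions), "sequence" %in% names(regions),
            "label" %in% names(regions))
  n_pos <- sum(regions$label == "eRNA")
  n_neg <- sum(regions$label == "NE")
  if (n_pos < 1L || n_neg < 1L)
    stop("assemble_dataset: need at least one eRNA and one NE record")
  if (n_neg < n_pos)
    stop(sprintf(
      "insufficient-negatives error: %d NE records for %d eRNAs",
      n_neg, n_pos))
  lens <- nchar(regions$sequence)
  if (length(unique(lens)) != 1L)
    stop("assemble_dataset: sequences must all have equal length")
  if (any(lens != regions$end - regions$start))
    stop("assemble_dataset: sequence length must equal end - start")
  pos <- regions[regions$label == "eRNA", , drop = FALSE]
  neg <- regions[regions$label == "NE", , drop = FALSE]
  if (n_neg > n_pos) {
    set.seed(as.integer(seed))
    neg <- neg[sort(sample.int(n_neg, n_pos)), , drop = FALSE]
  }
  out <- rbind(pos, neg)
  rownames(out) <- NULL
  attr(out, "tracks") <- tracks
  class(out) <- c("erna_dataset", "data.frame")
  out
}

#' Stratified train/test split
#'
#' Splits a dataset by the given ratio of parts, stratified by label so
#' both sides keep the balanced design.  The split is an exact partition:
#' train and test are disjoint and their union is the input.
#'
#' @param dataset A data.frame with a `label` column.
#' @param ratio Length-2 numeric `(train_parts, test_parts)`; default
#'   `c(4, 1)`.
#' @param seed Integer seed.
#' @return A list with elements `train` and `test`.
#' @export
split_train_test <- function(dataset, ratio = c(4, 1), seed = 1L) {
  stopifnot(is.data.frame(dataset), "label" %in% names(dataset))
  if (nrow(dataset) == 0L) stop("split_train_test: dataset is empty")
  if (length(ratio) != 2L || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("config error: ratio parts must be positive")
  test_frac <- ratio[2] / sum(ratio)
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  for (lab in unique(dataset$label)) {
    idx <- which(dataset$label == lab)
    n_test <- round(length(idx) * test_frac)
    if (n_test > 0L)
      test_idx <- c(test_idx, sample(idx, n_test))
  }
  test_idx <- sort(test_idx)
  keep_attrs <- attr(dataset, "tracks")
  train <- dataset[setdiff(seq_len(nrow(dataset)), test_idx), , drop = FALSE]
  test <- dataset[test_idx, , drop = FALSE]
  rownames(train) <- NULL; rownames(test) <- NULL
  attr(train, "tracks") <- keep_attrs
  attr(test, "tracks") <- keep_attrs
  list(train = train, test = test)
}

#' Write predictions as TSV
#'
#' Columns `name prob label_pred`.
#'
#' @param predictions Data.frame with `name`, `prob`, `label_pred`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  stopifnot(all(c("name", "prob", "label_pred") %in% names(predictions)))
  utils::write.table(predictions[c("name", "prob", "label_pred")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
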