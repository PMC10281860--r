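# Regularly-expressed eRNA (RE) identification: per-sample k-means
# clustering of the 5-mark feature vectors into a candidate-RE cluster
# and a candidate-AE/NE cluster, then cross-sample majority voting to fix
# the true REs, and the 6D fused histone matrix (5 marks + binary RE
# flag) consumed by the fusion classifier.

#' Cluster one sample's feature matrix into two classes
#'
#' K-means with `K = 2`, fixed-seed initialisation and 10 restarts (best
#' inertia kept), so partitions are reproducible.
#'
#' @param features Numeric matrix, regions x 5 marks (rownames = region
#'   names).
#' @param seed Integer seed.
#' @return A list with `cluster` (integer vector, 1/2 per region) and
#'   `centers` (2 x 5 centroid matrix).
#' @export
cluster_sample <- function(features, seed = 1L) {
  if (nrow(features) < 2L)
    stop("cluster_sample: need at least 2 regions")
  if (any(!is.finite(features)))
    stop("cluster_sample: features must be finite")
  if (nrow(unique(features)) < 2L)
    stop("degenerate-clustering error: all feature vectors identical")
  set.seed(as.integer(seed))
  if (nrow(features) == 2L) {
    # kmeans cannot take restarts here; two points split trivially
    centers <- features
    rownames(centers) <- NULL
    return(list(cluster = stats::setNames(1:2, rownames(features)),
                centers = centers))
  }
  km <- stats::kmeans(features, centers = 2L, nstart = 10L,
                      iter.max = 100L)
  list(cluster = stats::setNames(km$cluster, rownames(features)),
       centers = km$centers)
}

#' Label the candidate-RE cluster
#'
#' The candidate-RE cluster is the one whose centroid has the larger mean
#' over the four positive marks (ties broken by the smaller H3K36me3
#' centroid value); the candidate set contains only the eRNA-labelled
#' members of that cluster -- NEs can never be candidates.
#'
#' @param clustering A [cluster_sample()] result.
#' @param labels Named character vector (`eRNA`/`NE`) over the clustered
#'   region names.
#' @param sample_id Sample identifier carried into the result.
#' @return A list of class `candidate_set` with `sample_id` and
#'   `candidate_re_names`.
#' @export
label_candidate_cluster <- function(clustering, labels, sample_id = "") {
  centers <- clustering$centers
  if (nrow(centers) != 2L)
    stop("label_candidate_cluster: expected exactly 2 clusters")
  pos_marks <- names(MARK_POLARITY)[MARK_POLARITY == "positive"]
  pos_mean <- rowMeans(centers[, pos_marks, drop = FALSE])
  if (abs(pos_mean[1] - pos_mean[2]) < 1e-12) {
    neg <- centers[, "H3K36me3"]
    re_cluster <- which.min(neg)
  } else {
    re_cluster <- which.max(pos_mean)
  }
  members <- names(clustering$cluster)[clustering$cluster == re_cluster]
  cand <- members[labels[members] == "eRNA"]
  structure(list(sample_id = sample_id,
                 candidate_re_names = cand),
            class = "candidate_set")
}

#' Vote true REs across samples
#'
#' An eRNA is a true RE of the tissue iff it is a candidate RE in `m` of
#' the `n` per-sample candidate sets with `m >= n/2` for even `n`, or
#' `m > n/2` for odd `n` (both reduce to `m >= ceiling(n/2)`).  All other
#' eRNAs are AE; NEs stay NE.
#'
#' @param candidate_sets List of [label_candidate_cluster()] results (one
#'   per sample).
#' @param labels Named character vector (`eRNA`/`NE`) over all region
#'   names.
#' @return A list of class `re_assignment` with `flag` (named vector over
#'   regions with values `RE`/`AE`/`NE`), `m` (candidate counts) and `n`.
#' @export
vote_re <- function(candidate_sets, labels) {
  n <- length(candidate_sets)
  if (n < 1L) stop("input error: empty sample list")
  nm <- names(labels)
  if (is.null(nm)) stop("vote_re: labels must be named by region")
  m <- stats::setNames(integer(length(nm)), nm)
  for (cs in candidate_sets) {
    cand <- intersect(cs$candidate_re_names, nm)
    m[cand] <- m[cand] + 1L
  }
  threshold <- ceiling(n / 2)
  flag <- ifelse(labels == "NE", "NE",
                 ifelse(m >= threshold, "RE", "AE"))
  structure(list(flag = stats::setNames(flag, nm),
                 m = m, n = n, threshold = threshold),
            class = "re_assignment")
}

#' @export
print.re_assignment <- function(x, ...) {
  tab <- table(factor(x$flag, levels = c("RE", "AE", "NE")))
  cat(sprintf("re_assignment over %d regions (n = %d samples): %s\n",
              length(x$flag), x$n,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Build the 6D fused histone matrix
#'
#' Appends the binary RE flag (RE = 1, AE/NE = 0) to the chosen sample's
#' 5-mark feature matrix.
#'
#' @param features Numeric matrix, regions x 5 marks, rownames = region
#'   names (the chosen sample's [histone_feature_matrix()]).
#' @param assignment A [vote_re()] result covering all rows.
#' @return Numeric matrix, regions x 6 (`re_flag` column appended).
#' @export
build_6d_features <- function(features, assignment) {
  stopifnot(inherits(assignment, "re_assignment"))
  nm <- rownames(features)
  missing <- setdiff(nm, names(assignment$flag))
  if (length(missing) > 0L)
    stop(sprintf("consistency error: region %s missing from assignment",
                 missing[1]))
  re_flag <- as.numeric(assignment$flag[nm] == "RE")
  cbind(features, re_flag = re_flag)
}

#' Proportion of eRNAs flagged RE
#'
#' @param assignment A [vote_re()] result.
#' @return `|RE| / |eRNA|` as a fraction.
#' @export
re_proportion <- function(assignment) {
  stopifnot(inherits(assignment, "re_assignment"))
  erna <- assignment$flag[assignment$flag != "NE"]
  if (length(erna) == 0L) stop("re_proportion: no eRNA records")
  mean(erna == "RE")
}

#' Write an RE assignment as TSV
#'
#' Columns `name flag m n`.
#'
#' @param assignment A [vote_re()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_re_assignment <- function(assignment, path) {
  df <- data.frame(name = names(assignment$flag),
                   flag = unname(assignment$flag),
                   m = unname(assignment$m[names(assignment$flag)]),
                   n = assignment$n)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
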