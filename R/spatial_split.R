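#' Pairwise Euclidean distances between samples
#'
#' Distances between sample (column) vectors, optionally after per-feature
#' z-scoring so no feature dominates by scale. Zero-variance features get
#' zero weight under standardization (their z-score is undefined), with a
#' message.
#'
#' @param matrix features x samples matrix, >= 2 samples.
#' @param standardize z-score each feature first.
#' @return symmetric samples x samples distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(matrix, standardize = TRUE) {
  if (ncol(matrix) < 2L) stop("pairwise_distances: need >= 2 samples")
  m <- matrix
  if (standardize) {
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0)) {
      message("pairwise_distances: ", sum(sds == 0),
              " zero-variance feature(s) given zero weight")
      m <- m[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    if (nrow(m) == 0L) return(matrix(0, ncol(matrix), ncol(matrix),
                                     dimnames = list(colnames(matrix),
                                                     colnames(matrix))))
    m <- (m - rowMeans(m)) / sds
  }
  d <- as.matrix(stats::dist(t(m)))
  dimnames(d) <- list(colnames(matrix), colnames(matrix))
  d
}

#' Greedy farthest-point ordering
#'
#' Position 1 is `start`; position 2 the sample farthest from it; every
#' later position the unselected sample maximizing the mean distance to all
#' already-selected samples. Ties break to the smallest sample index, so
#' the order is deterministic given `start`.
#'
#' @param distances symmetric distance matrix.
#' @param start starting sample index (1-based).
#' @return integer permutation of `1:n`.
#' @export
farthest_point_order <- function(distances, start) {
  n <- nrow(distances)
  stopifnot(start >= 1L, start <= n)
  order_out <- integer(n)
  order_out[1L] <- start
  remaining <- setdiff(seq_len(n), start)
  sumd <- distances[, start]
  for (k in seq_len(n - 1L)) {
    # which.max returns the first (smallest-index) maximum: the tie rule
    best <- remaining[which.max(sumd[remaining] / k)]
    order_out[k + 1L] <- best
    remaining <- setdiff(remaining, best)
    sumd <- sumd + distances[, best]
  }
  order_out
}

#' Class-stratified spatial subset split
#'
#' Within each OS class independently: a seed sample is drawn at random,
#' the greedy farthest-point order is computed on the class's samples, and
#' the first `round(train_fraction * n_class)` samples (round half up)
#' form the training set; the rest are the test set. The only random
#' element is the per-class seed sample.
#'
#' @param matrix features x samples matrix (the feature space distances are
#'   computed in).
#' @param labels a `cohort_labels`.
#' @param train_fraction fraction of each class assigned to training.
#' @param rng_seed integer seed for the per-class seed draws.
#' @param standardize passed to [pairwise_distances()].
#' @return list of class `split_assignment`: `train_ids`, `test_ids`,
#'   `seed_sample` (named by class), `rng_seed`, `train_fraction`.
#' @export
spatial_subset_split <- function(matrix, labels, train_fraction = 2 / 3,
                                 rng_seed = 1L, standardize = TRUE) {
  lab <- labels$labels[colnames(matrix)]
  classes <- sort(unique(lab))
  sizes <- table(lab)
  if (any(sizes < 3L))
    stop("spatial_subset_split: class '",
         names(sizes)[which.min(sizes)], "' has < 3 samples")
  set.seed(as.integer(rng_seed))
  train_ids <- character(0); test_ids <- character(0)
  seed_sample <- character(0)
  for (cl in classes) {
    ids <- colnames(matrix)[lab == cl]
    d <- pairwise_distances(matrix[, ids, drop = FALSE],
                            standardize = standardize)
    start <- sample.int(length(ids), 1L)
    ord <- farthest_point_order(d, start)
    n_train <- floor(train_fraction * length(ids) + 0.5)
    train_ids <- c(train_ids, ids[ord[seq_len(n_train)]])
    test_ids <- c(test_ids, ids[ord[-seq_len(n_train)]])
    seed_sample[cl] <- ids[start]
  }
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 seed_sample = seed_sample,
                 rng_seed = as.integer(rng_seed),
                 train_fraction = train_fraction),
            class = "split_assignment")
}
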