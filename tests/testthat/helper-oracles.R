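# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (explicit loops, textbook formulas) and never call the
# package functions they are compared with.

# Euclidean distance table by double loop
oracle_distances <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((m[, i] - m[, j])^2))
  d
}

# greedy farthest-point order with explicit candidate scan and
# smallest-index tie-break
oracle_fps <- function(d, start) {
  n <- nrow(d)
  sel <- start
  while (length(sel) < n) {
    cand <- setdiff(seq_len(n), sel)
    score <- sapply(cand, function(c) mean(d[c, sel]))
    best <- cand[score == max(score)]
    sel <- c(sel, min(best))
  }
  sel
}

# AUC as explicit pairwise concordance with half credit for ties
oracle_auc <- function(p, pos) {
  tot <- 0; npairs <- 0
  for (i in which(pos)) for (j in which(!pos)) {
    npairs <- npairs + 1
    tot <- tot + if (p[i] > p[j]) 1 else if (p[i] == p[j]) 0.5 else 0
  }
  tot / npairs
}

# a small labeled cohort where the first feature separates the classes
toy_cohort <- function(n_per_class = 10, n_features = 4, shift = 3,
                       seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_class
  m <- matrix(rnorm(n_features * n), n_features, n,
              dimnames = list(paste0("f", seq_len(n_features)),
                              paste0("s", seq_len(n))))
  hi <- seq_len(n_per_class)
  m[1, hi] <- m[1, hi] + shift
  labels <- structure(list(
    median_os = 100,
    labels = setNames(ifelse(seq_len(n) %in% hi, "high-OS", "low-OS"),
                      colnames(m))), class = "cohort_labels")
  list(matrix = m, labels = labels)
}

write_tsv_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
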