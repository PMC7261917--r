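#' Welch's unequal-variance t statistic
#'
#' Two-sample t statistic with the Welch-Satterthwaite degrees of freedom
#' and a two-tailed p-value from the t reference distribution. Degenerate
#' inputs: zero variance in both groups with equal means gives `t = 0,
#' p = 1`; zero variance with unequal means gives the `p = 0` limit with a
#' warning.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return list with `t_stat`, `df`, `p_value`.
#' @export
welch_t <- function(group_a, group_b) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 < 2L || n2 < 2L)
    stop("welch_t: each group needs >= 2 values")
  m1 <- mean(group_a); m2 <- mean(group_b)
  v1 <- stats::var(group_a); v2 <- stats::var(group_b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    if (m1 == m2) return(list(t_stat = 0, df = n1 + n2 - 2, p_value = 1))
    warning("welch_t: zero variance with unequal means; p = 0 limit")
    return(list(t_stat = sign(m1 - m2) * Inf, df = n1 + n2 - 2, p_value = 0))
  }
  t_stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t_stat = t_stat, df = df, p_value = p)
}

#' Linear-scale fold change between two log2 groups
#'
#' Values are back-transformed (`2^x - 1`) and the ratio of group means is
#' returned, with an epsilon guard against zero denominators:
#' `FC = (mean_high + 1e-8) / (mean_low + 1e-8)`.
#'
#' @param high,low numeric vectors on the log2(x+1) scale.
#' @return fold change (high over low).
#' @export
fold_change <- function(high, low) {
  if (length(high) == 0L || length(low) == 0L)
    stop("fold_change: groups must be nonempty")
  eps <- 1e-8
  (mean(2^high - 1) + eps) / (mean(2^low - 1) + eps)
}

#' Construct a marker set
#'
#' @param cancer cancer identifier.
#' @param omic omic tag (`"miRNA"` or `"lncRNA"`).
#' @param markers character vector of feature IDs (deduplicated, order
#'   kept).
#' @return list of class `marker_set`.
#' @export
marker_set <- function(cancer, omic, markers) {
  structure(list(cancer = cancer, omic = omic, markers = unique(markers)),
            class = "marker_set")
}

#' Detect prognosis-related differentially expressed ncRNAs
#'
#' Per feature, Welch's t test and the linear-scale fold change between the
#' high-OS and low-OS groups. The pass rule is omic-specific: miRNAs pass
#' at `p < 0.05`; lncRNAs pass at `p < 0.01` together with a two-sided fold
#' change gate (`FC >= 2` or `FC <= 0.5`). P-values are unadjusted by
#' default; `adjust = TRUE` gates on Benjamini-Hochberg adjusted values
#' instead.
#'
#' @param matrix features x samples matrix, log2 scale.
#' @param labels a `cohort_labels` (see [label_by_median_os()]).
#' @param omic `"miRNA"` or `"lncRNA"`.
#' @param cancer cancer identifier stored in the returned marker set.
#' @param p_mirna,p_lncrna,fc_threshold filter thresholds.
#' @param adjust gate on BH-adjusted p-values.
#' @return list with `results` (data.frame: `feature_id`, `t_stat`,
#'   `p_value`, `fold_change`, `passes`) and `markers` (a [marker_set()]).
#' @export
detect_de <- function(matrix, labels, omic = c("miRNA", "lncRNA"),
                      cancer = NA_character_,
                      p_mirna = 0.05, p_lncrna = 0.01, fc_threshold = 2,
                      adjust = FALSE) {
  omic <- match.arg(omic)
  lab <- labels$labels[colnames(matrix)]
  hi <- which(lab == "high-OS"); lo <- which(lab == "low-OS")
  if (length(hi) < 2L) stop("detect_de: class 'high-OS' has < 2 samples")
  if (length(lo) < 2L) stop("detect_de: class 'low-OS' has < 2 samples")
  res <- t(apply(matrix, 1L, function(x) {
    w <- welch_t(x[hi], x[lo])
    c(w$t_stat, w$p_value, fold_change(x[hi], x[lo]))
  }))
  results <- data.frame(feature_id = rownames(matrix),
                        t_stat = res[, 1], p_value = res[, 2],
                        fold_change = res[, 3],
                        stringsAsFactors = FALSE)
  p_gate <- if (adjust) stats::p.adjust(results$p_value, "BH") else
    results$p_value
  if (omic == "miRNA") {
    results$passes <- p_gate < p_mirna
  } else {
    fc_pass <- results$fold_change >= fc_threshold |
      results$fold_change <= 1 / fc_threshold
    results$passes <- p_gate < p_lncrna & fc_pass
  }
  rownames(results) <- NULL
  list(results = results,
       markers = marker_set(cancer, omic,
                            results$feature_id[results$passes]))
}

#' Factor-analysis feature reduction for small cohorts
#'
#' Standardizes features, picks the number of factors K by the Kaiser
#' criterion (eigenvalues of the feature correlation matrix above 1,
#' capped at `n_samples - 1`, at least 1), fits a maximum-likelihood
#' factor model and returns the union, over factors, of the `n_top`
#' features with largest absolute loading. When the ML fit fails (e.g.
#' degenerate correlation structure or too few samples) it falls back to
#' principal-component loadings, with a message.
#'
#' @param matrix features x samples matrix.
#' @param n_top features kept per factor.
#' @return character vector of selected feature IDs.
#' @export
factor_reduce <- function(matrix, n_top = 10) {
  if (ncol(matrix) < 3L) stop("factor_reduce: need >= 3 samples")
  if (n_top >= nrow(matrix)) return(rownames(matrix))
  keep <- apply(matrix, 1L, stats::sd) > 0
  m <- matrix[keep, , drop = FALSE]
  x <- t(scale(t(m)))
  cc <- stats::cor(t(x))
  ev <- eigen(cc, symmetric = TRUE)
  k <- sum(ev$values > 1)
  k <- max(1L, min(k, ncol(m) - 1L))
  loadings <- tryCatch({
    fa <- stats::factanal(x = t(x), factors = k)
    unclass(fa$loadings)
  }, error = function(e) {
    message("factor_reduce: factanal failed (", conditionMessage(e),
            "); using principal-component loadings")
    ev$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(k)], 0)), k)
  })
  rownames(loadings) <- rownames(m)
  sel <- unique(unlist(lapply(seq_len(ncol(loadings)), function(j) {
    ord <- order(abs(loadings[, j]), decreasing = TRUE)
    rownames(loadings)[ord[seq_len(min(n_top, nrow(loadings)))]]
  })))
  sel
}
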