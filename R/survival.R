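#' Kaplan-Meier product-limit estimate
#'
#' At each distinct event time `t`, the survival estimate multiplies by
#' `1 - d_t / n_t` (events over at-risk count); censored times only shrink
#' the risk set. With no censoring the estimator equals the empirical
#' survival function.
#'
#' @param times positive observed times.
#' @param events 0/1 event flags (1 = event observed).
#' @return data.frame of class `km_curve` with one row per distinct event
#'   time: `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_estimate <- function(times, events) {
  if (length(times) == 0L) stop("km_estimate: empty input")
  stopifnot(length(times) == length(events), all(times > 0))
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), n_risk = numeric(0),
                    n_event = numeric(0), surv = numeric(0))
  for (t in ev_times) {
    n_t <- sum(times >= t)
    d_t <- sum(times == t & events == 1)
    s <- s * (1 - d_t / n_t)
    out <- rbind(out, data.frame(time = t, n_risk = n_t, n_event = d_t,
                                 surv = s))
  }
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a KM curve at given times
#'
#' Right-continuous step-function lookup; survival is 1 before the first
#' event time.
#'
#' @param curve a `km_curve` from [km_estimate()].
#' @param at times at which to evaluate.
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(curve, at) {
  vapply(at, function(t) {
    i <- which(curve$time <= t)
    if (length(i) == 0L) 1 else curve$surv[max(i)]
  }, 0)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: observed minus expected events in group 1
#' summed over distinct event times, with hypergeometric expectations and
#' variances; `chi2 = (O - E)^2 / V`, p-value from chi-square with 1 df.
#' With no events at all, `chi2 = 0` and `p = 1`.
#'
#' @param times positive observed times.
#' @param events 0/1 event flags.
#' @param groups two-level group labels.
#' @return list with `chi2` and `p`.
#' @export
log_rank <- function(times, events, groups) {
  groups <- as.character(groups)
  lev <- sort(unique(groups))
  if (length(lev) != 2L)
    stop("log_rank: need exactly two nonempty groups")
  ev_times <- sort(unique(times[events == 1]))
  if (length(ev_times) == 0L) return(list(chi2 = 0, p = 1))
  o_minus_e <- 0; v <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == lev[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == lev[1])
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v == 0) return(list(chi2 = 0, p = 1))
  chi2 <- o_minus_e^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Survival comparison of predicted prognosis groups
#'
#' Groups the clinical samples by the classifier's predicted label and
#' compares their survival: per-group median of observed `os_days` (the
#' KM median is also reported), per-group KM curves, and the log-rank
#' test. If one predicted group is empty the comparison is degenerate and
#' `p = 1`, with a warning.
#'
#' @param eval an `eval_report` from [roc_auc()].
#' @param clinical clinical data.frame with `sample`, `os_days` and
#'   optionally `event` (defaults to 1).
#' @return list of class `survival_comparison`: `groups`, `median_os`,
#'   `km_median_os`, `km_curves`, `logrank_chi2`, `logrank_p`.
#' @export
compare_predicted_groups <- function(eval, clinical) {
  common <- intersect(eval$sample_ids, clinical$sample)
  if (length(common) == 0L)
    stop("compare_predicted_groups: no overlap with clinical samples")
  cl <- clinical[match(common, clinical$sample), , drop = FALSE]
  if (is.null(cl$event)) cl$event <- 1L
  grp <- eval$predicted_label[match(common, eval$sample_ids)]
  names(grp) <- common
  if (length(unique(grp)) < 2L) {
    warning("compare_predicted_groups: a predicted group is empty; ",
            "degenerate comparison, p = 1")
    lr <- list(chi2 = 0, p = 1)
  } else {
    lr <- log_rank(cl$os_days, cl$event, grp)
  }
  med <- tapply(cl$os_days, grp, stats::median)
  km_curves <- lapply(split(seq_along(common), grp), function(i)
    km_estimate(cl$os_days[i], cl$event[i]))
  km_med <- vapply(km_curves, function(k) {
    i <- which(k$surv <= 0.5)
    if (length(i) == 0L) NA_real_ else k$time[min(i)]
  }, 0)
  structure(list(groups = grp,
                 median_os = med,
                 km_median_os = km_med,
                 km_curves = km_curves,
                 logrank_chi2 = lr$chi2,
                 logrank_p = lr$p),
            class = "survival_comparison")
}
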