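#' Fit the Gaussian naive Bayes PCPA model
#'
#' Class priors are the training class frequencies; each feature gets a
#' per-class mean and variance. Variances are floored at
#' `variance_floor` (default `1e-9` times the largest pooled feature
#' variance) so constant features cannot produce singular likelihoods.
#'
#' @param train features x samples training matrix.
#' @param labels a `cohort_labels` covering the training samples.
#' @param variance_floor positive variance floor; `NULL` for the default.
#' @return list of class `pcpa_model` with `family = "NB"`, `feature_ids`,
#'   `classes`, `prior`, `mean` and `var` (features x classes matrices) and
#'   `variance_floor`.
#' @export
fit_gaussian_nb <- function(train, labels, variance_floor = NULL) {
  lab <- labels$labels[colnames(train)]
  classes <- c("high-OS", "low-OS")
  if (!all(classes %in% lab))
    stop("fit_gaussian_nb: training data must contain both classes")
  if (is.null(variance_floor)) {
    pooled <- apply(train, 1L, stats::var)
    variance_floor <- 1e-9 * max(pooled, 1e-12)
  }
  mu <- sapply(classes, function(cl)
    rowMeans(train[, lab == cl, drop = FALSE]))
  va <- sapply(classes, function(cl)
    apply(train[, lab == cl, drop = FALSE], 1L, stats::var))
  va[is.na(va) | va < variance_floor] <- variance_floor
  dim(mu) <- dim(va) <- c(nrow(train), length(classes))
  dimnames(mu) <- dimnames(va) <- list(rownames(train), classes)
  prior <- as.vector(table(factor(lab, levels = classes))) / length(lab)
  names(prior) <- classes
  structure(list(family = "NB", feature_ids = rownames(train),
                 classes = classes, prior = prior, mean = mu, var = va,
                 variance_floor = variance_floor),
            class = "pcpa_model")
}

#' Posterior probability of the high-OS class
#'
#' For the naive Bayes family the posterior is computed as the log-sum of
#' per-feature Gaussian log-densities plus the log prior, normalized
#' across classes in log space, so thousands of features do not underflow.
#' Alternative families delegate to their backing fit.
#'
#' @param model a `pcpa_model`.
#' @param matrix features x samples matrix; its features must include all
#'   model features.
#' @return named numeric vector: probability of `"high-OS"` per sample.
#' @export
predict_proba <- function(model, matrix) {
  missing_f <- setdiff(model$feature_ids, rownames(matrix))
  if (length(missing_f))
    stop("predict_proba: matrix lacks model feature(s): ",
         paste(utils::head(missing_f, 5), collapse = ", "))
  x <- matrix[model$feature_ids, , drop = FALSE]
  if (model$family == "NB") {
    ll <- sapply(model$classes, function(cl) {
      colSums(stats::dnorm(x, mean = model$mean[, cl],
                           sd = sqrt(model$var[, cl]), log = TRUE)) +
        log(model$prior[[cl]])
    })
    if (ncol(x) == 1L) ll <- matrix(ll, nrow = 1L,
                                    dimnames = list(colnames(x),
                                                    model$classes))
    p <- 1 / (1 + exp(ll[, "low-OS"] - ll[, "high-OS"]))
    names(p) <- colnames(x)
    return(p)
  }
  predict_proba_alternative(model, x)
}

#' ROC curve and AUC by pairwise concordance
#'
#' The ROC is a threshold sweep over the unique predicted probabilities;
#' the AUC is the probability that a random positive outranks a random
#' negative, with half credit for ties (rank/Wilcoxon formula). Predicted
#' labels use a 0.5 threshold on `prob_high`.
#'
#' @param prob_high named numeric vector of high-OS probabilities.
#' @param truth character vector (or `cohort_labels`) of true classes,
#'   aligned with `prob_high`.
#' @return list of class `eval_report`: `sample_ids`, `prob_high`,
#'   `predicted_label`, `roc` (data.frame `fpr`, `tpr`), `auc`.
#' @export
roc_auc <- function(prob_high, truth) {
  if (inherits(truth, "cohort_labels")) truth <- truth$labels[names(prob_high)]
  pos <- truth == "high-OS"
  if (!any(pos) || all(pos))
    stop("roc_auc: need both classes in the truth labels")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  r <- rank(prob_high)
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(prob_high), decreasing = TRUE))
  roc <- data.frame(
    fpr = vapply(thr, function(t) mean(prob_high[!pos] >= t), 0),
    tpr = vapply(thr, function(t) mean(prob_high[pos] >= t), 0))
  predicted <- ifelse(prob_high >= 0.5, "high-OS", "low-OS")
  structure(list(sample_ids = names(prob_high), prob_high = prob_high,
                 predicted_label = predicted, roc = roc, auc = auc),
            class = "eval_report")
}

#' Serialize / restore a naive Bayes PCPA model as JSON
#'
#' NB is fully parametric, so the JSON round-trip is exact to double
#' precision.
#'
#' @param model a `pcpa_model` with `family = "NB"`.
#' @param path output file.
#' @return `path` invisibly; `model_from_json` returns the model.
#' @export
model_to_json <- function(model, path) {
  stopifnot(model$family == "NB")
  obj <- list(family = model$family, feature_ids = model$feature_ids,
              classes = model$classes, prior = model$prior,
              mean = model$mean, var = model$var,
              variance_floor = model$variance_floor)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mu <- as.matrix(obj$mean); va <- as.matrix(obj$var)
  dimnames(mu) <- dimnames(va) <- list(obj$feature_ids, obj$classes)
  prior <- stats::setNames(as.numeric(obj$prior), obj$classes)
  structure(list(family = obj$family, feature_ids = obj$feature_ids,
                 classes = obj$classes, prior = prior, mean = mu, var = va,
                 variance_floor = obj$variance_floor),
            class = "pcpa_model")
}

#' Fit an alternative classifier family (LR, SVM, NN)
#'
#' Thin adapters over standard implementations (`stats::glm`,
#' `e1071::svm`, `nnet::nnet`) exposing the same [predict_proba()]
#' contract. Hyperparameters come from `config`, otherwise library
#' defaults. These families exist for comparison only; the package's
#' default modeling path is [fit_gaussian_nb()].
#'
#' @param train features x samples training matrix.
#' @param labels a `cohort_labels`.
#' @param family `"LR"`, `"SVM"` or `"NN"`.
#' @param config named list of hyperparameters (`NN`: `size`, `decay`,
#'   `maxit`, `seed`).
#' @return a `pcpa_model` wrapping the backing fit.
#' @export
fit_alternative <- function(train, labels, family, config = list()) {
  if (!family %in% c("LR", "SVM", "NN"))
    stop("fit_alternative: unknown family '", family, "'")
  lab <- labels$labels[colnames(train)]
  y <- factor(lab, levels = c("low-OS", "high-OS"))
  df <- as.data.frame(t(train))
  names(df) <- make.names(names(df))
  fit <- switch(family,
    LR = suppressWarnings(stats::glm(y ~ ., data = cbind(y = y, df),
                                     family = stats::binomial())),
    SVM = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("fit_alternative: package 'e1071' required for SVM")
      e1071::svm(x = df, y = y, probability = TRUE)
    },
    NN = {
      if (!requireNamespace("nnet", quietly = TRUE))
        stop("fit_alternative: package 'nnet' required for NN")
      set.seed(config$seed %||% 1L)
      nnet::nnet(x = df, y = as.numeric(y) - 1,
                 size = config$size %||% 3L,
                 decay = config$decay %||% 1e-3,
                 maxit = config$maxit %||% 200L, trace = FALSE)
    })
  structure(list(family = family, feature_ids = rownames(train), fit = fit),
            class = "pcpa_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

predict_proba_alternative <- function(model, x) {
  df <- as.data.frame(t(x))
  names(df) <- make.names(names(df))
  p <- switch(model$family,
    LR = suppressWarnings(
      stats::predict(model$fit, newdata = df, type = "response")),
    SVM = {
      pr <- stats::predict(model$fit, newdata = df, probability = TRUE)
      attr(pr, "probabilities")[, "high-OS"]
    },
    NN = as.vector(stats::predict(model$fit, newdata = df)),
    stop("predict_proba: unknown family '", model$family, "'"))
  stats::setNames(as.numeric(p), colnames(x))
}
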