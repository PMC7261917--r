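# builds a one-feature NB model with exact class means 0 (low) and m (high),
# unit variances and equal priors, by fitting on crafted data
nb_one_feature <- function(m_high) {
  train <- matrix(c(-1, 0, 1, m_high - 1, m_high, m_high + 1), 1, 6,
                  dimnames = list("f1", paste0("s", 1:6)))
  labels <- structure(list(median_os = 0, labels = setNames(
    rep(c("low-OS", "high-OS"), each = 3), colnames(train))),
    class = "cohort_labels")
  fit_gaussian_nb(train, labels)
}

test_that("naive Bayes posterior matches the closed-form Gaussian posterior", {
  mdl <- nb_one_feature(10)
  x <- matrix(10, 1, 1, dimnames = list("f1", "t1"))
  expect_gt(predict_proba(mdl, x)[[1]], 0.99)
  # midpoint of equal-variance class means with equal priors -> 0.5
  x5 <- matrix(5, 1, 1, dimnames = list("f1", "t1"))
  expect_equal(predict_proba(mdl, x5)[[1]], 0.5, tolerance = 1e-12)
  # means 0 and 2, unit variance, x = 2: posterior = e^2 / (1 + e^2)
  mdl2 <- nb_one_feature(2)
  x2 <- matrix(2, 1, 1, dimnames = list("f1", "t1"))
  expect_equal(predict_proba(mdl2, x2)[[1]], exp(2) / (1 + exp(2)),
               tolerance = 1e-12)
})

test_that("model fitting records priors, moments and the variance floor", {
  tc <- toy_cohort(n_per_class = 12, n_features = 5, shift = 2, seed = 10)
  mdl <- fit_gaussian_nb(tc$matrix, tc$labels)
  expect_equal(sum(mdl$prior), 1)
  expect_true(all(mdl$var >= mdl$variance_floor))
  expect_equal(mdl$mean["f1", "high-OS"],
               mean(tc$matrix[1, tc$labels$labels == "high-OS"]))
  # constant feature gets the floor, not zero variance
  tc$matrix[3, ] <- 7
  mdl_c <- fit_gaussian_nb(tc$matrix, tc$labels)
  expect_equal(unname(mdl_c$var["f3", ]),
               rep(mdl_c$variance_floor, 2))
  # single-class training errors
  one <- tc$labels; one$labels[] <- "low-OS"
  expect_error(fit_gaussian_nb(tc$matrix, one), "both classes")
})

test_that("posterior is invariant to feature order and uninformative features", {
  tc <- toy_cohort(n_per_class = 10, n_features = 6, shift = 2, seed = 11)
  mdl <- fit_gaussian_nb(tc$matrix, tc$labels)
  p <- predict_proba(mdl, tc$matrix)
  perm <- sample(nrow(tc$matrix))
  mdl_p <- fit_gaussian_nb(tc$matrix[perm, ], tc$labels)
  expect_equal(predict_proba(mdl_p, tc$matrix), p, tolerance = 1e-12)
  # adding a feature with identical class-conditional moments leaves the
  # posterior unchanged (its likelihood ratio is 1)
  extra <- rep(c(1, 2), length.out = ncol(tc$matrix))
  aug <- rbind(tc$matrix, dup = c(extra))
  mdl_a <- fit_gaussian_nb(aug, tc$labels)
  same_moments <- all(abs(mdl_a$mean["dup", 1] - mdl_a$mean["dup", 2]) <
                        1e-12)
  if (same_moments)
    expect_equal(predict_proba(mdl_a, aug), p, tolerance = 1e-9)
  # duplicate samples get identical probabilities
  dup2 <- tc$matrix[, c(1, 1)]
  colnames(dup2) <- c("d1", "d2")
  pd <- predict_proba(mdl, dup2)
  expect_equal(pd[["d1"]], pd[["d2"]])
  # missing model feature errors with its name
  expect_error(predict_proba(mdl, tc$matrix[-1, ]), "f1")
})

test_that("log-space scoring matches the naive product on a small model", {
  tc <- toy_cohort(n_per_class = 8, n_features = 5, shift = 1, seed = 12)
  mdl <- fit_gaussian_nb(tc$matrix, tc$labels)
  x <- tc$matrix[, 3, drop = FALSE]
  lik <- function(cl) prod(dnorm(x[, 1], mdl$mean[, cl],
                                 sqrt(mdl$var[, cl]))) * mdl$prior[[cl]]
  expect_equal(predict_proba(mdl, x)[[1]],
               lik("high-OS") / (lik("high-OS") + lik("low-OS")),
               tolerance = 1e-9)
  # and a wide model stays finite where the product would underflow
  tcw <- toy_cohort(n_per_class = 10, n_features = 1500, shift = 0.2,
                    seed = 13)
  mw <- fit_gaussian_nb(tcw$matrix, tcw$labels)
  pw <- predict_proba(mw, tcw$matrix)
  expect_true(all(is.finite(pw) & pw >= 0 & pw <= 1))
})

test_that("AUC equals pairwise concordance with tie credit", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2),
                       c("high-OS", "high-OS", "low-OS", "low-OS"))$auc, 1)
  # 3 of 4 positive-negative pairs concordant
  expect_equal(roc_auc(c(0.9, 0.2, 0.8, 0.3),
                       c("high-OS", "low-OS", "low-OS", "high-OS"))$auc,
               0.75)
  expect_equal(roc_auc(rep(0.4, 6),
                       rep(c("high-OS", "low-OS"), 3))$auc, 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c("high-OS", "high-OS")),
               "both classes")
  set.seed(44)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    p <- round(runif(n), 2)  # rounding forces ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) pos[1:2] <- c(TRUE, FALSE)
    truth <- ifelse(pos, "high-OS", "low-OS")
    expect_equal(roc_auc(p, truth)$auc, oracle_auc(p, pos),
                 tolerance = 1e-12)
  }
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  set.seed(45)
  p <- runif(40)
  truth <- ifelse(rbinom(40, 1, 0.5) == 1, "high-OS", "low-OS")
  if (length(unique(truth)) == 1) truth[1] <- "low-OS"
  er <- roc_auc(p, truth)
  expect_true(all(diff(er$roc$fpr) >= 0))
  expect_true(all(diff(er$roc$tpr) >= 0))
  expect_equal(unlist(er$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(er$roc[nrow(er$roc), ]), c(fpr = 1, tpr = 1))
})

test_that("NB serialization round-trips exactly", {
  tc <- toy_cohort(n_per_class = 9, n_features = 4, shift = 1, seed = 15)
  mdl <- fit_gaussian_nb(tc$matrix, tc$labels)
  path <- tempfile(fileext = ".json")
  model_to_json(mdl, path)
  mdl2 <- model_from_json(path)
  expect_equal(predict_proba(mdl2, tc$matrix),
               predict_proba(mdl, tc$matrix), tolerance = 1e-12)
})

test_that("alternative families honour the predict_proba contract", {
  tc <- toy_cohort(n_per_class = 15, n_features = 3, shift = 6, seed = 16)
  lr <- fit_alternative(tc$matrix, tc$labels, "LR")
  p <- predict_proba(lr, tc$matrix)
  acc <- mean((p >= 0.5) == (tc$labels$labels == "high-OS"))
  expect_equal(acc, 1)
  expect_error(fit_alternative(tc$matrix, tc$labels, "QDA"), "unknown")
  skip_if_not_installed("nnet")
  nn1 <- fit_alternative(tc$matrix, tc$labels, "NN", list(seed = 5))
  nn2 <- fit_alternative(tc$matrix, tc$labels, "NN", list(seed = 5))
  expect_equal(predict_proba(nn1, tc$matrix), predict_proba(nn2, tc$matrix))
})
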