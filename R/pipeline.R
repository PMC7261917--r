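#' Run the full prognosis pipeline on one cohort
#'
#' Chains the per-cancer stages: median-OS labeling, per-omic differential
#' expression, merging the selected features, the class-stratified spatial
#' split (with the factor-analysis reduction when the training count would
#' fall below `fa_threshold`), Gaussian naive Bayes fitting, held-out
#' ROC/AUC, the predicted-group survival comparison, and the MOS scan over
#' the cohort's miRNA markers on the test-set low-OS samples.
#'
#' @param cohort list with `cancer`, `mirna`, `lncrna`, `clinical` (as
#'   produced by [simulate_cancer_cohort()], or assembled from ingest).
#' @param split_seed seed for the spatial split's per-class seed samples.
#' @param train_fraction per-class training fraction.
#' @param fa_threshold training-sample count below which the combined
#'   feature matrix is reduced by [factor_reduce()].
#' @param fa_top features kept per factor in the reduction.
#' @param epsilon MOS flagging threshold.
#' @return list with `cancer`, `labels`, `de_mirna`, `de_lncrna`,
#'   `mirna_markers`, `lncrna_markers`, `split`, `model`, `eval`,
#'   `survival`, `mos`.
#' @export
run_cancer_pipeline <- function(cohort, split_seed = 1L,
                                train_fraction = 2 / 3,
                                fa_threshold = 50L, fa_top = 10L,
                                epsilon = 1e-6) {
  labels <- label_by_median_os(cohort$clinical)
  de_mir <- detect_de(cohort$mirna, labels, "miRNA", cancer = cohort$cancer)
  de_lnc <- detect_de(cohort$lncrna, labels, "lncRNA",
                      cancer = cohort$cancer)
  mir_mk <- de_mir$markers$markers
  lnc_mk <- de_lnc$markers$markers
  if (length(mir_mk) + length(lnc_mk) == 0L)
    stop("run_cancer_pipeline: no markers detected for ", cohort$cancer)
  x <- merge_omics(cohort$mirna[mir_mk, , drop = FALSE],
                   cohort$lncrna[lnc_mk, , drop = FALSE])
  n_train_expected <- floor(train_fraction * ncol(x) + 0.5)
  if (n_train_expected < fa_threshold && nrow(x) > fa_top) {
    sel <- factor_reduce(x, n_top = fa_top)
    x <- x[sel, , drop = FALSE]
    mir_mk <- intersect(mir_mk, sel)
    lnc_mk <- intersect(lnc_mk, sel)
  }
  split <- spatial_subset_split(x, labels, train_fraction, split_seed)
  train <- x[, split$train_ids, drop = FALSE]
  test <- x[, split$test_ids, drop = FALSE]
  model <- fit_gaussian_nb(train, labels)
  eval <- roc_auc(predict_proba(model, test),
                  labels$labels[colnames(test)])
  surv <- compare_predicted_groups(eval, cohort$clinical)
  mos <- NULL
  if (length(mir_mk)) {
    low_test <- split$test_ids[
      labels$labels[split$test_ids] == "low-OS"]
    if (length(low_test)) {
      refs <- high_os_reference(train, labels, mir_mk)
      mos <- mos_scan(model, x[, low_test, drop = FALSE], mir_mk, refs,
                      epsilon = epsilon, cancer = cohort$cancer)
    }
  }
  list(cancer = cohort$cancer, labels = labels,
       de_mirna = de_mir, de_lncrna = de_lnc,
       mirna_markers = marker_set(cohort$cancer, "miRNA", mir_mk),
       lncrna_markers = marker_set(cohort$cancer, "lncRNA", lnc_mk),
       split = split, model = model, eval = eval, survival = surv,
       mos = mos)
}

#' Run the pipeline over a pan-cancer bundle
#'
#' Applies [run_cancer_pipeline()] to every cohort and assembles the
#' cross-cancer layers: the marker incidence matrix and per-omic sharing
#' summary, the refined-pathway regulation matrix, and the MOS
#' alternative-marker sets per cancer.
#'
#' @param bundle a pan-cancer bundle from [simulate_pan_cancer()] (or an
#'   equivalently shaped list with `cohorts`, `targets`, `pathways`).
#' @param split_seed,... passed to [run_cancer_pipeline()].
#' @return list with `per_cancer` (pipeline results by cancer),
#'   `incidence`, `sharing` (per-omic summary data.frame), `regulation`
#'   (cancer x pathway fraction matrix over refined pathways) and
#'   `alternative_markers` (named list per cancer).
#' @export
run_pan_cancer_pipeline <- function(bundle, split_seed = 1L, ...) {
  per_cancer <- lapply(bundle$cohorts, run_cancer_pipeline,
                       split_seed = split_seed, ...)
  # incidence wants unique cancer columns, so build per omic and merge rows
  inc_mir <- build_incidence(lapply(per_cancer, `[[`, "mirna_markers"))
  inc_lnc <- build_incidence(lapply(per_cancer, `[[`, "lncrna_markers"))
  incidence <- structure(
    list(incidence = rbind(inc_mir$incidence, inc_lnc$incidence),
         omic = c(inc_mir$omic, inc_lnc$omic)),
    class = "incidence_matrix")
  sharing <- sharing_summary(incidence)
  refined <- refine_pathways(bundle$pathways)
  regulation <- regulation_matrix(lapply(per_cancer, `[[`, "mirna_markers"),
                                  bundle$targets, refined)
  alt <- lapply(per_cancer, function(pc)
    if (is.null(pc$mos)) character(0) else pc$mos$alternative_markers)
  list(per_cancer = per_cancer, incidence = incidence, sharing = sharing,
       regulation = regulation, alternative_markers = alt)
}

#' Marker-recovery study on synthetic pan-cancer data
#'
#' Generates a pan-cancer dataset per seed, runs the full pipeline, and
#' scores it against the planted ground truth: differential-expression
#' recovery of planted markers (pooled and per omic), the null miRNA
#' pass rate, mean held-out AUC, the MOS flag rates for planted
#' protective miRNAs and for null miRNAs, and the per-omic recovered
#' sharing fractions.
#'
#' @param seeds integer vector of generator seeds (one replicate each).
#' @param config_args named list of overrides passed to [sim_config()]
#'   (`seed` is supplied per replicate).
#' @return data.frame with one row per seed: `seed`, `de_recovery`,
#'   `de_recovery_mirna`, `de_recovery_lncrna`, `null_pass_rate`,
#'   `mean_auc`, `mos_sensitivity`, `mos_null_rate`,
#'   `mirna_shared_fraction`, `lncrna_shared_fraction`.
#' @export
recovery_study <- function(seeds, config_args = list()) {
  one <- function(sd) {
    cfg <- do.call(sim_config, c(list(seed = sd), config_args))
    bundle <- simulate_pan_cancer(cfg)
    res <- run_pan_cancer_pipeline(bundle, split_seed = sd)
    truth <- bundle$truth
    rec <- vapply(names(res$per_cancer), function(cn) {
      pc <- res$per_cancer[[cn]]
      pl <- truth$planted_markers[[cn]]
      c(mir_hit = sum(pl$mirna %in% pc$de_mirna$markers$markers),
        mir_n = length(pl$mirna),
        lnc_hit = sum(pl$lncrna %in% pc$de_lncrna$markers$markers),
        lnc_n = length(pl$lncrna),
        null_pass = sum(!pc$de_mirna$markers$markers %in% pl$mirna),
        null_n = cfg$n_mirna - length(pl$mirna))
    }, numeric(6))
    aucs <- vapply(res$per_cancer, function(pc) pc$eval$auc, 0)
    protective <- names(truth$direction)[truth$direction == "protective"]
    mos_stats <- vapply(names(res$per_cancer), function(cn) {
      pc <- res$per_cancer[[cn]]
      pl <- truth$planted_markers[[cn]]$mirna
      prot <- intersect(pl, protective)
      flagged <- if (is.null(pc$mos)) character(0) else
        pc$mos$alternative_markers
      nulls <- setdiff(rownames(bundle$cohorts[[cn]]$mirna), pl)
      c(prot_flag = sum(prot %in% flagged), prot_n = length(prot),
        null_flag = sum(flagged %in% nulls), null_n = length(nulls))
    }, numeric(4))
    sh <- res$sharing
    data.frame(
      seed = sd,
      de_recovery = (sum(rec["mir_hit", ]) + sum(rec["lnc_hit", ])) /
        (sum(rec["mir_n", ]) + sum(rec["lnc_n", ])),
      de_recovery_mirna = sum(rec["mir_hit", ]) / sum(rec["mir_n", ]),
      de_recovery_lncrna = sum(rec["lnc_hit", ]) / sum(rec["lnc_n", ]),
      null_pass_rate = sum(rec["null_pass", ]) / sum(rec["null_n", ]),
      mean_auc = mean(aucs),
      mos_sensitivity = sum(mos_stats["prot_flag", ]) /
        sum(mos_stats["prot_n", ]),
      mos_null_rate = sum(mos_stats["null_flag", ]) /
        sum(mos_stats["null_n", ]),
      mirna_shared_fraction =
        sh$shared_fraction[sh$omic == "miRNA"],
      lncrna_shared_fraction =
        sh$shared_fraction[sh$omic == "lncRNA"])
  }
  do.call(rbind, lapply(seeds, one))
}
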