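#' Configuration for the synthetic pan-cancer generator
#'
#' Bundles every knob of the synthetic data generator into a validated list.
#' The defaults describe the study conditions the rest of the package is
#' exercised under: a small pan-cancer panel of cohorts whose overall
#' survival is driven by a handful of planted ncRNA markers — miRNA markers
#' planted with the same identity in every cancer, lncRNA markers planted in
#' exactly one cancer each, mirroring the empirical sharing asymmetry
#' between the two omics.
#'
#' Expression for feature f in a cohort is drawn as
#' `Normal(mu_f, expr_noise_sd)` on the log2(x+1) scale, with `mu_f` drawn
#' once per feature from `Normal(baseline_log2_mean, baseline_log2_sd)`.
#' Survival time per sample is exponential with
#' `log-hazard = log(baseline_hazard) + sum(+/- effect_size_beta * z_m)`
#' over planted markers m (z_m the cohort z-score of the marker's
#' expression; the sign is negative for protective markers). An independent
#' exponential censoring time gives an expected censored fraction of about
#' `censoring_rate`.
#'
#' @param n_cancers number of cancer cohorts.
#' @param samples_per_cancer samples per cohort.
#' @param n_mirna,n_lncrna features per omic.
#' @param n_shared_mirna_markers miRNA markers planted (same identity) in
#'   every cancer.
#' @param n_specific_lncrna_markers_per_cancer lncRNA markers planted in
#'   exactly one cancer each; allocations are disjoint across cancers.
#' @param effect_size_beta per-marker log-hazard coefficient magnitude.
#' @param baseline_hazard baseline event rate (events/day).
#' @param censoring_rate expected censored fraction, in `[0, 1]`.
#' @param expr_noise_sd per-feature expression SD, log2 units.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-feature
#'   baseline means, log2 units.
#' @param n_genes size of the target-gene universe.
#' @param targets_per_mirna genes assigned to each miRNA in the target map.
#' @param n_pathways,pathway_size,pathway_overlap chain-overlap pathway
#'   construction: consecutive pathways share exactly `pathway_overlap`
#'   genes.
#' @param weibull_shape Weibull shape of the survival-time distribution;
#'   the default 1 gives exponential times.
#' @param emit_linear emit linear-scale (`2^x - 1`) expression matrices
#'   instead of log2, for exercising ingest's transform path.
#' @param seed root seed; all randomness derives from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cancers = 3,
                       samples_per_cancer = 400,
                       n_mirna = 150,
                       n_lncrna = 150,
                       n_shared_mirna_markers = 4,
                       n_specific_lncrna_markers_per_cancer = 2,
                       effect_size_beta = 1.0,
                       baseline_hazard = 1 / 1000,
                       censoring_rate = 0,
                       expr_noise_sd = 2.5,
                       baseline_log2_mean = 3,
                       baseline_log2_sd = 1.5,
                       n_genes = 200,
                       targets_per_mirna = 10,
                       n_pathways = 8,
                       pathway_size = 20,
                       pathway_overlap = 3,
                       weibull_shape = 1,
                       emit_linear = FALSE,
                       seed = 1L) {
  cfg <- list(
    n_cancers = as.integer(n_cancers),
    samples_per_cancer = as.integer(samples_per_cancer),
    n_mirna = as.integer(n_mirna),
    n_lncrna = as.integer(n_lncrna),
    n_shared_mirna_markers = as.integer(n_shared_mirna_markers),
    n_specific_lncrna_markers_per_cancer =
      as.integer(n_specific_lncrna_markers_per_cancer),
    effect_size_beta = effect_size_beta,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    expr_noise_sd = expr_noise_sd,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    n_genes = as.integer(n_genes),
    targets_per_mirna = as.integer(targets_per_mirna),
    n_pathways = as.integer(n_pathways),
    pathway_size = as.integer(pathway_size),
    pathway_overlap = as.integer(pathway_overlap),
    weibull_shape = weibull_shape,
    emit_linear = isTRUE(emit_linear),
    seed = as.integer(seed)
  )
  counts <- c("n_cancers", "n_mirna", "n_lncrna", "n_shared_mirna_markers",
              "n_specific_lncrna_markers_per_cancer", "n_genes",
              "targets_per_mirna", "n_pathways", "pathway_size",
              "pathway_overlap")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L)
      stop("sim_config: '", nm, "' must be a nonnegative count")
  }
  if (cfg$n_shared_mirna_markers > cfg$n_mirna)
    stop("sim_config: n_shared_mirna_markers exceeds n_mirna")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate > 1)
    stop("sim_config: censoring_rate must lie in [0, 1]")
  if (cfg$expr_noise_sd <= 0 || cfg$baseline_hazard <= 0)
    stop("sim_config: expr_noise_sd and baseline_hazard must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# stable per-component seed stream: component 0 = marker allocation,
# 1..n_cancers = cohorts, n_cancers + 1 = pathways/targets.  Kept below
# 2^31 - 1 so it is a valid R integer seed.
derive_seed <- function(seed, component) {
  as.integer((as.double(seed) * 7919 + as.double(component) * 104729 + 17) %%
               2147483647)
}

mirna_ids <- function(n) sprintf("mir_%03d", seq_len(n))
lncrna_ids <- function(n) sprintf("lnc_%03d", seq_len(n))
gene_ids <- function(n) sprintf("gene_%03d", seq_len(n))

# Global marker allocation: which feature identities are planted where, and
# each marker's direction.  Deterministic in config$seed alone, so every
# cohort agrees on it.  Directions alternate by position in the planted
# list: odd = protective, even = hazardous.
allocate_markers <- function(config) {
  set.seed(derive_seed(config$seed, 0L))
  mir <- mirna_ids(config$n_mirna)
  lnc <- lncrna_ids(config$n_lncrna)
  n_spec_total <- config$n_cancers * config$n_specific_lncrna_markers_per_cancer
  if (n_spec_total > config$n_lncrna)
    stop("allocate_markers: cannot plant ", n_spec_total,
         " disjoint cancer-specific lncRNA markers among ", config$n_lncrna,
         " lncRNAs")
  shared <- sort(sample(mir, config$n_shared_mirna_markers))
  spec_pool <- sort(sample(lnc, n_spec_total))
  per_cancer <- split(spec_pool,
                      rep(seq_len(config$n_cancers),
                          each = config$n_specific_lncrna_markers_per_cancer))
  dir_of <- function(ids) {
    if (length(ids) == 0) return(character(0))
    stats::setNames(ifelse(seq_along(ids) %% 2 == 1, "protective",
                           "hazardous"), ids)
  }
  direction <- c(dir_of(shared), dir_of(spec_pool))
  list(shared_mirna = shared,
       specific_lncrna = per_cancer,
       direction = direction)
}

#' Simulate one cancer cohort
#'
#' Draws the miRNA and lncRNA expression matrices, the clinical table and
#' the ground-truth slice for one cancer, reproducibly from
#' `config$seed` and `cancer_id` alone (adding a cancer never perturbs the
#' others).
#'
#' @param config a [sim_config()].
#' @param cancer_id integer cohort index in `1..n_cancers`.
#' @return list with elements `cancer` (label `"C<id>"`), `mirna` and
#'   `lncrna` (features x samples matrices, log2 scale unless
#'   `config$emit_linear`), `clinical` (data.frame `sample`, `os_days`,
#'   `event`), and `truth` (planted marker ids and directions).
#' @export
simulate_cancer_cohort <- function(config, cancer_id) {
  stopifnot(inherits(config, "sim_config"))
  if (config$samples_per_cancer <= 0L)
    stop("simulate_cancer_cohort: samples_per_cancer must be positive")
  cancer_id <- as.integer(cancer_id)
  if (cancer_id < 1L || cancer_id > config$n_cancers)
    stop("simulate_cancer_cohort: cancer_id out of range")
  alloc <- allocate_markers(config)
  set.seed(derive_seed(config$seed, cancer_id))
  cancer <- sprintf("C%02d", cancer_id)
  n <- config$samples_per_cancer
  samples <- sprintf("%s_s%03d", cancer, seq_len(n))

  draw_matrix <- function(ids) {
    mu <- stats::rnorm(length(ids), config$baseline_log2_mean,
                       config$baseline_log2_sd)
    m <- matrix(stats::rnorm(length(ids) * n, mean = mu,
                             sd = config$expr_noise_sd),
                nrow = length(ids), ncol = n,
                dimnames = list(ids, samples))
    m
  }
  mirna <- draw_matrix(mirna_ids(config$n_mirna))
  lncrna <- draw_matrix(lncrna_ids(config$n_lncrna))

  planted_mir <- alloc$shared_mirna
  planted_lnc <- alloc$specific_lncrna[[cancer_id]]
  zscore <- function(v) if (stats::sd(v) == 0) rep(0, length(v)) else
    (v - mean(v)) / stats::sd(v)
  loghaz <- rep(log(config$baseline_hazard), n)
  for (mk in planted_mir) {
    s <- if (alloc$direction[[mk]] == "protective") -1 else 1
    loghaz <- loghaz + s * config$effect_size_beta * zscore(mirna[mk, ])
  }
  for (mk in planted_lnc) {
    s <- if (alloc$direction[[mk]] == "protective") -1 else 1
    loghaz <- loghaz + s * config$effect_size_beta * zscore(lncrna[mk, ])
  }
  # proportional-hazards Weibull: S(t) = exp(-exp(loghaz) * t^shape);
  # shape 1 reduces to exponential with rate exp(loghaz)
  k <- config$weibull_shape
  t_event <- stats::rweibull(n, shape = k, scale = exp(-loghaz / k))
  if (config$censoring_rate > 0) {
    c_rate <- config$baseline_hazard * config$censoring_rate /
      (1 - config$censoring_rate)
    t_cens <- stats::rexp(n, rate = c_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  clinical <- data.frame(sample = samples, os_days = time, event = event,
                         stringsAsFactors = FALSE)
  if (config$emit_linear) {
    mirna <- 2^mirna - 1
    lncrna <- 2^lncrna - 1
  }
  list(cancer = cancer,
       mirna = mirna,
       lncrna = lncrna,
       clinical = clinical,
       truth = list(
         mirna_markers = planted_mir,
         lncrna_markers = planted_lnc,
         direction = alloc$direction[c(planted_mir, planted_lnc)]))
}

#' Simulate a full pan-cancer dataset
#'
#' Runs [simulate_cancer_cohort()] for every cancer and
#' [simulate_pathways_and_targets()] once, returning the cohort bundle, the
#' pan-cancer ground truth, the miRNA target map and the pathway
#' collection. Two calls with equal configs produce identical output.
#'
#' @param config a [sim_config()].
#' @return list with `cohorts` (named by cancer label), `truth`
#'   (`planted_markers` per cancer, `direction`), `targets` (named list
#'   miRNA -> gene vector) and `pathways` (a pathway collection, see
#'   [read_gmt()]).
#' @export
simulate_pan_cancer <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  alloc <- allocate_markers(config)
  cohorts <- lapply(seq_len(config$n_cancers), function(i)
    simulate_cancer_cohort(config, i))
  names(cohorts) <- vapply(cohorts, `[[`, "", "cancer")
  pt <- simulate_pathways_and_targets(config)
  planted <- lapply(seq_len(config$n_cancers), function(i)
    list(mirna = alloc$shared_mirna,
         lncrna = alloc$specific_lncrna[[i]]))
  names(planted) <- names(cohorts)
  list(cohorts = cohorts,
       truth = list(planted_markers = planted, direction = alloc$direction),
       targets = pt$targets,
       pathways = pt$pathways)
}

#' Simulate pathway gene sets and a miRNA target map
#'
#' Builds `n_pathways` gene sets of `pathway_size` genes in a chain where
#' consecutive pathways share exactly `pathway_overlap` genes, and assigns
#' `targets_per_mirna` distinct target genes to every miRNA. Each planted
#' shared miRNA marker is guaranteed at least one target gene unique to a
#' single pathway, so refined-pathway regulation fractions are nonzero by
#' construction.
#'
#' @param config a [sim_config()].
#' @return list with `pathways` (pathway collection) and `targets`
#'   (named list miRNA -> character vector of genes).
#' @export
simulate_pathways_and_targets <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$pathway_overlap >= config$pathway_size)
    stop("simulate_pathways_and_targets: pathway_overlap must be < pathway_size")
  if (config$n_genes < config$n_pathways * config$pathway_size)
    stop("simulate_pathways_and_targets: n_genes too small for ",
         config$n_pathways, " pathways of ", config$pathway_size)
  alloc <- allocate_markers(config)
  set.seed(derive_seed(config$seed, config$n_cancers + 1L))
  genes <- gene_ids(config$n_genes)
  step <- config$pathway_size - config$pathway_overlap
  pw_names <- c("PI3K", "MAPK", "Cell_cycle", "Wnt", "P53", "Hippo", "TGFb",
                "Notch")
  if (config$n_pathways <= length(pw_names)) {
    nms <- pw_names[seq_len(config$n_pathways)]
  } else {
    nms <- c(pw_names, sprintf("pathway_%02d",
                               seq(length(pw_names) + 1, config$n_pathways)))
  }
  sets <- lapply(seq_len(config$n_pathways), function(p) {
    start <- (p - 1L) * step
    genes[(start + 1L):(start + config$pathway_size)]
  })
  names(sets) <- nms
  pathways <- pathway_collection(sets, refined = FALSE)

  multiplicity <- table(unlist(sets))
  unique_genes <- names(multiplicity)[multiplicity == 1]
  mirs <- mirna_ids(config$n_mirna)
  targets <- lapply(mirs, function(m)
    sort(sample(genes, config$targets_per_mirna)))
  names(targets) <- mirs
  for (mk in alloc$shared_mirna) {
    if (!any(targets[[mk]] %in% unique_genes)) {
      repl <- sample(unique_genes, 1)
      targets[[mk]] <- sort(c(targets[[mk]][-1], repl))
    }
  }
  list(pathways = pathways, targets = targets)
}
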