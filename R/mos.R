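#' High-OS reference expression levels for markers
#'
#' The reference level of a marker is the mean (or median) of its
#' expression among high-OS training samples; low-OS samples never enter
#' the reference.
#'
#' @param train features x samples training matrix.
#' @param labels a `cohort_labels` covering the training samples.
#' @param markers character vector of marker feature IDs.
#' @param stat `"mean"` (default) or `"median"`.
#' @return named numeric vector, marker -> reference level.
#' @export
high_os_reference <- function(train, labels, markers,
                              stat = c("mean", "median")) {
  stat <- match.arg(stat)
  missing_m <- setdiff(markers, rownames(train))
  if (length(missing_m))
    stop("high_os_reference: marker(s) absent from matrix: ",
         paste(utils::head(missing_m, 5), collapse = ", "))
  lab <- labels$labels[colnames(train)]
  hi <- which(lab == "high-OS")
  if (length(hi) < 2L)
    stop("high_os_reference: need >= 2 high-OS training samples")
  sub <- train[markers, hi, drop = FALSE]
  if (stat == "mean") rowMeans(sub) else apply(sub, 1L, stats::median)
}

#' Marker-oriented simulation (MOS) counterfactual scan
#'
#' For each marker independently, every low-OS sample whose expression of
#' that marker lies below its high-OS reference level is raised to the
#' reference — all other features untouched — and the samples are
#' re-scored by the PCPA model. The marker's `mean_delta` is the mean
#' change in high-OS probability over the perturbed samples; a marker is
#' flagged prognosis-alternative when at least one sample was perturbed
#' and `mean_delta > epsilon`. Input matrices are never modified.
#'
#' @param model a fitted `pcpa_model` whose feature space contains the
#'   markers.
#' @param low_os_samples features x samples matrix of low-OS samples
#'   (typically the test-set low-OS samples).
#' @param markers character vector of miRNA marker IDs to scan.
#' @param references named vector of reference levels
#'   (see [high_os_reference()]).
#' @param epsilon nonnegative flagging threshold on `mean_delta`.
#' @param cancer identifier stored in the report.
#' @return list of class `mos_report`: `cancer`, `per_marker` (data.frame
#'   `marker`, `mean_delta`, `n_perturbed`, `flagged`),
#'   `alternative_markers`, `epsilon`.
#' @export
mos_scan <- function(model, low_os_samples, markers, references,
                     epsilon = 1e-6, cancer = NA_character_) {
  if (ncol(low_os_samples) == 0L)
    stop("mos_scan: no low-OS samples to perturb")
  missing_m <- setdiff(markers, model$feature_ids)
  if (length(missing_m))
    stop("mos_scan: model lacks marker(s): ",
         paste(utils::head(missing_m, 5), collapse = ", "))
  before <- predict_proba(model, low_os_samples)
  rows <- lapply(markers, function(mk) {
    idx <- which(low_os_samples[mk, ] < references[[mk]])
    if (length(idx) == 0L)
      return(data.frame(marker = mk, mean_delta = 0, n_perturbed = 0L,
                        flagged = FALSE, stringsAsFactors = FALSE))
    pert <- low_os_samples
    pert[mk, idx] <- references[[mk]]
    after <- predict_proba(model, pert[, idx, drop = FALSE])
    delta <- mean(after - before[idx])
    data.frame(marker = mk, mean_delta = delta,
               n_perturbed = length(idx),
               flagged = delta > epsilon, stringsAsFactors = FALSE)
  })
  per_marker <- do.call(rbind, rows)
  structure(list(cancer = cancer, per_marker = per_marker,
                 alternative_markers = per_marker$marker[per_marker$flagged],
                 epsilon = epsilon),
            class = "mos_report")
}

#' Common candidate target genes per cancer category
#'
#' For each category of the taxonomy, intersects (over its member cancers
#' present in the input) the sets of genes targeted by each cancer's
#' prognosis-alternative markers, restricted to the union of the canonical
#' pathway gene sets (unrefined). With `combine = "union"` the per-cancer
#' gene sets are united instead.
#'
#' @param alternative_markers_by_cancer named list, cancer -> character
#'   vector of prognosis-alternative miRNA markers.
#' @param targets named list, miRNA -> gene vector.
#' @param pathways a `pathway_collection` (its unrefined union restricts
#'   the candidate genes).
#' @param taxonomy data.frame `cancer_type`, `category` (see
#'   [cancer_taxonomy()]).
#' @param combine `"intersection"` (default) or `"union"` across member
#'   cancers.
#' @return named list per category, each with `category`, `cancers`,
#'   `n_markers` (distinct alternative markers across member cancers),
#'   `common_genes`, and `support` (for each common gene, the supporting
#'   markers per cancer).
#' @export
category_common_genes <- function(alternative_markers_by_cancer, targets,
                                  pathways, taxonomy,
                                  combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  pw_union <- unique(unlist(pathways$sets))
  cats <- split(taxonomy$cancer_type, taxonomy$category)
  out <- list()
  for (cat in names(cats)) {
    members <- intersect(cats[[cat]],
                         names(alternative_markers_by_cancer))
    if (length(members) == 0L) next
    if (length(members) == 1L)
      message("category_common_genes: category '", cat,
              "' has a single cancer; common genes are that cancer's set")
    per_cancer_genes <- lapply(members, function(cn) {
      mks <- alternative_markers_by_cancer[[cn]]
      intersect(unique(unlist(targets[mks])), pw_union)
    })
    common <- if (combine == "intersection")
      Reduce(intersect, per_cancer_genes) else
      Reduce(union, per_cancer_genes)
    common <- sort(common)
    support <- lapply(stats::setNames(common, common), function(g)
      lapply(stats::setNames(members, members), function(cn) {
        mks <- alternative_markers_by_cancer[[cn]]
        mks[vapply(mks, function(m) g %in% targets[[m]], NA)]
      }))
    out[[cat]] <- list(
      category = cat, cancers = members,
      n_markers = length(unique(unlist(
        alternative_markers_by_cancer[members]))),
      common_genes = common, support = support)
  }
  out
}

#' Annotate genes against the known drug-target table
#'
#' Left-joins the genes against a gene -> drug table (the bundled
#' synthetic fixture by default); genes without annotation are retained
#' with an empty drug list.
#'
#' @param genes character vector of gene symbols.
#' @param drug_target_table data.frame with columns `gene`, `drug`, or a
#'   TSV path; `NULL` uses the bundled fixture.
#' @return named list, gene -> character vector of drugs (possibly
#'   empty).
#' @export
annotate_known_targets <- function(genes, drug_target_table = NULL) {
  if (is.null(drug_target_table))
    drug_target_table <- system.file("extdata",
                                     "known_drug_targets_synthetic.tsv",
                                     package = "panprog")
  if (is.character(drug_target_table))
    drug_target_table <- utils::read.delim(drug_target_table, sep = "\t",
                                           stringsAsFactors = FALSE)
  lapply(stats::setNames(genes, genes), function(g)
    drug_target_table$drug[drug_target_table$gene == g])
}
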