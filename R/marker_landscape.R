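#' Binary marker x cancer incidence matrix
#'
#' Rows are the deduplicated union of all markers, columns the cancers;
#' entry 1 iff the marker belongs to that cancer's set. Each marker keeps
#' its omic tag.
#'
#' @param marker_sets list of [marker_set()] objects with unique cancer
#'   identifiers.
#' @return list of class `incidence_matrix`: `incidence` (0/1 matrix) and
#'   `omic` (named character vector per marker).
#' @export
build_incidence <- function(marker_sets) {
  cancers <- vapply(marker_sets, `[[`, "", "cancer")
  if (anyDuplicated(cancers))
    stop("build_incidence: cancer identifiers must be unique")
  all_markers <- sort(unique(unlist(lapply(marker_sets, `[[`, "markers"))))
  inc <- matrix(0L, length(all_markers), length(marker_sets),
                dimnames = list(all_markers, cancers))
  omic <- stats::setNames(rep(NA_character_, length(all_markers)),
                          all_markers)
  for (ms in marker_sets) {
    inc[ms$markers, ms$cancer] <- 1L
    omic[ms$markers] <- ms$omic
  }
  structure(list(incidence = inc, omic = omic),
            class = "incidence_matrix")
}

#' Cross-cancer sharing summary per omic
#'
#' A marker is shared when it appears in at least two cancer types and
#' cancer-specific when it appears in exactly one.
#'
#' @param incidence an `incidence_matrix` from [build_incidence()].
#' @return data.frame with one row per omic: `omic`, `n_total`,
#'   `n_shared`, `shared_fraction`, `n_specific`, `specific_fraction`.
#' @export
sharing_summary <- function(incidence) {
  if (nrow(incidence$incidence) == 0L)
    stop("sharing_summary: empty incidence matrix")
  rs <- rowSums(incidence$incidence)
  do.call(rbind, lapply(sort(unique(incidence$omic)), function(om) {
    sel <- incidence$omic == om
    n <- sum(sel)
    n_shared <- sum(rs[sel] >= 2)
    n_specific <- sum(rs[sel] == 1)
    data.frame(omic = om, n_total = n, n_shared = n_shared,
               shared_fraction = n_shared / n,
               n_specific = n_specific,
               specific_fraction = n_specific / n,
               stringsAsFactors = FALSE)
  }))
}

#' Top markers ranked by number of associated cancer types
#'
#' Markers sort by incidence row sum, descending, ties broken
#' lexicographically by marker ID; the top `k` per omic are returned.
#'
#' @param incidence an `incidence_matrix`.
#' @param k markers kept per omic (all, when fewer exist).
#' @return data.frame `marker`, `omic`, `n_cancers`, ranked.
#' @export
rank_markers <- function(incidence, k = 20) {
  rs <- rowSums(incidence$incidence)
  do.call(rbind, lapply(sort(unique(incidence$omic)), function(om) {
    sel <- names(rs)[incidence$omic == om]
    ord <- sel[order(-rs[sel], sel)]
    top <- ord[seq_len(min(k, length(ord)))]
    data.frame(marker = top, omic = om, n_cancers = as.integer(rs[top]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' The bundled 19-type, 9-category cancer taxonomy
#'
#' TCGA cohort codes grouped into nine categories (urologic, gynecologic,
#' core GI, developmental GI, thoracic, CNS, head and neck, endocrine,
#' melanocytic), shipped as a plain-text fixture.
#'
#' @return data.frame with columns `cancer_type` and `category`.
#' @export
cancer_taxonomy <- function() {
  path <- system.file("extdata", "cancer_taxonomy.tsv", package = "panprog")
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
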