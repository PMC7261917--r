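#' Construct a pathway collection
#'
#' @param sets named list of character gene vectors.
#' @param refined whether the sets have already been made pairwise
#'   disjoint by [refine_pathways()].
#' @return list of class `pathway_collection`.
#' @export
pathway_collection <- function(sets, refined = FALSE) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  sets <- lapply(sets, unique)
  structure(list(sets = sets, refined = isTRUE(refined)),
            class = "pathway_collection")
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then genes, tab-separated.
#' Duplicate genes within a line are deduplicated. Lines with fewer than
#' three fields (i.e. no genes) are a format error.
#'
#' @param path GMT file path.
#' @return a `pathway_collection` (unrefined).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("read_gmt: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("read_gmt: line ", i, " has fewer than 3 fields")
    sets[[f[1]]] <- unique(f[-(1:2)])
  }
  pathway_collection(sets, refined = FALSE)
}

#' Write a pathway collection as GMT
#'
#' @param collection a `pathway_collection`.
#' @param path output path.
#' @param description description field written on every line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path, description = "na") {
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, description, collection$sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Refine pathways to gene-specific (pairwise disjoint) sets
#'
#' Every gene occurring in two or more sets is removed from all of them,
#' so each surviving gene belongs to exactly one pathway. A set that
#' becomes empty is retained (with a warning).
#'
#' @param collection an unrefined `pathway_collection`.
#' @return the refined collection (`refined = TRUE`).
#' @export
refine_pathways <- function(collection) {
  stopifnot(inherits(collection, "pathway_collection"))
  if (collection$refined)
    stop("refine_pathways: collection is already refined")
  multiplicity <- table(unlist(collection$sets))
  shared <- names(multiplicity)[multiplicity >= 2]
  sets <- lapply(collection$sets, function(g) setdiff(g, shared))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty))
    warning("refine_pathways: set(s) emptied by refinement: ",
            paste(empty, collapse = ", "))
  pathway_collection(sets, refined = TRUE)
}

#' Fraction of a cancer's miRNA markers regulating a pathway
#'
#' A marker regulates the pathway when at least one of its target genes
#' lies inside the pathway's gene set. Markers absent from the target map
#' count in the denominator and regulate nothing.
#'
#' @param markers a [marker_set()] or character vector of miRNA IDs.
#' @param targets named list, miRNA -> character vector of target genes.
#' @param pathway character vector of (refined) pathway genes.
#' @return fraction in `[0, 1]`.
#' @export
marker_regulation_fraction <- function(markers, targets, pathway) {
  if (inherits(markers, "marker_set")) markers <- markers$markers
  if (length(markers) == 0L)
    stop("marker_regulation_fraction: empty marker set")
  hits <- vapply(markers, function(m)
    !is.null(targets[[m]]) && any(targets[[m]] %in% pathway), NA)
  mean(hits)
}

#' Per-gene regulation profile within a pathway
#'
#' For every gene of the pathway, the fraction of the cancer's miRNA
#' markers that target it; genes regulated by strictly more than
#' `min_fraction` of the markers are returned.
#'
#' @param markers a [marker_set()] or character vector of miRNA IDs
#'   (the denominator is their count).
#' @param targets named list, miRNA -> gene vector.
#' @param pathway character vector of (refined) pathway genes.
#' @param min_fraction strict lower gate on the regulation fraction.
#' @return data.frame `gene`, `fraction`, sorted by decreasing fraction.
#' @export
gene_regulation_profile <- function(markers, targets, pathway,
                                    min_fraction = 0.07) {
  if (inherits(markers, "marker_set")) markers <- markers$markers
  n <- length(markers)
  frac <- vapply(pathway, function(g)
    sum(vapply(markers, function(m) g %in% targets[[m]], NA)) / n, 0)
  keep <- frac > min_fraction
  out <- data.frame(gene = pathway[keep], fraction = frac[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$fraction, out$gene), , drop = FALSE]
}

#' Regulation fractions for every cancer and pathway
#'
#' Convenience wrapper producing the cancer x pathway matrix of
#' [marker_regulation_fraction()] values over a refined collection.
#'
#' @param marker_sets list of miRNA [marker_set()]s (one per cancer).
#' @param targets named list, miRNA -> gene vector.
#' @param collection a refined `pathway_collection`.
#' @return numeric matrix, cancers x pathways.
#' @export
regulation_matrix <- function(marker_sets, targets, collection) {
  stopifnot(collection$refined)
  cancers <- vapply(marker_sets, `[[`, "", "cancer")
  out <- t(vapply(marker_sets, function(ms)
    vapply(collection$sets, function(pw)
      marker_regulation_fraction(ms, targets, pw), 0),
    numeric(length(collection$sets))))
  dimnames(out) <- list(cancers, names(collection$sets))
  out
}

#' Translate lncRNA marker identifiers to gene symbols
#'
#' Markers are mapped through the supplied identifier -> symbol table;
#' symbols are deduplicated and unmapped identifiers are reported, not
#' silently dropped.
#'
#' @param markers a [marker_set()] or character vector of lncRNA IDs.
#' @param mapping named character vector, identifier -> symbol.
#' @return list with `symbols` (unique mapped symbols) and `unmapped`
#'   (identifiers without a mapping).
#' @export
map_lncrna_symbols <- function(markers, mapping) {
  if (inherits(markers, "marker_set")) markers <- markers$markers
  hit <- markers %in% names(mapping)
  list(symbols = unique(unname(mapping[markers[hit]])),
       unmapped = markers[!hit])
}
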