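#' Read an expression TSV into a features x samples matrix
#'
#' The expected dialect is Xena-style: first column holds feature IDs, the
#' remaining columns one sample each (or the transpose, with
#' `orientation = "samples-in-rows"`). Cells `"NA"` and `""` parse as
#' missing. Linear-scale inputs are transformed to `log2(x + 1)`.
#'
#' @param path TSV file path.
#' @param orientation `"features-in-rows"` (default) or `"samples-in-rows"`.
#' @param scale `"log2p1"` (values already log2(x+1)) or `"linear"`.
#' @param omic tag attached to the matrix: `"miRNA"`, `"lncRNA"` or
#'   `"merged"`.
#' @return numeric matrix, features in rows, with `omic` attribute; missing
#'   cells are `NA`.
#' @export
read_expression_tsv <- function(path,
                                orientation = c("features-in-rows",
                                                "samples-in-rows"),
                                scale = c("log2p1", "linear"),
                                omic = "miRNA") {
  orientation <- match.arg(orientation)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("read_expression_tsv: no such file: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header))
    stop("read_expression_tsv: duplicate ",
         if (orientation == "features-in-rows") "sample" else "feature",
         " IDs in header")
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = "character")
  ids <- df[[1]]
  body <- df[, -1, drop = FALSE]
  num <- suppressWarnings(
    vapply(body, as.numeric, numeric(nrow(body))))
  if (nrow(body) == 1L) num <- matrix(num, nrow = 1L,
                                      dimnames = list(NULL, colnames(body)))
  bad <- which(is.na(num) & !is.na(as.matrix(body)))
  if (length(bad))
    stop("read_expression_tsv: non-numeric, non-NA cell(s) in ", path)
  m <- matrix(num, nrow = nrow(body), dimnames = list(ids, header))
  if (orientation == "samples-in-rows") m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("read_expression_tsv: duplicate sample IDs")
  if (anyDuplicated(rownames(m)))
    stop("read_expression_tsv: duplicate feature IDs")
  if (scale == "linear") m <- log2(m + 1)
  attr(m, "omic") <- omic
  m
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_tsv()]: first column `feature`, one column
#' per sample, full precision.
#'
#' @param matrix features x samples numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  df <- data.frame(feature = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop features, then samples, containing missing values
#'
#' Two-pass rule: first every feature (row) with at least one `NA` is
#' removed, then every remaining sample (column) with at least one `NA`.
#' The result contains no missing values; applying the filter twice equals
#' applying it once.
#'
#' @param matrix features x samples matrix, possibly with `NA`s.
#' @return filtered matrix (possibly with zero rows or columns, with a
#'   warning).
#' @export
filter_missing <- function(matrix) {
  keep_f <- rowSums(is.na(matrix)) == 0
  out <- matrix[keep_f, , drop = FALSE]
  keep_s <- colSums(is.na(out)) == 0
  out <- out[, keep_s, drop = FALSE]
  if (nrow(out) == 0L || ncol(out) == 0L)
    warning("filter_missing: result is empty")
  attr(out, "omic") <- attr(matrix, "omic")
  out
}

#' Sum isoform expression per mature strand and log-transform
#'
#' Linear-scale isoform rows mapping to the same mature ID are summed per
#' sample, then transformed `log2(x + 1)`. Isoforms without a mapping are
#' dropped with a warning.
#'
#' @param isoform_matrix linear-scale isoforms x samples matrix.
#' @param isoform_to_mature named character vector, isoform ID -> mature ID.
#' @return mature strands x samples matrix, log2 scale.
#' @export
aggregate_isoforms <- function(isoform_matrix, isoform_to_mature) {
  mapped <- rownames(isoform_matrix) %in% names(isoform_to_mature)
  if (any(!mapped))
    warning("aggregate_isoforms: dropping ", sum(!mapped),
            " unmapped isoform(s)")
  m <- isoform_matrix[mapped, , drop = FALSE]
  grp <- isoform_to_mature[rownames(m)]
  summed <- rowsum(m, group = grp)
  out <- log2(summed + 1)
  attr(out, "omic") <- attr(isoform_matrix, "omic")
  out
}

#' Collapse rows sharing an identifier by their per-sample mean
#'
#' Rows are renamed through `accession_to_id` (identifiers absent from the
#' map keep their name); rows that then share an ID are replaced by their
#' arithmetic mean per sample, on the stored (log) scale.
#'
#' @param matrix features x samples matrix.
#' @param accession_to_id named character vector, accession -> final ID.
#' @return matrix with unique row IDs.
#' @export
collapse_duplicate_ids <- function(matrix, accession_to_id) {
  ids <- rownames(matrix)
  hit <- ids %in% names(accession_to_id)
  ids[hit] <- accession_to_id[ids[hit]]
  sums <- rowsum(matrix, group = ids)
  counts <- as.vector(table(ids)[rownames(sums)])
  out <- sums / counts
  attr(out, "omic") <- attr(matrix, "omic")
  out
}

#' Read a clinical TSV
#'
#' Expected columns: `sample`, `os_days`, optional `event` (defaults to 1,
#' i.e. death observed) and optional `sample_type_code` (two-digit TCGA
#' barcode field).
#'
#' @param path TSV file path.
#' @return data.frame with at least `sample`, `os_days`, `event`.
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", ""),
                          colClasses = c(sample = "character"))
  if (!all(c("sample", "os_days") %in% names(df)))
    stop("read_clinical_tsv: need columns 'sample' and 'os_days'")
  if (is.null(df$event)) df$event <- 1L
  df$event[is.na(df$event)] <- 1L
  if (!is.null(df$sample_type_code))
    df$sample_type_code <- sprintf("%02d", as.integer(df$sample_type_code))
  df
}

#' Intersect an expression matrix with usable clinical samples
#'
#' Clinical rows with missing or non-positive `os_days` are removed, as are
#' (when a `sample_type_code` column is present) samples whose TCGA
#' sample-type code is outside 01-09, i.e. normal tissue. The matrix and
#' table are then restricted to the shared samples, in the matrix's column
#' order.
#'
#' @param matrix features x samples matrix.
#' @param clinical clinical data.frame (see [read_clinical_tsv()]).
#' @return list with aligned `matrix` and `clinical`.
#' @export
align_with_clinical <- function(matrix, clinical) {
  cl <- clinical[!is.na(clinical$os_days) & clinical$os_days > 0, ,
                 drop = FALSE]
  if (!is.null(cl$sample_type_code)) {
    code <- suppressWarnings(as.integer(cl$sample_type_code))
    cl <- cl[!is.na(code) & code >= 1L & code <= 9L, , drop = FALSE]
  }
  common <- intersect(colnames(matrix), cl$sample)
  if (length(common) == 0L)
    stop("align_with_clinical: no samples shared between matrix and clinical")
  keep <- colnames(matrix)[colnames(matrix) %in% common]
  m <- matrix[, keep, drop = FALSE]
  attr(m, "omic") <- attr(matrix, "omic")
  cl <- cl[match(keep, cl$sample), , drop = FALSE]
  rownames(cl) <- NULL
  list(matrix = m, clinical = cl)
}

#' Label samples by the cohort's median overall survival
#'
#' The median OS of the retained samples (midpoint of the central pair for
#' even n) is the classification indicator: samples with `os_days`
#' strictly above it are `"high-OS"`, everything else — including ties at
#' the median — is `"low-OS"`.
#'
#' @param clinical clinical data.frame with `sample` and `os_days`.
#' @return list of class `cohort_labels`: `median_os` and `labels`, a named
#'   character vector over samples with values `"high-OS"`/`"low-OS"`.
#' @export
label_by_median_os <- function(clinical) {
  if (nrow(clinical) < 2L)
    stop("label_by_median_os: need at least 2 samples")
  med <- stats::median(clinical$os_days)
  labels <- ifelse(clinical$os_days > med, "high-OS", "low-OS")
  names(labels) <- clinical$sample
  if (all(labels == "low-OS"))
    warning("label_by_median_os: no sample exceeds the median OS; ",
            "all samples labelled low-OS")
  structure(list(median_os = med, labels = labels),
            class = "cohort_labels")
}

#' Row-concatenate two omics over their shared samples
#'
#' Feature namespaces must be disjoint (error otherwise); the merged matrix
#' covers the sample intersection and carries omic tag `"merged"`.
#'
#' @param mirna,lncrna features x samples matrices.
#' @return merged matrix.
#' @export
merge_omics <- function(mirna, lncrna) {
  clash <- intersect(rownames(mirna), rownames(lncrna))
  if (length(clash))
    stop("merge_omics: colliding feature IDs: ",
         paste(utils::head(clash, 5), collapse = ", "))
  common <- intersect(colnames(mirna), colnames(lncrna))
  if (length(common) == 0L)
    stop("merge_omics: empty sample intersection")
  out <- rbind(mirna[, common, drop = FALSE], lncrna[, common, drop = FALSE])
  attr(out, "omic") <- "merged"
  out
}
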