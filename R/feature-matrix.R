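#' Feature-by-sample matrix with an explicit missingness mask
#'
#' The basic container consumed by every preprocessing and modelling stage:
#' a numeric grid of features (rows) by samples (columns) together with a
#' same-shape logical mask distinguishing a value that is absent (never
#' observed) from a stored zero. GDC-style level-3 summaries (copy-number
#' calls, FPKM-UQ expression, methylation beta ratios, miRNA abundances,
#' RPPA protein levels) all arrive in this shape.
#'
#' @param values numeric matrix, features in rows, samples in columns. Row
#'   and column names are used as feature and sample identifiers; if absent
#'   they are generated. `NA` entries are taken as absent.
#' @param subset_name label of the omics subset (e.g. `"RNA-seq"`).
#' @param absent_mask optional logical matrix of the same shape; `TRUE`
#'   marks an absent entry. Defaults to `is.na(values)`.
#' @param provenance free-text description of the measured component.
#'
#' @return An object of class `feature_matrix`: a list with elements
#'   `subset_name`, `values` (absent entries stored as `NA`), `absent`
#'   (logical mask) and `provenance`.
#' @examples
#' m <- feature_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2", "s3"))), "RNA-seq")
#' n_features(m); n_samples(m)
#' @export
feature_matrix <- function(values, subset_name = "subset",
                           absent_mask = NULL, provenance = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop_field("values", "must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("f%0*d", nchar(nrow(values)), seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%0*d", nchar(ncol(values)), seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop_field("feature_ids", sprintf("duplicate feature id '%s'",
                                      rownames(values)[duplicated(rownames(values))][1]))
  if (anyDuplicated(colnames(values)))
    stop_field("sample_ids", sprintf("duplicate sample id '%s'",
                                     colnames(values)[duplicated(colnames(values))][1]))
  if (is.null(absent_mask)) absent_mask <- is.na(values)
  if (!is.logical(absent_mask) || !identical(dim(absent_mask), dim(values)))
    stop_field("absent_mask", "must be a logical matrix of the same shape as values")
  absent_mask[is.na(absent_mask)] <- TRUE
  values[absent_mask] <- NA_real_
  if (anyNA(values[!absent_mask]))
    absent_mask[is.na(values)] <- TRUE
  dimnames(absent_mask) <- dimnames(values)
  structure(
    list(subset_name = as.character(subset_name), values = values,
         absent = absent_mask, provenance = as.character(provenance)),
    class = "feature_matrix")
}

#' @rdname feature_matrix
#' @param m a `feature_matrix`.
#' @export
n_features <- function(m) nrow(m$values)

#' @rdname feature_matrix
#' @export
n_samples <- function(m) ncol(m$values)

#' @rdname feature_matrix
#' @export
feature_ids <- function(m) rownames(m$values)

#' @rdname feature_matrix
#' @export
sample_ids <- function(m) colnames(m$values)

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d features x %d samples (%d absent entries)\n",
              x$subset_name, n_features(x), n_samples(x), sum(x$absent)))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

# Subset a feature_matrix by row/column index keeping mask and metadata.
fm_subset <- function(m, rows = NULL, cols = NULL) {
  v <- m$values; a <- m$absent
  if (!is.null(rows)) { v <- v[rows, , drop = FALSE]; a <- a[rows, , drop = FALSE] }
  if (!is.null(cols)) { v <- v[, cols, drop = FALSE]; a <- a[, cols, drop = FALSE] }
  structure(list(subset_name = m$subset_name, values = v, absent = a,
                 provenance = m$provenance), class = "feature_matrix")
}

check_feature_matrix <- function(m) {
  if (!inherits(m, "feature_matrix")) stop("expected a `feature_matrix`", call. = FALSE)
  invisible(m)
}
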