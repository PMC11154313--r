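#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample ids with the feature-id column first,
#' one feature per row. Empty cells and the literal `NA` mark absent
#' entries (they populate the absent mask); any other non-numeric cell,
#' a ragged row or a duplicated id is a parse error reported with its
#' line number.
#'
#' @param path file path.
#' @param subset_name subset label stored on the result; defaults to the
#'   file name without extension.
#' @param provenance free-text component description.
#' @return A [feature_matrix()].
#' @export
read_matrix_tsv <- function(path, subset_name = NULL, provenance = "") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 1L) stop(sprintf("%s: empty file", path), call. = FALSE)
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1]]
  if (length(header) < 2L)
    stop(sprintf("%s:1: header must hold a feature-id column plus sample ids", path),
         call. = FALSE)
  samples <- header[-1]
  if (anyDuplicated(samples))
    stop(sprintf("%s:1: duplicate sample id '%s'", path,
                 samples[duplicated(samples)][1]), call. = FALSE)
  p <- length(lines) - 1L
  vals <- matrix(NA_real_, p, length(samples))
  feats <- character(p)
  for (i in seq_len(p)) {
    row <- cells[[i + 1L]]
    if (length(row) != length(header))
      stop(sprintf("%s:%d: ragged row (%d cells, expected %d)", path, i + 1L,
                   length(row), length(header)), call. = FALSE)
    feats[i] <- row[1]
    body <- row[-1]
    absent <- body == "" | body == "NA"
    num <- suppressWarnings(as.numeric(body))
    bad <- which(!absent & is.na(num))
    if (length(bad))
      stop(sprintf("%s:%d: non-numeric cell '%s' (column %d)", path, i + 1L,
                   body[bad[1]], bad[1] + 1L), call. = FALSE)
    vals[i, ] <- num
  }
  if (anyDuplicated(feats))
    stop(sprintf("%s: duplicate feature id '%s'", path,
                 feats[duplicated(feats)][1]), call. = FALSE)
  dimnames(vals) <- list(feats, samples)
  feature_matrix(vals,
                 subset_name = subset_name %||%
                   sub("\\.[^.]*$", "", basename(path)),
                 provenance = provenance)
}

#' Write a feature matrix to TSV
#'
#' Inverse of [read_matrix_tsv()]: absent entries are emitted as `NA`.
#'
#' @param m a [feature_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  check_feature_matrix(m)
  v <- m$values
  body <- matrix(ifelse(m$absent, "NA",
                        formatC(v, format = "g", digits = 15)),
                 nrow(v), ncol(v))
  lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], body[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort to a directory of TSV files
#'
#' Emits one matrix TSV per subset, a sample sheet
#' (`sample_id`, `vital_status`, `survival_days`, `censored`) and a JSON
#' sidecar recording the generating spec including its seed.
#'
#' @param cohort an `omics_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  check_cohort(cohort)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(cohort$subsets))
    write_matrix_tsv(cohort$subsets[[s]],
                     file.path(dir, paste0(safe_name(s), ".tsv")))
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$spec)) {
    spec <- unclass(cohort$spec)
    jsonlite::write_json(spec, file.path(dir, "cohort_spec.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(dir)
}

safe_name <- function(s) gsub("[^A-Za-z0-9_.-]", "_", s)

#' Read a cohort from a directory written by [write_cohort()]
#'
#' @param dir directory holding subset TSVs and `samples.tsv`.
#' @param subsets subset names to read; defaults to the five standard
#'   omics subsets found in the directory.
#' @return An `omics_cohort` (its `spec` element is `NULL`; the JSON
#'   sidecar documents provenance but is not re-hydrated).
#' @export
read_cohort <- function(dir, subsets = NULL) {
  sheet_path <- file.path(dir, "samples.tsv")
  if (!file.exists(sheet_path))
    stop(sprintf("sample sheet not found: %s", sheet_path), call. = FALSE)
  samples <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "vital_status", "survival_days", "censored")
  if (!all(need %in% names(samples)))
    stop(sprintf("%s: sample sheet must hold columns %s", sheet_path,
                 paste(need, collapse = ", ")), call. = FALSE)
  samples$censored <- as.logical(samples$censored)
  if (is.null(subsets)) {
    found <- list.files(dir, pattern = "\\.tsv$")
    found <- setdiff(sub("\\.tsv$", "", found), "samples")
    subsets <- OMICS_SUBSETS[vapply(OMICS_SUBSETS,
                                    function(s) safe_name(s) %in% found, TRUE)]
    if (!length(subsets)) subsets <- found
  }
  mats <- list()
  for (s in subsets) {
    f <- file.path(dir, paste0(safe_name(s), ".tsv"))
    mats[[s]] <- read_matrix_tsv(f, subset_name = s,
                                 provenance = subset_provenance(s))
    unknown <- setdiff(sample_ids(mats[[s]]), samples$sample_id)
    if (length(unknown))
      stop(sprintf("%s: sample '%s' missing from the sample sheet", f,
                   unknown[1]), call. = FALSE)
  }
  structure(list(subsets = mats, samples = samples, spec = NULL),
            class = "omics_cohort")
}

#' Aggregate a copy-number segment table to genes
#'
#' Accepts copy-number input in segment form (`chromosome`, `start`,
#' `end`, `copy_number`, `sample_id`; 1-based inclusive coordinates) and
#' aggregates it to a gene-by-sample matrix: each gene receives the copy
#' number of the segment with the largest overlap of its body.
#'
#' @param segments data frame with the five columns above.
#' @param genes data frame with `gene_id`, `chromosome`, `start`, `end`.
#' @return A [feature_matrix()] (subset `"DNA-seq"`); gene/sample pairs
#'   with no overlapping segment are absent.
#' @export
segments_to_gene_matrix <- function(segments, genes) {
  need_s <- c("chromosome", "start", "end", "copy_number", "sample_id")
  need_g <- c("gene_id", "chromosome", "start", "end")
  if (!all(need_s %in% names(segments)))
    stop_field("segments", paste("needs columns", paste(need_s, collapse = ", ")))
  if (!all(need_g %in% names(genes)))
    stop_field("genes", paste("needs columns", paste(need_g, collapse = ", ")))
  samples <- sort(unique(segments$sample_id))
  vals <- matrix(NA_real_, nrow(genes), length(samples),
                 dimnames = list(genes$gene_id, samples))
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    hits <- segments[segments$chromosome == g$chromosome &
                       segments$end >= g$start & segments$start <= g$end, ,
                     drop = FALSE]
    if (!nrow(hits)) next
    overlap <- pmin(hits$end, g$end) - pmax(hits$start, g$start) + 1L
    for (s in unique(hits$sample_id)) {
      sel <- hits$sample_id == s
      vals[gi, s] <- hits$copy_number[sel][which.max(overlap[sel])]
    }
  }
  feature_matrix(vals, subset_name = "DNA-seq",
                 provenance = "segment copy number aggregated by maximum overlap")
}
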