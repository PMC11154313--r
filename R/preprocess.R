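#' Preprocessing configuration
#'
#' Thresholds for the three-stage missing-value handling: features are
#' dropped when stored zeros exceed `zero_feature_threshold` of their
#' present entries, samples are dropped when absent entries exceed
#' `missing_sample_threshold` of the features, and remaining absent
#' entries are filled by a `impute_neighbors`-nearest-sample mean.
#'
#' @param zero_feature_threshold fraction in (0,1); default 0.20.
#' @param missing_sample_threshold fraction in (0,1); default 0.20.
#' @param impute_neighbors number of nearest samples used for imputation.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(zero_feature_threshold = 0.20,
                              missing_sample_threshold = 0.20,
                              impute_neighbors = 10L) {
  for (f in c("zero_feature_threshold", "missing_sample_threshold")) {
    x <- get(f)
    if (!is.numeric(x) || length(x) != 1L || x <= 0 || x >= 1)
      stop_field(f, "must be a single fraction in (0, 1)")
  }
  structure(list(zero_feature_threshold = zero_feature_threshold,
                 missing_sample_threshold = missing_sample_threshold,
                 impute_neighbors = check_count(impute_neighbors, "impute_neighbors")),
            class = "preprocess_config")
}

#' Remove features with an excessive zero prevalence
#'
#' A feature is removed iff the count of samples where its stored value is
#' exactly zero, divided by the count of samples where it has a present
#' value, is strictly greater than `threshold`. Absent entries are not
#' zeros and enter neither numerator nor denominator; a feature with no
#' present entry at all is removed. The order of surviving features is
#' preserved.
#'
#' @param m a [feature_matrix()].
#' @param threshold fraction in (0,1); default 0.20.
#' @return A filtered `feature_matrix`.
#' @export
filter_features_by_zeros <- function(m, threshold = 0.20) {
  check_feature_matrix(m)
  if (n_features(m) == 0L || n_samples(m) == 0L)
    stop("empty matrix: nothing to filter", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop_field("threshold", "must be in (0, 1)")
  present <- rowSums(!m$absent)
  zeros <- rowSums(!m$absent & !is.na(m$values) & m$values == 0)
  frac <- ifelse(present > 0, zeros / present, 1)
  keep <- frac <= threshold & present > 0
  if (!any(keep)) warning("all features removed by the zero-prevalence filter")
  fm_subset(m, rows = which(keep))
}

#' Remove samples with too many absent entries
#'
#' A sample is removed iff its number of absent entries divided by the
#' number of features is strictly greater than `threshold`; the feature
#' set is unchanged.
#'
#' @inheritParams filter_features_by_zeros
#' @return A filtered `feature_matrix`.
#' @export
filter_samples_by_missing <- function(m, threshold = 0.20) {
  check_feature_matrix(m)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop_field("threshold", "must be in (0, 1)")
  frac <- colSums(m$absent) / n_features(m)
  keep <- frac <= threshold
  if (!any(keep))
    stop("all samples exceed the missingness threshold: nothing left to analyze",
         call. = FALSE)
  fm_subset(m, cols = which(keep))
}

#' Fill absent entries by a k-nearest-sample mean
#'
#' Each absent entry (feature f, sample s) is replaced by the mean of f's
#' values over the `neighbors` samples nearest to s, where distance is the
#' root mean squared difference over features present in both samples and
#' only samples with f present are candidates. If fewer than `neighbors`
#' candidates exist, all of them are used. Ties in distance are broken by
#' sample order.
#'
#' @param m a [feature_matrix()].
#' @param neighbors number of nearest samples averaged; default 10.
#' @return A `feature_matrix` with `absent` all `FALSE`.
#' @export
impute_missing <- function(m, neighbors = 10L) {
  check_feature_matrix(m)
  neighbors <- check_count(neighbors, "neighbors")
  if (n_samples(m) < neighbors + 1L)
    stop(sprintf("need at least neighbors + 1 = %d samples, have %d",
                 neighbors + 1L, n_samples(m)), call. = FALSE)
  if (!any(m$absent)) return(m)
  null_rows <- rowSums(!m$absent) == 0L
  if (any(null_rows))
    stop(sprintf(
      "feature '%s' is absent in all samples; run drop_null_features() first",
      feature_ids(m)[which(null_rows)[1]]), call. = FALSE)
  v <- m$values
  ns <- n_samples(m)
  need <- which(colSums(m$absent) > 0L)
  for (s in need) {
    d <- vapply(seq_len(ns), function(t) {
      if (t == s) return(Inf)
      shared <- !m$absent[, s] & !m$absent[, t]
      if (!any(shared)) return(Inf)
      sqrt(mean((v[shared, s] - v[shared, t])^2))
    }, numeric(1))
    for (f in which(m$absent[, s])) {
      cand <- which(!m$absent[f, ])
      cand <- cand[order(d[cand], cand)]
      use <- cand[seq_len(min(neighbors, length(cand)))]
      m$values[f, s] <- mean(v[f, use])
    }
  }
  m$absent[] <- FALSE
  m
}

#' Remove features that are null across all samples
#'
#' Drops every feature whose stored values are zero (or absent) in every
#' sample.
#'
#' @param m a [feature_matrix()].
#' @return A `feature_matrix` without all-null features.
#' @export
drop_null_features <- function(m) {
  check_feature_matrix(m)
  informative <- rowSums(!m$absent & !is.na(m$values) & m$values != 0) > 0L
  fm_subset(m, rows = which(informative))
}

#' Run the full three-stage preprocessing cascade on one matrix
#'
#' Applies, in order: the zero-prevalence feature filter, the
#' missing-sample filter, k-nearest-sample imputation, and null-feature
#' removal. Returns the cleaned matrix together with a per-stage report of
#' removed features/samples.
#'
#' @param m a [feature_matrix()].
#' @param config a [preprocess_config()].
#' @return A list with `matrix` (the cleaned `feature_matrix`) and
#'   `report` (counts and ids removed per stage).
#' @export
preprocess_matrix <- function(m, config = preprocess_config()) {
  check_feature_matrix(m)
  f0 <- feature_ids(m); s0 <- sample_ids(m)
  m1 <- filter_features_by_zeros(m, config$zero_feature_threshold)
  m2 <- filter_samples_by_missing(m1, config$missing_sample_threshold)
  m3 <- if (any(m2$absent)) {
    # features left with no present value after the sample filter are null by
    # definition and fall to stage four; imputation runs on the others
    m2a <- fm_subset(m2, rows = which(rowSums(!m2$absent) > 0L))
    impute_missing(m2a, min(config$impute_neighbors, n_samples(m2a) - 1L))
  } else m2
  m4 <- drop_null_features(m3)
  report <- list(
    subset = m$subset_name,
    features_in = length(f0), samples_in = length(s0),
    removed_zero_features = setdiff(f0, feature_ids(m1)),
    removed_missing_samples = setdiff(s0, sample_ids(m2)),
    imputed_entries = sum(m2$absent),
    removed_null_features = setdiff(feature_ids(m1), feature_ids(m4)),
    features_out = n_features(m4), samples_out = n_samples(m4))
  list(matrix = m4, report = report)
}

#' Assemble padded classifier inputs from a cohort
#'
#' Runs the preprocessing cascade on each requested subset, restricts to
#' the samples covered by all of them, fixes a deterministic feature order
#' (lexicographic by feature id), and right-pads every subset's feature
#' vector with zeros to the maximum subset length so all recurrent
#' branches share one input width. Stored values pass through unscaled: no
#' normalization is applied and padding never alters a surviving value.
#' Labels are binary with dead as the positive class.
#'
#' @param cohort an `omics_cohort`.
#' @param config a [preprocess_config()].
#' @param subsets character vector of subset names to use; default all.
#' @return A list with `inputs` (named list of samples-by-width numeric
#'   matrices, one per subset, all with the same width), `labels` (integer,
#'   1 = dead), `sample_ids`, `widths` (unpadded feature count per subset),
#'   `pad_width`, and `reports` (per-subset preprocessing reports).
#' @export
assemble_model_inputs <- function(cohort, config = preprocess_config(),
                                  subsets = names(cohort$subsets)) {
  check_cohort(cohort)
  missing_sub <- setdiff(subsets, names(cohort$subsets))
  if (length(missing_sub))
    stop_field("subsets", paste("not in cohort:", paste(missing_sub, collapse = ", ")))
  cleaned <- lapply(cohort$subsets[subsets], preprocess_matrix, config = config)
  mats <- lapply(cleaned, `[[`, "matrix")
  common <- Reduce(intersect, lapply(mats, sample_ids))
  if (!length(common))
    stop("empty sample intersection across requested subsets", call. = FALSE)
  common <- cohort$samples$sample_id[cohort$samples$sample_id %in% common]
  widths <- vapply(mats, n_features, integer(1))
  pad_width <- max(widths)
  inputs <- lapply(mats, function(m) {
    ord <- order(feature_ids(m))
    x <- t(m$values[ord, common, drop = FALSE])
    if (ncol(x) < pad_width) {
      pad <- matrix(0, nrow(x), pad_width - ncol(x))
      colnames(pad) <- sprintf("pad%04d", seq_len(ncol(pad)))
      x <- cbind(x, pad)
    }
    x
  })
  lab <- cohort$samples$vital_status[match(common, cohort$samples$sample_id)]
  list(inputs = inputs,
       labels = as.integer(lab == "dead"),
       sample_ids = common,
       widths = widths,
       pad_width = pad_width,
       reports = lapply(cleaned, `[[`, "report"))
}
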