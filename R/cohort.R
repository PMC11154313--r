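OMICS_SUBSETS <- c("DNA-seq", "RNA-seq", "Methylation", "miRNA-seq", "Protein")

#' Specification of a synthetic multi-omics cohort
#'
#' Describes the statistical structure of a simulated dead-vs-alive cancer
#' cohort: group sizes, per-subset feature counts, planted copy-number
#' amplifications and expression fold changes in the dead group, a null
#' protein layer (identical distribution in both groups), injected
#' missingness, and exponential survival times. Defaults are desk-scale
#' analogues of a GDC pancreatic-cancer cohort: the alive group is larger
#' than the dead group, the protein subset covers only a small fraction of
#' samples, six genes carry a ~4x copy-number amplification in the dead
#' group and ten genes an 8.5-26x expression fold change, and censoring
#' affects 20% of samples.
#'
#' @param n_alive,n_dead group sizes (samples).
#' @param features_per_subset named integer vector, feature count for each
#'   of the five subsets.
#' @param planted_amplifications data frame with columns `gene_id`,
#'   `alive_mean`, `ratio`: copy-number genes whose dead-group mean is
#'   `alive_mean * ratio`.
#' @param planted_degs data frame with columns `gene_id`, `alive_mean`,
#'   `fold_change`: expression genes up-regulated in the dead group.
#' @param null_protein_sigma dispersion of protein levels, identical in
#'   both groups (no protein signal).
#' @param zero_fraction,missing_fraction fractions of entries set to zero /
#'   marked absent, uniformly at random (planted genes are protected).
#' @param hazard_alive,hazard_dead exponential survival rates per day;
#'   `hazard_dead >= hazard_alive`.
#' @param censor_prob probability that a sample's time is censored.
#' @param subset_coverage named fraction vector: share of samples covered
#'   by each subset (the protein layer typically covers few samples).
#' @param cnv_sd normal dispersion of copy-number values.
#' @param expression_sdlog log-scale dispersion of expression and miRNA
#'   values.
#' @param seed integer RNG seed; the whole cohort is a deterministic
#'   function of the spec including this seed.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_alive = 300L,
                        n_dead = 200L,
                        features_per_subset = c(
                          "DNA-seq" = 120L, "RNA-seq" = 200L,
                          "Methylation" = 150L, "miRNA-seq" = 80L,
                          "Protein" = 40L),
                        planted_amplifications = default_planted_amplifications(),
                        planted_degs = default_planted_degs(),
                        null_protein_sigma = 0.5,
                        zero_fraction = 0.10,
                        missing_fraction = 0.05,
                        hazard_alive = 1 / 720,
                        hazard_dead = 1 / 180,
                        censor_prob = 0.2,
                        subset_coverage = c(
                          "DNA-seq" = 1, "RNA-seq" = 1, "Methylation" = 1,
                          "miRNA-seq" = 1, "Protein" = 0.25),
                        cnv_sd = 0.3,
                        expression_sdlog = 0.15,
                        seed = 1L) {
  n_alive <- check_count(n_alive, "n_alive")
  n_dead <- check_count(n_dead, "n_dead")
  if (is.null(names(features_per_subset)) ||
      !all(names(features_per_subset) %in% OMICS_SUBSETS))
    stop_field("features_per_subset",
               paste("must be named with subset names among:",
                     paste(OMICS_SUBSETS, collapse = ", ")))
  for (s in names(features_per_subset))
    check_count(features_per_subset[[s]], paste0("features_per_subset['", s, "']"))
  planted_amplifications <- check_planted(planted_amplifications, "ratio",
                                          "planted_amplifications")
  planted_degs <- check_planted(planted_degs, "fold_change", "planted_degs")
  check_fraction(zero_fraction, "zero_fraction")
  check_fraction(missing_fraction, "missing_fraction")
  check_fraction(censor_prob, "censor_prob", allow_one = TRUE)
  if (!is.numeric(null_protein_sigma) || null_protein_sigma <= 0)
    stop_field("null_protein_sigma", "must be a positive number")
  if (!is.numeric(hazard_alive) || hazard_alive <= 0)
    stop_field("hazard_alive", "must be a positive rate")
  if (!is.numeric(hazard_dead) || hazard_dead <= 0)
    stop_field("hazard_dead", "must be a positive rate")
  if (hazard_dead < hazard_alive)
    stop_field("hazard_dead", "must be >= hazard_alive")
  cov <- rep(1, length(features_per_subset))
  names(cov) <- names(features_per_subset)
  cov[names(subset_coverage)[names(subset_coverage) %in% names(cov)]] <-
    subset_coverage[names(subset_coverage) %in% names(cov)]
  for (s in names(cov))
    if (!is.finite(cov[[s]]) || cov[[s]] <= 0 || cov[[s]] > 1)
      stop_field("subset_coverage", "fractions must be in (0, 1]")
  structure(
    list(n_alive = n_alive, n_dead = n_dead,
         features_per_subset = features_per_subset,
         planted_amplifications = planted_amplifications,
         planted_degs = planted_degs,
         null_protein_sigma = null_protein_sigma,
         zero_fraction = zero_fraction, missing_fraction = missing_fraction,
         hazard_alive = hazard_alive, hazard_dead = hazard_dead,
         censor_prob = censor_prob, subset_coverage = cov,
         cnv_sd = cnv_sd, expression_sdlog = expression_sdlog,
         seed = check_count(seed, "seed", min = 0L)),
    class = "cohort_spec")
}

check_planted <- function(df, ratio_col, field) {
  if (is.null(df)) {
    df <- data.frame(gene_id = character(), alive_mean = numeric())
    df[[ratio_col]] <- numeric()
    return(df)
  }
  need <- c("gene_id", "alive_mean", ratio_col)
  if (!is.data.frame(df) || !all(need %in% names(df)))
    stop_field(field, paste("must be a data frame with columns",
                            paste(need, collapse = ", ")))
  if (nrow(df) && (any(df$alive_mean <= 0) || any(df[[ratio_col]] <= 0)))
    stop_field(field, "alive_mean and ratios/fold-changes must be > 0")
  df
}

#' @rdname cohort_spec
#' @export
default_planted_amplifications <- function() {
  data.frame(
    gene_id = c("EWSR1", "FLT3", "GPC3", "HIF1A", "HLF", "MEN1"),
    alive_mean = c(1.32, 1.30, 1.32, 1.30, 1.30, 1.32),
    ratio = c(4.04, 4.11, 4.11, 4.35, 4.03, 4.12))
}

#' @rdname cohort_spec
#' @export
default_planted_degs <- function() {
  data.frame(
    gene_id = c("RPL30", "RPS28P7", "Metazoa_SRP", "H3F3B", "OAZ1",
                "RPS11", "CAPNS1", "FN1", "LCN2", "RPL37"),
    alive_mean = rep(10, 10),
    fold_change = c(26.06, 16.81, 10.33, 9.77, 9.52, 9.18, 9.10, 8.76, 8.66, 8.53))
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d alive + %d dead samples, seed %d\n",
              x$n_alive, x$n_dead, x$seed))
  cat("  features:", paste(sprintf("%s=%d", names(x$features_per_subset),
                                   x$features_per_subset), collapse = ", "), "\n")
  cat(sprintf("  planted: %d amplifications, %d DEGs; zero/missing fractions %.2f/%.2f\n",
              nrow(x$planted_amplifications), nrow(x$planted_degs),
              x$zero_fraction, x$missing_fraction))
  invisible(x)
}

#' Generate a synthetic multi-omics cohort
#'
#' Draws a full dead-vs-alive cohort from a [cohort_spec()]: truncated-normal
#' copy numbers (floor 0) with planted dead-group amplifications, log-normal
#' expression with planted fold changes, Beta-distributed methylation ratios
#' in \[0,1\], negative-binomial miRNA counts, protein levels from one shared
#' distribution in both groups, exponential survival times with group-specific
#' hazards and Bernoulli censoring. Requested zero/missing fractions are then
#' injected uniformly at random, protecting the planted genes so that
#' downstream ratio checks on them remain exact. The result is byte-identical
#' across calls with the same spec.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `omics_cohort`: a list with `subsets` (named
#'   list of [feature_matrix()] objects), `samples` (data frame with
#'   `sample_id`, `vital_status`, `survival_days`, `censored`) and `spec`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_alive = 20, n_dead = 10, seed = 7))
#' table(co$samples$vital_status)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec", call. = FALSE)
  with_seed(spec$seed, {
    n <- spec$n_alive + spec$n_dead
    ids <- sprintf("S%04d", seq_len(n))
    status <- c(rep("alive", spec$n_alive), rep("dead", spec$n_dead))
    dead <- status == "dead"

    subsets <- list()
    for (s in names(spec$features_per_subset)) {
      p <- spec$features_per_subset[[s]]
      fids <- sprintf("%s_f%04d", gsub("[^A-Za-z]", "", s), seq_len(p))
      vals <- switch(s,
        "DNA-seq" = {
          planted <- spec$planted_amplifications
          k <- min(nrow(planted), p)
          if (k) fids[seq_len(k)] <- planted$gene_id[seq_len(k)]
          mu <- matrix(2, p, n)  # diploid baseline
          if (k) {
            mu[seq_len(k), !dead] <- planted$alive_mean[seq_len(k)]
            mu[seq_len(k), dead] <- planted$alive_mean[seq_len(k)] *
              planted$ratio[seq_len(k)]
          }
          pmax(matrix(stats::rnorm(p * n, mu, spec$cnv_sd), p, n), 0)
        },
        "RNA-seq" = ,
        "miRNA-seq" = {
          sdl <- spec$expression_sdlog
          base_mean <- if (s == "RNA-seq") 10 else 50
          mu <- matrix(base_mean, p, n)
          if (s == "RNA-seq") {
            planted <- spec$planted_degs
            k <- min(nrow(planted), p)
            if (k) {
              fids[seq_len(k)] <- planted$gene_id[seq_len(k)]
              mu[seq_len(k), !dead] <- planted$alive_mean[seq_len(k)]
              mu[seq_len(k), dead] <- planted$alive_mean[seq_len(k)] *
                planted$fold_change[seq_len(k)]
            }
          }
          # meanlog chosen so the arithmetic mean equals mu
          v <- matrix(stats::rlnorm(p * n, log(mu) - sdl^2 / 2, sdl), p, n)
          if (s == "miRNA-seq") round(v) else v
        },
        "Methylation" = {
          m0 <- stats::runif(p, 0.1, 0.9)  # per-CpG mean beta, shared by groups
          matrix(stats::rbeta(p * n, rep(m0 * 10, n), rep((1 - m0) * 10, n)), p, n)
        },
        "Protein" = {
          mu0 <- stats::rnorm(p, 0.3, 0.5)  # per-antibody level, shared by groups
          matrix(stats::rnorm(p * n, rep(mu0, n), spec$null_protein_sigma), p, n)
        },
        stop_field("features_per_subset", paste("unknown subset", s)))
      dimnames(vals) <- list(fids, ids)
      cov <- spec$subset_coverage[[s]]
      if (cov < 1) {
        keep <- sort(sample.int(n, max(2L, round(cov * n))))
        vals <- vals[, keep, drop = FALSE]
      }
      subsets[[s]] <- feature_matrix(vals, subset_name = s,
                                     provenance = subset_provenance(s))
    }

    hz <- ifelse(dead, spec$hazard_dead, spec$hazard_alive)
    days <- stats::rexp(n, hz)
    days[days <= 0] <- .Machine$double.eps
    censored <- stats::rbinom(n, 1L, spec$censor_prob) == 1L

    cohort <- structure(
      list(subsets = subsets,
           samples = data.frame(sample_id = ids, vital_status = status,
                                survival_days = days, censored = censored,
                                stringsAsFactors = FALSE),
           spec = spec),
      class = "omics_cohort")
    protected <- c(spec$planted_amplifications$gene_id, spec$planted_degs$gene_id)
    inject_missingness(cohort, spec$zero_fraction, spec$missing_fraction,
                       seed = spec$seed + 1L, protect = protected)
  })
}

subset_provenance <- function(s) {
  switch(s,
    "DNA-seq" = "weighted median of strand copy numbers (level-3 segments, per gene)",
    "RNA-seq" = "upper-quartile FPKM (FPKM-UQ) expression",
    "Methylation" = "methylated over total array intensity (beta ratio)",
    "miRNA-seq" = "miRNA read counts",
    "Protein" = "RPPA relative protein level (supercurve interpolation)",
    "")
}

#' Inject zeros and absent entries into a cohort
#'
#' Sets a requested fraction of stored entries to zero and marks another
#' fraction absent, uniformly at random across each subset matrix, to
#' exercise the preprocessing filters. Features named in `protect` are left
#' untouched so planted effect sizes remain recoverable.
#'
#' @param cohort an `omics_cohort`.
#' @param zero_fraction,missing_fraction fractions in \[0, 1).
#' @param seed integer RNG seed.
#' @param protect character vector of feature ids to leave untouched.
#' @return A modified copy of the cohort.
#' @export
inject_missingness <- function(cohort, zero_fraction, missing_fraction,
                               seed = 1L, protect = character()) {
  check_cohort(cohort)
  check_fraction(zero_fraction, "zero_fraction")
  check_fraction(missing_fraction, "missing_fraction")
  if (zero_fraction == 0 && missing_fraction == 0) return(cohort)
  with_seed(seed, {
    for (s in names(cohort$subsets)) {
      m <- cohort$subsets[[s]]
      editable <- which(!(feature_ids(m) %in% protect))
      if (!length(editable)) next
      cells <- as.matrix(expand.grid(row = editable, col = seq_len(n_samples(m))))
      ncell <- nrow(cells)
      n_zero <- min(round(zero_fraction * ncell), ncell)
      n_miss <- min(round(missing_fraction * ncell), ncell - n_zero)
      pick <- sample.int(ncell, min(ncell, n_zero + n_miss))
      zc <- cells[pick[seq_len(n_zero)], , drop = FALSE]
      mc <- cells[pick[seq_len(n_miss) + n_zero], , drop = FALSE]
      if (nrow(zc)) m$values[zc] <- 0
      if (nrow(mc)) { m$values[mc] <- NA_real_; m$absent[mc] <- TRUE }
      cohort$subsets[[s]] <- m
    }
    cohort
  })
}

check_cohort <- function(cohort) {
  if (!inherits(cohort, "omics_cohort"))
    stop("expected an `omics_cohort`", call. = FALSE)
  invisible(cohort)
}

#' @export
print.omics_cohort <- function(x, ...) {
  cat(sprintf("<omics_cohort> %d samples (%d alive, %d dead)\n",
              nrow(x$samples), sum(x$samples$vital_status == "alive"),
              sum(x$samples$vital_status == "dead")))
  for (s in names(x$subsets))
    cat(sprintf("  %-12s %4d features x %4d samples\n", s,
                n_features(x$subsets[[s]]), n_samples(x$subsets[[s]])))
  invisible(x)
}
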