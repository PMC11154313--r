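#' Relative copy-number amplification, dead versus alive group
#'
#' Per gene: group mean copy numbers, observed ranges and the relative
#' amplification (ratio of the dead-group mean over the alive-group
#' mean). Records with a ratio strictly greater than `threshold` are
#' flagged as amplified; an alive mean of zero yields an undefined
#' (flagged) record excluded from flagging.
#'
#' @param dead,alive numeric matrices of copy numbers, genes in rows and
#'   samples in columns, with matching row names.
#' @param threshold flagging threshold on the ratio; default 4 (strict
#'   inequality).
#' @return A data frame of class `amplification_table` sorted by gene id:
#'   `gene_id`, `dead_mean`, `dead_min`, `dead_max`, `alive_mean`,
#'   `alive_min`, `alive_max`, `relative_amplification` (also rounded to
#'   2 decimals in `ratio_2dp`), `amplified`, `undefined`.
#' @examples
#' dead <- matrix(c(5.3, 5.4), 1, 2, dimnames = list("FLT3", NULL))
#' alive <- matrix(c(1.3, 1.3), 1, 2, dimnames = list("FLT3", NULL))
#' relative_amplification_table(dead, alive)
#' @export
relative_amplification_table <- function(dead, alive, threshold = 4) {
  genes <- check_group_matrices(dead, alive)
  if (ncol(dead) == 0L || ncol(alive) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  dm <- rowMeans(dead, na.rm = TRUE); am <- rowMeans(alive, na.rm = TRUE)
  ratio <- ifelse(is.finite(am) & am > 0, dm / am, NaN)
  rng <- function(m, f) apply(m, 1, function(x)
    if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE))
  out <- data.frame(
    gene_id = genes,
    dead_mean = dm, dead_min = rng(dead, min), dead_max = rng(dead, max),
    alive_mean = am, alive_min = rng(alive, min), alive_max = rng(alive, max),
    relative_amplification = ratio,
    ratio_2dp = round(ratio, 2),
    undefined = !is.finite(ratio),
    stringsAsFactors = FALSE, row.names = NULL)
  out$amplified <- !out$undefined & out$relative_amplification > threshold
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("amplification_table", "data.frame"))
}

check_group_matrices <- function(dead, alive) {
  if (!is.matrix(dead) || !is.matrix(alive))
    stop("dead and alive must be matrices (genes x samples)", call. = FALSE)
  gd <- rownames(dead); ga <- rownames(alive)
  if (is.null(gd) || is.null(ga) || !identical(gd, ga))
    stop("dead and alive must share identical row names (gene ids)",
         call. = FALSE)
  gd
}

#' Fold-change ranking of expression, dead versus alive group
#'
#' Per gene the ratio of the dead-group mean expression over the
#' alive-group mean, with a pseudocount guarding zero denominators.
#' Returns the genes whose fold change strictly exceeds `threshold`,
#' sorted in descending order and truncated to `top_n`.
#'
#' @inheritParams relative_amplification_table
#' @param threshold fold-change cutoff (strict); default 8.5.
#' @param top_n maximum number of records returned; default 10.
#' @param pseudocount added to both means before the ratio.
#' @return A data frame of class `fold_change_table`: `gene_id`,
#'   `dead_mean_expression`, `alive_mean_expression`, `fold_change`,
#'   `guarded` (TRUE when the pseudocount mattered, i.e. alive mean 0).
#' @export
fold_change_table <- function(dead, alive, threshold = 8.5, top_n = 10L,
                              pseudocount = 1e-8) {
  genes <- check_group_matrices(dead, alive)
  if (ncol(dead) == 0L || ncol(alive) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  dm <- rowMeans(dead, na.rm = TRUE); am <- rowMeans(alive, na.rm = TRUE)
  dm[is.nan(dm)] <- 0; am[is.nan(am)] <- 0  # feature absent in a whole group
  fc <- (dm + pseudocount) / (am + pseudocount)
  out <- data.frame(gene_id = genes,
                    dead_mean_expression = dm,
                    alive_mean_expression = am,
                    fold_change = fc,
                    guarded = am == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[out$fold_change > threshold, , drop = FALSE]
  out <- out[order(-out$fold_change), , drop = FALSE]
  if (nrow(out) > top_n) out <- out[seq_len(top_n), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("fold_change_table", "data.frame"))
}

#' Group comparison of protein levels
#'
#' Per protein: group means with 95% normal-theory confidence intervals,
#' a two-sided F test for variance equality and a two-sided
#' unequal-variance (Welch) t test for the mean difference. Proteins with
#' fewer than two observations in either group are marked not-reported
#' ("NR") rather than raising an error.
#'
#' @inheritParams relative_amplification_table
#' @param conf_level confidence level of the interval; default 0.95.
#' @return A data frame of class `protein_comparison_table`: `protein_id`,
#'   `dead_mean`, `dead_ci_lower`, `dead_ci_upper`, `alive_mean`,
#'   `alive_ci_lower`, `alive_ci_upper`, `f_test_p`, `t_test_p`,
#'   `data_status` (`"complete"` or `"not-reported"`).
#' @export
protein_group_tests <- function(dead, alive, conf_level = 0.95) {
  proteins <- check_group_matrices(dead, alive)
  rows <- lapply(seq_along(proteins), function(i) {
    xd <- dead[i, ]; xa <- alive[i, ]
    xd <- xd[is.finite(xd)]; xa <- xa[is.finite(xa)]
    base <- data.frame(protein_id = proteins[i],
                       dead_mean = NA_real_, dead_ci_lower = NA_real_,
                       dead_ci_upper = NA_real_,
                       alive_mean = NA_real_, alive_ci_lower = NA_real_,
                       alive_ci_upper = NA_real_,
                       f_test_p = NA_real_, t_test_p = NA_real_,
                       data_status = "not-reported",
                       stringsAsFactors = FALSE)
    if (length(xd) < 2L || length(xa) < 2L) return(base)
    ci <- function(x) {
      se <- stats::sd(x) / sqrt(length(x))
      q <- stats::qnorm(1 - (1 - conf_level) / 2)
      c(mean(x), mean(x) - q * se, mean(x) + q * se)
    }
    cid <- ci(xd); cia <- ci(xa)
    tt <- if (stats::sd(xd) == 0 && stats::sd(xa) == 0) {
      # degenerate: identical constants give t = 0, p = 1
      if (isTRUE(all.equal(mean(xd), mean(xa)))) list(p.value = 1)
      else list(p.value = 0)
    } else stats::t.test(xd, xa, var.equal = FALSE)
    ft <- if (stats::sd(xd) == 0 || stats::sd(xa) == 0) list(p.value = NA_real_)
          else stats::var.test(xd, xa)
    base$dead_mean <- cid[1]; base$dead_ci_lower <- cid[2]; base$dead_ci_upper <- cid[3]
    base$alive_mean <- cia[1]; base$alive_ci_lower <- cia[2]; base$alive_ci_upper <- cia[3]
    base$f_test_p <- ft$p.value
    base$t_test_p <- tt$p.value
    base$data_status <- "complete"
    base
  })
  structure(do.call(rbind, rows),
            class = c("protein_comparison_table", "data.frame"))
}

#' Rule-based drug-target triage
#'
#' Applies the selection logic used to shortlist druggable candidates:
#' copy-number amplifications alone are not druggable, so genes present
#' only in the amplification table are excluded; genes whose protein
#' comparison is significant at `alpha` are excluded (the protein level
#' is already informative); genes on the caller-supplied known-marker
#' list lack novelty and are excluded. The remaining up-regulated genes
#' are ranked by fold change. Every gene carries rationale flags
#' justifying its inclusion or exclusion.
#'
#' @param amplifications an [relative_amplification_table()] result (may
#'   be `NULL`).
#' @param fold_changes a [fold_change_table()] result (non-empty).
#' @param protein_comparisons a [protein_group_tests()] result (may be
#'   `NULL`).
#' @param known_markers character vector of gene ids already established
#'   as markers (novelty screen); no database is queried.
#' @param alpha significance level for the protein exclusion; default
#'   0.05.
#' @return An object of class `target_triage`: `candidates` (data frame
#'   ranked by fold change) and `flags` (per-gene rationale: one or more
#'   of `high-fold-change`, `cnv-only`, `protein-informative`,
#'   `known-marker`).
#' @export
triage_drug_targets <- function(amplifications = NULL, fold_changes,
                                protein_comparisons = NULL,
                                known_markers = character(),
                                alpha = 0.05) {
  if (is.null(fold_changes) || nrow(fold_changes) == 0L)
    stop("fold_changes must be non-empty", call. = FALSE)
  fc_genes <- fold_changes$gene_id
  amp_genes <- if (is.null(amplifications)) character() else amplifications$gene_id
  all_genes <- union(fc_genes, amp_genes)
  flags <- setNames(vector("list", length(all_genes)), all_genes)
  sig_proteins <- character()
  if (!is.null(protein_comparisons)) {
    ok <- protein_comparisons$data_status == "complete" &
      !is.na(protein_comparisons$t_test_p) &
      protein_comparisons$t_test_p < alpha
    sig_proteins <- protein_comparisons$protein_id[ok]
  }
  for (g in all_genes) {
    fl <- character()
    if (g %in% fc_genes) fl <- c(fl, "high-fold-change")
    if (g %in% amp_genes && !(g %in% fc_genes)) fl <- c(fl, "cnv-only")
    if (g %in% sig_proteins) fl <- c(fl, "protein-informative")
    if (g %in% known_markers) fl <- c(fl, "known-marker")
    flags[[g]] <- fl
  }
  excluded <- vapply(flags, function(fl)
    any(fl %in% c("cnv-only", "protein-informative", "known-marker")), TRUE)
  cand <- fold_changes[!excluded[fold_changes$gene_id], , drop = FALSE]
  cand <- cand[order(-cand$fold_change), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, flags = flags, alpha = alpha,
                 known_markers = known_markers),
            class = "target_triage")
}

#' @export
print.target_triage <- function(x, ...) {
  cat(sprintf("<target_triage> %d candidate(s) of %d screened genes\n",
              nrow(x$candidates), length(x$flags)))
  if (nrow(x$candidates))
    print(x$candidates[, c("gene_id", "fold_change")], row.names = FALSE)
  invisible(x)
}

#' Split a subset matrix into dead/alive group matrices
#'
#' Convenience accessor: extracts one omics subset from a cohort as two
#' genes-by-samples matrices, dead and alive, imputing nothing (absent
#' entries become `NA`).
#'
#' @param cohort an `omics_cohort`.
#' @param subset subset name.
#' @return A list with `dead` and `alive` matrices.
#' @export
split_by_vital_status <- function(cohort, subset) {
  check_cohort(cohort)
  m <- cohort$subsets[[subset]]
  if (is.null(m)) stop_field("subset", paste("not in cohort:", subset))
  status <- cohort$samples$vital_status[match(sample_ids(m),
                                              cohort$samples$sample_id)]
  list(dead = m$values[, status == "dead", drop = FALSE],
       alive = m$values[, status == "alive", drop = FALSE])
}
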