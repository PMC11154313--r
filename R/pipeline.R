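#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: where the cohort comes from
#' (a directory of TSVs, an in-memory cohort, or a [cohort_spec()] to
#' simulate), the preprocessing and classifier configurations, marker
#' thresholds and the output directory.
#'
#' @param cohort_dir directory of subset TSVs plus `samples.tsv`
#'   (see [write_cohort()]); ignored when `cohort` or `simulate` is given.
#' @param cohort an in-memory `omics_cohort`.
#' @param simulate a [cohort_spec()] to generate the cohort from.
#' @param subsets subsets used by the classifier; default all available.
#' @param preprocess a [preprocess_config()].
#' @param classifier a [classifier_config()].
#' @param amp_threshold,fc_threshold,top_n,alpha marker thresholds.
#' @param known_markers character vector for the novelty screen.
#' @param run_ablation whether to run the subset ablation study.
#' @param out_dir output directory for all artifacts.
#' @param seed global seed, recorded in the manifest.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL, cohort = NULL, simulate = NULL,
                            subsets = NULL,
                            preprocess = preprocess_config(),
                            classifier = classifier_config(),
                            amp_threshold = 4, fc_threshold = 8.5,
                            top_n = 10L, alpha = 0.05,
                            known_markers = character(),
                            run_ablation = FALSE,
                            out_dir = tempfile("vitalnet_run_"),
                            seed = 1L) {
  if (is.null(cohort_dir) && is.null(cohort) && is.null(simulate))
    stop_field("cohort", "supply one of cohort_dir, cohort or simulate")
  structure(list(cohort_dir = cohort_dir, cohort = cohort, simulate = simulate,
                 subsets = subsets, preprocess = preprocess,
                 classifier = classifier, amp_threshold = amp_threshold,
                 fc_threshold = fc_threshold, top_n = check_count(top_n, "top_n"),
                 alpha = alpha, known_markers = known_markers,
                 run_ablation = isTRUE(run_ablation),
                 out_dir = out_dir, seed = check_count(seed, "seed", min = 0L)),
            class = "pipeline_config")
}

#' Run the end-to-end dead-vs-alive analysis
#'
#' Executes the stages in order — simulate (optional), preprocess, train
#' (with the sensitivity restart rule), evaluate (confusion metrics,
#' C-index, Brier, ROC, log-rank; optional subset ablation), markers
#' (relative amplification and fold-change tables, protein tests) and
#' triage — writing every artifact plus a manifest (seeds, stage status
#' and timings, per-filter counts) to `config$out_dir`. Any stage error
#' halts the run; the manifest records the failing stage and message, and
#' the error is re-raised with the stage name.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly, as a list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be a pipeline_config", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("vitalnet")),
                   seed = config$seed, stages = list())
  state <- new.env(parent = emptyenv())

  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- round(proc.time()[["elapsed"]] - t0, 3)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed", seconds = elapsed,
                                       error = conditionMessage(res))
      jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(res)), call. = FALSE)
    }
    manifest$stages[[name]] <<- c(list(status = "completed", seconds = elapsed),
                                  res$info %||% list())
    res$value
  }

  state$cohort <- stage("simulate", function() {
    if (!is.null(config$cohort)) return(list(value = config$cohort))
    if (!is.null(config$simulate)) {
      co <- generate_cohort(config$simulate)
      write_cohort(co, file.path(config$out_dir, "cohort"))
      return(list(value = co, info = list(simulated = TRUE,
                                          n_samples = nrow(co$samples))))
    }
    list(value = NULL, info = list(simulated = FALSE))
  })

  state$asm <- stage("preprocess", function() {
    if (is.null(state$cohort)) state$cohort <- read_cohort(config$cohort_dir)
    subsets <- config$subsets %||% names(state$cohort$subsets)
    asm <- assemble_model_inputs(state$cohort, config$preprocess, subsets)
    jsonlite::write_json(asm$reports,
                         file.path(config$out_dir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA)
    list(value = asm,
         info = list(subsets = subsets, n_samples = length(asm$sample_ids),
                     pad_width = asm$pad_width))
  })

  state$fit <- stage("train", function() {
    fit <- train_with_sensitivity_restart(state$asm$inputs, state$asm$labels,
                                          config$classifier)
    utils::write.table(fit$log, file.path(config$out_dir, "training_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(value = fit,
         info = list(restarts = fit$restarts, converged = fit$converged,
                     min_sensitivity = fit$report$min_sensitivity))
  })

  state$metrics <- stage("evaluate", function() {
    asm <- state$asm
    pred <- predict(state$fit$model, asm$inputs)
    sheet <- state$cohort$samples
    sel <- match(asm$sample_ids, sheet$sample_id)
    rep <- evaluate_predictions(pred$prob_dead, asm$labels,
                                time = sheet$survival_days[sel],
                                censored = sheet$censored[sel])
    utils::write.table(
      data.frame(sample_id = asm$sample_ids, probability = pred$prob_dead,
                 label = pred$label),
      file.path(config$out_dir, "predictions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rep$roc, file.path(config$out_dir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out <- unclass(rep)
    out$confusion <- unclass(out$confusion)
    out$roc <- NULL
    if (config$run_ablation) {
      abl <- ablate_subsets(asm$inputs, asm$labels, config$classifier)
      utils::write.table(abl, file.path(config$out_dir, "ablation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$ablation <- abl
    }
    jsonlite::write_json(out, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    list(value = rep)
  })

  state$markers <- stage("markers", function() {
    co <- state$cohort
    out <- list()
    if ("DNA-seq" %in% names(co$subsets)) {
      g <- split_by_vital_status(co, "DNA-seq")
      out$amplification <- relative_amplification_table(
        g$dead, g$alive, threshold = config$amp_threshold)
      utils::write.table(out$amplification,
                         file.path(config$out_dir, "amplification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("RNA-seq" %in% names(co$subsets)) {
      g <- split_by_vital_status(co, "RNA-seq")
      out$fold_change <- fold_change_table(g$dead, g$alive,
                                           threshold = config$fc_threshold,
                                           top_n = config$top_n)
      utils::write.table(out$fold_change,
                         file.path(config$out_dir, "fold_change.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if ("Protein" %in% names(co$subsets)) {
      g <- split_by_vital_status(co, "Protein")
      out$protein <- protein_group_tests(g$dead, g$alive)
      tab <- out$protein
      # preserve the NR convention in the emitted table
      for (cn in setdiff(names(tab), c("protein_id", "data_status")))
        tab[[cn]] <- ifelse(tab$data_status == "not-reported", "NR",
                            formatC(tab[[cn]], format = "g", digits = 6))
      utils::write.table(tab, file.path(config$out_dir, "protein_tests.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (is.null(out$fold_change) || nrow(out$fold_change) == 0L)
      stop("no up-regulated genes passed the fold-change threshold; nothing to triage",
           call. = FALSE)
    list(value = out,
         info = list(n_amplified = if (is.null(out$amplification)) 0L
                                   else sum(out$amplification$amplified),
                     n_degs = nrow(out$fold_change)))
  })

  state$triage <- stage("triage", function() {
    tri <- triage_drug_targets(state$markers$amplification,
                               state$markers$fold_change,
                               state$markers$protein,
                               known_markers = config$known_markers,
                               alpha = config$alpha)
    jsonlite::write_json(list(candidates = tri$candidates, flags = tri$flags),
                         file.path(config$out_dir, "triage.json"),
                         auto_unbox = TRUE, digits = NA)
    list(value = tri, info = list(n_candidates = nrow(tri$candidates)))
  })

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
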