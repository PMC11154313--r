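#' Fit the multi-omics vital-status classifier
#'
#' The main modelling entry point. Takes either an `omics_cohort` (which
#' is preprocessed and assembled into padded per-subset input blocks) or a
#' ready-made named list of samples-by-width matrices plus a binary label
#' vector, and trains the multi-branch LSTM classifier under the
#' sensitivity restart rule: training is reseeded and repeated until every
#' structurally connected weight has mean absolute output derivative above
#' the configured threshold, or the restart cap is reached.
#'
#' @param x an `omics_cohort` from [generate_cohort()]/[read_cohort()], or
#'   a named list of numeric matrices (samples in rows), one per subset.
#' @param labels integer/logical vector (1 = dead, the positive class);
#'   ignored when `x` is a cohort.
#' @param config a [classifier_config()].
#' @param subsets subset names to use when `x` is a cohort.
#' @param preprocess a [preprocess_config()] applied when `x` is a cohort.
#' @return An object of class `vitalnet` with components `model` (the
#'   trained `vitalnet_model`), `config`, `restarts`, `converged`,
#'   `sensitivity` (the final report), `log` (per-epoch accuracy),
#'   `fitted_prob`, `labels` and `sample_ids`.
#' @examples
#' \donttest{
#' co <- generate_cohort(cohort_spec(n_alive = 40, n_dead = 40, seed = 3))
#' cfg <- classifier_config(lstm_hidden_units = 8, block_length = 16,
#'                          epochs = 15, max_restarts = 2, seed = 1)
#' fit <- vitalnet(co, config = cfg, subsets = c("DNA-seq", "RNA-seq"))
#' print(fit)
#' }
#' @seealso [predict.vitalnet()], [summary.vitalnet()], [cv_vitalnet()],
#'   [ablate_subsets()]
#' @export
vitalnet <- function(x, labels = NULL, config = classifier_config(),
                     subsets = NULL, preprocess = preprocess_config()) {
  cl <- match.call()
  if (inherits(x, "omics_cohort")) {
    asm <- assemble_model_inputs(x, preprocess,
                                 subsets = subsets %||% names(x$subsets))
    inputs <- asm$inputs
    labels <- asm$labels
    ids <- asm$sample_ids
  } else if (is.list(x) && all(vapply(x, is.matrix, TRUE))) {
    if (is.null(labels)) stop("`labels` must be supplied with matrix inputs",
                              call. = FALSE)
    inputs <- x
    labels <- as.integer(labels)
    ids <- rownames(x[[1]]) %||% as.character(seq_len(nrow(x[[1]])))
    asm <- NULL
  } else {
    stop("`x` must be an omics_cohort or a named list of matrices", call. = FALSE)
  }
  if (length(labels) != nrow(inputs[[1]]))
    stop("labels length does not match the number of samples", call. = FALSE)
  res <- train_with_sensitivity_restart(inputs, labels, config)
  fitted <- predict(res$model, inputs)
  structure(list(model = res$model, config = config,
                 restarts = res$restarts, converged = res$converged,
                 sensitivity = res$report, log = res$log,
                 validation_accuracy = res$validation_accuracy,
                 fitted_prob = fitted$prob_dead, labels = labels,
                 sample_ids = ids, assembly = asm, call = cl),
            class = "vitalnet")
}

#' @export
print.vitalnet <- function(x, ...) {
  cat("Multi-omics recurrent vital-status classifier\n\n")
  cat("Call: "); print(x$call)
  print(x$model)
  cat(sprintf("Restart rule: %d run(s), %s (min active sensitivity %.4g, epsilon %.3g)\n",
              x$restarts,
              if (x$converged) "converged" else "cap reached (flagged)",
              x$sensitivity$min_sensitivity, x$sensitivity$epsilon))
  cm <- confusion_matrix(x$labels, as.integer(x$fitted_prob >= 0.5))
  met <- classification_metrics(cm)
  cat(sprintf("Training accuracy %.3f (sensitivity %.3f, specificity %.3f)\n",
              met$accuracy, met$sensitivity, met$specificity))
  invisible(x)
}

#' Summarise a fitted vital-status classifier
#'
#' Reports the architecture, the restart diagnostics, training-set
#' confusion metrics, the per-component sensitivity summary, and the
#' relative importance of each omics subset's fusion input measured as
#' the L1 norm of its outgoing first-layer weights (the autoencoder-style
#' reading of the feed-forward stack; reported, never used for
#' selection).
#'
#' @param object a `vitalnet` fit.
#' @param ... unused.
#' @return An object of class `summary.vitalnet`.
#' @export
summary.vitalnet <- function(object, ...) {
  P <- unpack_params(object$model$theta, object$model$skel)
  imp <- colSums(abs(P$ff.W1))
  names(imp) <- object$model$subsets
  cm <- confusion_matrix(object$labels,
                         as.integer(object$fitted_prob >= 0.5))
  structure(list(fit = object, input_importance = imp,
                 confusion = cm, metrics = classification_metrics(cm)),
            class = "summary.vitalnet")
}

#' @export
print.summary.vitalnet <- function(x, ...) {
  print(x$fit)
  cat("\nFusion-input importance (L1 of outgoing first-layer weights):\n")
  print(round(x$input_importance, 4))
  cat("\nPer-component sensitivities (active weights):\n")
  print(x$fit$sensitivity$by_component, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Predict from a fitted classifier
#'
#' @param object a `vitalnet` fit.
#' @param newdata an `omics_cohort` or named list of matrices; omitting it
#'   returns the fitted values.
#' @param ... unused.
#' @inherit predict.vitalnet_model return
#' @export
predict.vitalnet <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(data.frame(prob_dead = object$fitted_prob,
                      label = ifelse(object$fitted_prob >= 0.5, "dead", "alive"),
                      stringsAsFactors = FALSE))
  if (inherits(newdata, "omics_cohort")) {
    asm <- assemble_model_inputs(newdata, preprocess_config(),
                                 subsets = object$model$subsets)
    newdata <- asm$inputs
  }
  predict(object$model, newdata)
}

#' @export
coef.vitalnet <- function(object, ...) {
  theta <- object$model$theta
  slices <- param_slices(object$model$skel)
  nm <- character(length(theta))
  for (k in seq_len(nrow(slices)))
    nm[slices$start[k]:slices$end[k]] <-
      sprintf("%s[%d]", slices$component[k],
              seq_len(slices$end[k] - slices$start[k] + 1L))
  stats::setNames(theta, nm)
}

#' @export
fitted.vitalnet <- function(object, ...) object$fitted_prob

#' @export
residuals.vitalnet <- function(object, ...) object$labels - object$fitted_prob

#' Plot the training history of a fit
#'
#' Train and validation accuracy per epoch of the accepted run.
#'
#' @param x a `vitalnet` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.vitalnet <- function(x, ...) {
  lg <- x$log
  graphics::plot(lg$epoch, lg$train_accuracy, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "accuracy", ...)
  if (any(is.finite(lg$validation_accuracy)))
    graphics::lines(lg$epoch, lg$validation_accuracy, lty = 2)
  graphics::legend("bottomright", legend = c("train", "validation"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Simulate vital-status labels from the fitted probabilities
#'
#' @param object a `vitalnet` fit.
#' @param nsim number of label vectors to draw.
#' @param seed integer seed.
#' @param ... unused.
#' @return A data frame with `nsim` columns of 0/1 labels drawn
#'   independently from the fitted dead-class probabilities.
#' @export
simulate.vitalnet <- function(object, nsim = 1, seed = NULL, ...) {
  p <- object$fitted_prob
  draw <- function(i) stats::rbinom(length(p), 1L, p)
  out <- if (is.null(seed)) lapply(seq_len(nsim), draw)
         else with_seed(seed, lapply(seq_len(nsim), draw))
  out <- as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
  rownames(out) <- object$sample_ids
  out
}
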