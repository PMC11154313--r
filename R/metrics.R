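#' Confusion matrix for binary vital-status classification
#'
#' Counts actual-versus-predicted cells with dead as the positive class.
#'
#' @param truth,predicted equal-length binary vectors (1/TRUE/"dead" =
#'   positive).
#' @param tp,fn,fp,tn alternatively, the four counts directly.
#' @return An object of class `confusion_matrix` with fields `tp`, `fn`,
#'   `fp`, `tn`.
#' @examples
#' confusion_matrix(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' confusion_matrix(tp = 4061, fn = 203, fp = 128, tn = 3071)
#' @export
confusion_matrix <- function(truth = NULL, predicted = NULL,
                             tp = NULL, fn = NULL, fp = NULL, tn = NULL) {
  if (is.null(tp)) {
    if (length(truth) != length(predicted))
      stop("truth and predicted must have equal length", call. = FALSE)
    t1 <- as_binary(truth); p1 <- as_binary(predicted)
    tp <- sum(t1 & p1); fn <- sum(t1 & !p1)
    fp <- sum(!t1 & p1); tn <- sum(!t1 & !p1)
  }
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

as_binary <- function(x) {
  if (is.character(x) || is.factor(x)) as.character(x) == "dead"
  else as.logical(as.numeric(x))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("actual+", "actual-"),
                              c("predicted+", "predicted-")))
  print(m)
  invisible(x)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' accuracy = (tp+tn)/total, sensitivity = tp/(tp+fn),
#' specificity = tn/(tn+fp). A zero denominator yields `NaN` (flagged as
#' undefined, never a silent 0).
#'
#' @param cm a [confusion_matrix()].
#' @return A list with `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' classification_metrics(confusion_matrix(tp = 4061, fn = 203,
#'                                         fp = 128, tn = 3071))
#' @export
classification_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) stop("expected a confusion_matrix",
                                              call. = FALSE)
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  safe_div <- function(num, den) if (den > 0) num / den else NaN
  list(accuracy = safe_div(cm$tp + cm$tn, total),
       sensitivity = safe_div(cm$tp, cm$tp + cm$fn),
       specificity = safe_div(cm$tn, cm$tn + cm$fp))
}

#' Harrell concordance index
#'
#' The fraction of comparable pairs whose predicted risk ordering agrees
#' with the outcome ordering. A pair is comparable when the member with
#' the shorter survival time had an observed event; it is concordant when
#' that member also has the higher risk score, and ties in risk count
#' one half.
#'
#' @param risk numeric risk scores (higher = expected shorter survival).
#' @param event 1/TRUE if the event (death) was observed, 0 if censored.
#' @param time positive survival times.
#' @return Concordance in \[0,1\], or `NaN` (flagged undefined) when no
#'   pair is comparable.
#' @export
harrell_c_index <- function(risk, event, time) {
  n <- length(risk)
  if (length(event) != n || length(time) != n)
    stop("risk, event and time must have equal length", call. = FALSE)
  if (any(time <= 0)) stop("times must be > 0", call. = FALSE)
  event <- as.logical(as.numeric(event))
  concordant <- 0
  comparable <- 0
  # pairs ordered by the event member with the shorter time
  for (i in which(event)) {
    later <- time > time[i]
    comparable <- comparable + sum(later)
    concordant <- concordant + sum(risk[i] > risk[later]) +
      0.5 * sum(risk[i] == risk[later])
  }
  if (comparable == 0) return(NaN)
  concordant / comparable
}

#' Brier score at the binary vital-status endpoint
#'
#' Mean squared difference between the predicted positive-class
#' probability and the observed binary outcome; larger scores indicate
#' higher inaccuracy.
#'
#' @param prob predicted probabilities in \[0,1\].
#' @param outcome binary outcomes.
#' @return Score in \[0,1\].
#' @export
brier_score <- function(prob, outcome) {
  if (length(prob) != length(outcome))
    stop("prob and outcome must have equal length", call. = FALSE)
  if (any(prob < 0 | prob > 1)) stop("probabilities must lie in [0,1]",
                                     call. = FALSE)
  y <- as.numeric(as_binary(outcome))
  mean((prob - y)^2)
}

#' ROC points and area under the curve
#'
#' Sweeps the decision threshold over the distinct score values plus
#' infinite endpoints, emitting (FPR, TPR) points and the trapezoidal
#' area. With no censoring the area equals pairwise concordance.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels.
#' @return A list with `points` (data frame `threshold`, `fpr`, `tpr`) and
#'   `auc`.
#' @export
roc_points <- function(scores, labels) {
  y <- as_binary(labels)
  if (!any(y) || all(y)) stop("both classes must be present", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  pts <- t(vapply(thr, function(th) {
    pred <- scores >= th
    c(fpr = sum(pred & !y) / sum(!y), tpr = sum(pred & y) / sum(y))
  }, numeric(2)))
  auc <- sum(diff(pts[, "fpr"]) * (utils::head(pts[, "tpr"], -1) +
                                     utils::tail(pts[, "tpr"], -1)) / 2)
  list(points = data.frame(threshold = thr, fpr = pts[, "fpr"],
                           tpr = pts[, "tpr"]),
       auc = auc)
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison of two survival curves: at each distinct
#' event time, observed versus expected events under the pooled-risk
#' null; the statistic is chi-squared with one degree of freedom.
#'
#' @param time_a,event_a times and event indicators of group A.
#' @param time_b,event_b times and event indicators of group B.
#' @return A list with `statistic`, `p_value` and `df`. With no events in
#'   either group both are `NaN` (flagged undefined).
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b))
    stop("both groups must be non-empty", call. = FALSE)
  ev_a <- as.numeric(as_binary(event_a)); ev_b <- as.numeric(as_binary(event_b))
  if (sum(ev_a) + sum(ev_b) == 0)
    return(list(statistic = NaN, p_value = NaN, df = 1L))
  time <- c(time_a, time_b)
  event <- c(ev_a, ev_b)
  group <- factor(rep(c("a", "b"), c(length(time_a), length(time_b))))
  if (stats::var(event) == 0 && length(unique(time)) == 1L)
    return(list(statistic = 0, p_value = 1, df = 1L))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd_$chisq
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
       df = 1L)
}

#' Kaplan-Meier step-function table
#'
#' Product-limit survival estimate for each group, emitted as a plain
#' table (time, at risk, events, survival) suitable for plotting a step
#' curve.
#'
#' @param time,event survival times and event indicators.
#' @param group group labels.
#' @return A data frame with columns `group`, `time`, `n_risk`,
#'   `n_event`, `survival`.
#' @export
km_table <- function(time, event, group) {
  fit <- survival::survfit(survival::Surv(time, as.numeric(as_binary(event))) ~
                             group)
  strata <- if (is.null(fit$strata)) setNames(length(fit$time), "all")
            else fit$strata
  data.frame(group = rep(sub("^group=", "", names(strata)), strata),
             time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv, row.names = NULL)
}

#' Full evaluation report for a set of predictions
#'
#' Bundles the confusion-matrix metrics, Harrell C-index (risk score =
#' predicted dead-class probability), Brier score, ROC area and the
#' two-group log-rank test of predicted risk groups into one report.
#' A C-index near 0.70 is conventionally annotated as a good model and
#' 0.50 as random background.
#'
#' @param prob predicted dead-class probabilities.
#' @param labels observed binary vital status (1 = dead).
#' @param time optional survival times (days).
#' @param censored optional logical censoring flags (`TRUE` = censored).
#' @param mean_fold_accuracy optional CV accuracy to carry in the report.
#' @return An object of class `metrics_report`.
#' @export
evaluate_predictions <- function(prob, labels, time = NULL, censored = NULL,
                                 mean_fold_accuracy = NA_real_) {
  y <- as.numeric(as_binary(labels))
  cm <- confusion_matrix(y, as.integer(prob >= 0.5))
  met <- classification_metrics(cm)
  roc <- roc_points(prob, y)
  out <- list(confusion = cm,
              accuracy = met$accuracy, sensitivity = met$sensitivity,
              specificity = met$specificity,
              brier = brier_score(prob, y),
              auc = roc$auc, roc = roc$points,
              mean_fold_accuracy = mean_fold_accuracy,
              c_index = NA_real_, logrank_statistic = NA_real_,
              logrank_p = NA_real_)
  if (!is.null(time)) {
    event <- if (is.null(censored)) rep(1, length(time)) else 1 - as.numeric(censored)
    out$c_index <- harrell_c_index(prob, event, time)
    hi <- prob >= stats::median(prob)
    if (any(hi) && any(!hi)) {
      lr <- logrank_test(time[hi], event[hi], time[!hi], event[!hi])
      out$logrank_statistic <- lr$statistic
      out$logrank_p <- lr$p_value
    }
  }
  structure(out, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  accuracy %.3f  sensitivity %.3f  specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("  AUC %.3f  Brier %.3f  C-index %s  log-rank p %s\n",
              x$auc, x$brier,
              ifelse(is.na(x$c_index), "-", sprintf("%.3f", x$c_index)),
              ifelse(is.na(x$logrank_p), "-", format.pval(x$logrank_p, digits = 3))))
  invisible(x)
}
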