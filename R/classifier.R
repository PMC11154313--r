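#' Sigmoid activation-parameter partition
#'
#' The feed-forward stack uses parametrised sigmoid units
#' \eqn{\sigma_p(x) = 1/(1+e^{-px})}. Unit slopes are drawn uniformly from
#' `sampling_interval`, avoiding a biased hand selection of activation
#' shapes; `bounds` records the ordered parameter grid
#' \eqn{P_{min} < P_2 < \dots < P_{max}} the draw is conceived over. The
#' slopes are fixed at build time and are not trained.
#'
#' @param n_functions number of grid points (>= 2).
#' @param sampling_interval length-2 numeric `(low, high)`.
#' @param bounds optional strictly increasing grid; defaults to
#'   `n_functions` equally spaced points spanning `sampling_interval`.
#' @return An object of class `activation_partition`.
#' @export
activation_partition <- function(n_functions = 8L,
                                 sampling_interval = c(-1, 1),
                                 bounds = NULL) {
  n_functions <- check_count(n_functions, "n_functions", min = 2L)
  if (!is.numeric(sampling_interval) || length(sampling_interval) != 2L ||
      sampling_interval[1] >= sampling_interval[2])
    stop_field("sampling_interval", "must be (low, high) with low < high")
  if (is.null(bounds))
    bounds <- seq(sampling_interval[1], sampling_interval[2],
                  length.out = n_functions)
  if (is.unsorted(bounds, strictly = TRUE))
    stop_field("bounds", "must be strictly increasing")
  structure(list(n_functions = n_functions, bounds = bounds,
                 sampling_interval = sampling_interval),
            class = "activation_partition")
}

#' Classifier architecture and training configuration
#'
#' All constants of the multi-branch recurrent classifier: one LSTM branch
#' per omics subset (`lstm_hidden_units` hidden units, one scalar output),
#' a binary switching layer gating each branch, a dropout layer
#' (`dropout_rate`), a feed-forward stack (`ff_hidden_widths`, parametrised
#' sigmoid activations) and a two-way softmax head. Training uses Adam with
#' minibatches, early stopping on held-out accuracy, k-fold
#' cross-validation, and the sensitivity restart rule: training restarts
#' with a new seed until every (structurally connected) weight's mean
#' absolute output derivative exceeds `sensitivity_threshold`.
#'
#' @param lstm_hidden_units LSTM hidden width per branch; default 128.
#' @param dropout_rate dropout probability after the switching layer.
#' @param ff_hidden_widths widths of the feed-forward hidden layers.
#' @param subset_switches optional named logical, `FALSE` gates a subset's
#'   branch off (it then contributes exact zeros).
#' @param k_folds folds for cross-validation; default 5.
#' @param sensitivity_threshold restart threshold epsilon; default 0.01.
#' @param max_restarts cap on reseeded training runs; default 20.
#' @param adapt_hidden,adapt_tolerance hidden-unit adaptation switch and
#'   minimum accuracy gain required to keep growing.
#' @param epochs,batch_size,learning_rate,patience Adam training constants
#'   and early-stopping patience.
#' @param block_length length of the fixed feature blocks a padded input
#'   vector is split into to form the recurrent sequence.
#' @param init_scale half-width of the uniform LSTM weight initialisation.
#' @param validation_fraction held-out fraction used for early stopping
#'   when no fold structure is supplied.
#' @param activation an [activation_partition()].
#' @param warm_start optional previously built/trained model whose weights
#'   seed the first run (transfer learning); default `NULL`.
#' @param seed integer seed; run r of the restart rule uses `seed + r - 1`.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(lstm_hidden_units = 128L,
                              dropout_rate = 0.5,
                              ff_hidden_widths = c(96L, 76L),
                              subset_switches = NULL,
                              k_folds = 5L,
                              sensitivity_threshold = 0.01,
                              max_restarts = 20L,
                              adapt_hidden = FALSE,
                              adapt_tolerance = 0.01,
                              epochs = 100L,
                              batch_size = 32L,
                              learning_rate = 1e-3,
                              patience = 10L,
                              block_length = 64L,
                              init_scale = 0.01,
                              validation_fraction = 0.2,
                              activation = activation_partition(),
                              warm_start = NULL,
                              seed = 1L) {
  check_fraction(dropout_rate, "dropout_rate")
  if (any(ff_hidden_widths < 1)) stop_field("ff_hidden_widths", "widths must be >= 1")
  if (!is.numeric(sensitivity_threshold) || sensitivity_threshold < 0)
    stop_field("sensitivity_threshold", "epsilon must be >= 0")
  structure(list(
    lstm_hidden_units = check_count(lstm_hidden_units, "lstm_hidden_units"),
    dropout_rate = dropout_rate,
    ff_hidden_widths = as.integer(ff_hidden_widths),
    n_classes = 2L,
    subset_switches = subset_switches,
    k_folds = check_count(k_folds, "k_folds", min = 2L),
    sensitivity_threshold = sensitivity_threshold,
    max_restarts = check_count(max_restarts, "max_restarts"),
    adapt_hidden = isTRUE(adapt_hidden),
    adapt_tolerance = adapt_tolerance,
    epochs = check_count(epochs, "epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    learning_rate = learning_rate,
    patience = check_count(patience, "patience"),
    block_length = check_count(block_length, "block_length"),
    init_scale = init_scale,
    validation_fraction = check_fraction(validation_fraction, "validation_fraction"),
    activation = activation,
    warm_start = warm_start,
    seed = check_count(seed, "seed", min = 0L)),
    class = "classifier_config")
}

#' Build an untrained multi-branch recurrent classifier
#'
#' Instantiates one LSTM branch per subset (each emitting a single scalar),
#' the binary switching layer, and the feed-forward/softmax head whose
#' first layer has one input per subset (a switched-off branch contributes
#' exact zeros there). All parameters are a deterministic function of
#' `seed`: LSTM weights uniform on `(-init_scale, init_scale)` with forget
#' bias 1, feed-forward weights Glorot-uniform, sigmoid slopes drawn from
#' the activation partition's sampling interval.
#'
#' @param config a [classifier_config()].
#' @param input_widths named integer vector, padded input width per subset.
#' @param seed optional override of `config$seed`.
#' @return An object of class `vitalnet_model`.
#' @export
build_model <- function(config, input_widths, seed = config$seed) {
  if (is.null(names(input_widths)))
    stop_field("input_widths", "must be named by subset")
  subsets <- names(input_widths)
  gates <- setNames(rep(TRUE, length(subsets)), subsets)
  sw <- config$subset_switches
  if (!is.null(sw)) gates[names(sw)[names(sw) %in% subsets]] <-
      as.logical(sw[names(sw) %in% subsets])
  if (!any(gates)) stop("all subsets are switched off", call. = FALSE)
  H <- config$lstm_hidden_units
  B <- config$block_length
  skel <- make_skeleton(subsets, H, B, config$ff_hidden_widths, length(subsets))
  with_seed(seed, {
    act <- lapply(config$ff_hidden_widths, function(d)
      stats::runif(d, config$activation$sampling_interval[1],
                   config$activation$sampling_interval[2]))
    theta <- numeric(sum(skeleton_sizes(skel)))
    P <- unpack_params(theta, skel)
    for (s in subsets) {
      P[[paste0("lstm.", s, ".Wx")]][] <-
        stats::runif(4L * H * B, -config$init_scale, config$init_scale)
      P[[paste0("lstm.", s, ".Wh")]][] <-
        stats::runif(4L * H * H, -config$init_scale, config$init_scale)
      b <- numeric(4L * H); b[GATE_F(H)] <- 1  # open forget gates at start
      P[[paste0("lstm.", s, ".b")]][] <- b
      P[[paste0("lstm.", s, ".v")]][] <- stats::runif(H, -1, 1) / sqrt(H)
    }
    for (k in grep("^(ff|out)\\.W", names(skel), value = TRUE)) {
      d <- skel[[k]]
      r <- sqrt(6 / (d[1] + d[2]))
      P[[k]][] <- stats::runif(prod(d), -r, r)
    }
    structure(list(
      subsets = subsets, gates = gates,
      input_widths = vapply(input_widths, as.integer, integer(1)),
      hidden_units = H, block_length = B,
      ff_widths = config$ff_hidden_widths,
      act = act, skel = skel, theta = pack_params(P),
      seed = as.integer(seed), train_seed = as.integer(seed)),
      class = "vitalnet_model")
  })
}

#' @export
print.vitalnet_model <- function(x, ...) {
  on_off <- ifelse(x$gates, "on", "off")
  cat(sprintf("<vitalnet_model> %d LSTM branches (%d hidden units, block %d), %s head\n",
              length(x$subsets), x$hidden_units, x$block_length,
              paste(c(x$ff_widths, 2L), collapse = "-")))
  cat("  branches:", paste(sprintf("%s[%s]", x$subsets, on_off), collapse = " "), "\n")
  cat(sprintf("  %d parameters\n", length(x$theta)))
  invisible(x)
}

#' Number of trainable parameters of a model
#' @param model a `vitalnet_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) length(model$theta)

#' Random k-fold assignment
#'
#' Randomly partitions samples into `k` folds whose sizes differ by at
#' most one; deterministic under `seed`.
#'
#' @param ids sample identifiers.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A data frame of class `fold_assignment` with columns
#'   `sample_id` and `fold`.
#' @export
kfold_split <- function(ids, k = 5L, seed = 1L) {
  k <- check_count(k, "k", min = 2L)
  n <- length(ids)
  if (n < k) stop(sprintf("need at least k = %d samples, have %d", k, n),
                  call. = FALSE)
  with_seed(seed, {
    fold <- integer(n)
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
    structure(data.frame(sample_id = ids, fold = fold, stringsAsFactors = FALSE),
              class = c("fold_assignment", "data.frame"))
  })
}

#' Train a model on all folds but one
#'
#' Gradient training (backpropagation through time on the recurrent
#' branches, Adam updates) on the k-1 training folds with early stopping
#' on held-out accuracy. If `config$warm_start` holds a compatible model
#' its weights are the starting point (transfer learning).
#'
#' @param model a `vitalnet_model` from [build_model()].
#' @param inputs named list of samples-by-width matrices.
#' @param labels integer vector, 1 = dead (positive class).
#' @param folds a [kfold_split()] assignment.
#' @param held_out fold index held out for validation.
#' @param config a [classifier_config()].
#' @return A list with `model` (trained), `log` (per-epoch train/validation
#'   accuracy) and `best_epoch`.
#' @export
train_fold <- function(model, inputs, labels, folds, held_out, config) {
  k <- max(folds$fold)
  if (!held_out %in% seq_len(k))
    stop_field("held_out", sprintf("must be a fold index in 1..%d", k))
  model <- apply_warm_start(model, config)
  nn_train(model, inputs, labels, config,
           val_idx = which(folds$fold == held_out))
}

apply_warm_start <- function(model, config) {
  ws <- config$warm_start
  if (is.null(ws)) return(model)
  if (inherits(ws, "vitalnet")) ws <- ws$model
  if (!inherits(ws, "vitalnet_model"))
    stop_field("warm_start", "must be a vitalnet_model or vitalnet fit")
  if (length(ws$theta) != length(model$theta))
    stop_field("warm_start", "parameter count does not match the new model")
  model$theta <- ws$theta
  model$act <- ws$act
  model
}

#' Per-weight sensitivity of the positive-class output
#'
#' For every weight, the mean over evaluation samples of the absolute
#' partial derivative of the positive-class (dead) pre-softmax output with
#' respect to that weight, computed by exact backpropagation (summed over
#' the recurrent steps of each sample, as finite differences would
#' measure). Weights that are structurally disconnected from the output —
#' a gated-off branch, first-layer columns fed by a gated-off subset, or
#' input weights multiplying feature positions that are identically zero
#' over the evaluation set (zero padding) — have derivative exactly zero
#' by construction; they are recorded but excluded from the restart rule's
#' minimum.
#'
#' @param model a `vitalnet_model`.
#' @param inputs named list of samples-by-width matrices.
#' @param epsilon restart threshold the report is judged against.
#' @return An object of class `sensitivity_report`: `sensitivity` (one
#'   value per weight), `active` (structural-connectivity mask),
#'   `min_sensitivity` (over active weights), `all_above_threshold`,
#'   `epsilon`, `by_component` summary and `slices` (component index map).
#' @export
compute_weight_sensitivities <- function(model, inputs,
                                         epsilon = 0.01) {
  n <- nrow(inputs[[1]])
  if (n == 0L) stop("inputs are empty", call. = FALSE)
  acc <- numeric(length(model$theta))
  dpos <- matrix(c(0, 1), 1L)  # d(output)/d(logit) for the dead-class logit
  for (i in seq_len(n)) {
    xi <- slice_inputs(inputs, i)
    fw <- nn_forward(model, xi, keep_cache = TRUE)
    acc <- acc + abs(nn_backward(model, xi, fw$cache, dpos))
  }
  sens <- acc / n
  active <- structural_active_mask(model, inputs)
  min_s <- if (any(active)) min(sens[active]) else NA_real_
  slices <- param_slices(model$skel)
  by_comp <- do.call(rbind, lapply(seq_len(nrow(slices)), function(k) {
    idx <- slices$start[k]:slices$end[k]
    act <- active[idx]
    data.frame(component = slices$component[k], n_weights = length(idx),
               n_active = sum(act),
               min = if (any(act)) min(sens[idx][act]) else NA_real_,
               mean = if (any(act)) mean(sens[idx][act]) else NA_real_,
               max = if (any(act)) max(sens[idx][act]) else NA_real_)
  }))
  structure(list(sensitivity = sens, active = active,
                 min_sensitivity = min_s,
                 all_above_threshold = isTRUE(min_s > epsilon),
                 epsilon = epsilon, by_component = by_comp,
                 slices = slices, n_samples = n),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %d weights (%d active) over %d samples\n",
              length(x$sensitivity), sum(x$active), x$n_samples))
  cat(sprintf("  min active sensitivity %.4g (epsilon %.3g): %s\n",
              x$min_sensitivity, x$epsilon,
              if (x$all_above_threshold) "all above threshold" else "below threshold"))
  invisible(x)
}

# TRUE for weights that can influence the output given the gates and the
# observed inputs; FALSE marks weights with identically zero derivative.
structural_active_mask <- function(model, inputs) {
  active <- rep(TRUE, length(model$theta))
  slices <- param_slices(model$skel)
  idx_of <- function(comp) {
    k <- match(comp, slices$component)
    slices$start[k]:slices$end[k]
  }
  B <- model$block_length; H <- model$hidden_units
  for (si in seq_along(model$subsets)) {
    s <- model$subsets[[si]]
    if (!model$gates[[s]]) {
      for (p in c("Wx", "Wh", "b", "v", "c"))
        active[idx_of(paste0("lstm.", s, ".", p))] <- FALSE
      # first-layer weights fed by this branch's (zero) fusion input
      w1 <- idx_of("ff.W1")
      m <- matrix(w1, model$ff_widths[1], length(model$subsets))
      active[m[, si]] <- FALSE
      next
    }
    xs <- inputs[[s]]
    seqs <- as_sequence(xs, B)
    seen <- Reduce(`|`, lapply(seqs, function(X) colSums(abs(X)) > 0))
    wx <- matrix(idx_of(paste0("lstm.", s, ".Wx")), 4L * H, B)
    active[wx[, !seen]] <- FALSE
    # the forget gate multiplies the cell state, zero until step two, and the
    # recurrent weights multiply the hidden state, likewise zero at step one
    seen_later <- if (length(seqs) > 1L)
      Reduce(`|`, lapply(seqs[-1L], function(X) colSums(abs(X)) > 0))
    else rep(FALSE, B)
    active[wx[GATE_F(H), !seen_later]] <- FALSE
    if (length(seqs) == 1L) {
      active[idx_of(paste0("lstm.", s, ".Wh"))] <- FALSE
      b <- matrix(idx_of(paste0("lstm.", s, ".b")), 4L * H, 1L)
      active[b[GATE_F(H), 1L]] <- FALSE
    }
  }
  # the metric differentiates the positive-class (dead) pre-softmax output;
  # output weights feeding only the alive logit have derivative 0 by design
  ow <- matrix(idx_of("out.W"), 2L, utils::tail(model$ff_widths, 1L))
  active[ow[1L, ]] <- FALSE
  active[idx_of("out.b")[1L]] <- FALSE
  active
}

# Stratified holdout indices for early stopping.
holdout_indices <- function(labels, fraction, seed) {
  with_seed(seed, {
    idx <- unlist(lapply(unique(labels), function(l) {
      pool <- which(labels == l)
      take <- max(1L, round(fraction * length(pool)))
      sample(pool, min(take, length(pool)))
    }))
    sort(idx)
  })
}

#' Sensitivity-restart training
#'
#' Repeatedly builds and trains the classifier, reseeding run r with
#' `seed + r - 1`, until every structurally connected weight's sensitivity
#' exceeds `config$sensitivity_threshold` or `config$max_restarts` runs
#' have been spent. Each run trains with Adam and early stopping on a
#' stratified held-out split. If the cap is hit the best-validation-
#' accuracy model is returned with `converged = FALSE` (flagged, not an
#' error).
#'
#' @inheritParams train_fold
#' @param config a [classifier_config()].
#' @return A list with `model` (accepted or best model), `restarts` (runs
#'   used), `converged`, `report` (final [compute_weight_sensitivities()]
#'   report), `log` (training log of the returned model) and
#'   `validation_accuracy`.
#' @export
train_with_sensitivity_restart <- function(inputs, labels,
                                           config = classifier_config()) {
  widths <- vapply(inputs, ncol, integer(1))
  eps <- config$sensitivity_threshold
  best <- NULL
  for (r in seq_len(config$max_restarts)) {
    seed_r <- config$seed + r - 1L
    model <- build_model(config, widths, seed = seed_r)
    model$train_seed <- seed_r
    if (r == 1L) model <- apply_warm_start(model, config)
    val_idx <- holdout_indices(labels, config$validation_fraction, seed_r)
    fit <- nn_train(model, inputs, labels, config, val_idx = val_idx)
    report <- compute_weight_sensitivities(fit$model, inputs, epsilon = eps)
    val_acc <- model_accuracy(fit$model, slice_inputs(inputs, val_idx),
                              labels[val_idx])
    run <- list(model = fit$model, restarts = r, converged = report$all_above_threshold,
                report = report, log = fit$log, validation_accuracy = val_acc)
    if (is.null(best) || val_acc > best$validation_accuracy) best <- run
    if (report$all_above_threshold) {
      run$restarts <- r
      return(run)
    }
  }
  best$restarts <- config$max_restarts
  best$converged <- FALSE
  best
}

#' k-fold cross-validation of the classifier
#'
#' Runs the full k-fold protocol: for each fold a fresh model is built
#' (seed `config$seed + fold - 1`), trained on the remaining folds with
#' early stopping on the held-out fold, and scored on it.
#'
#' @inheritParams train_fold
#' @param config a [classifier_config()].
#' @return A list with `folds` (per-fold train/validation accuracy),
#'   `mean_validation_accuracy` and `mean_train_accuracy`.
#' @export
cv_vitalnet <- function(inputs, labels, config = classifier_config()) {
  n <- nrow(inputs[[1]])
  widths <- vapply(inputs, ncol, integer(1))
  folds <- kfold_split(seq_len(n), config$k_folds, seed = config$seed)
  rows <- vector("list", config$k_folds)
  for (f in seq_len(config$k_folds)) {
    model <- build_model(config, widths, seed = config$seed + f - 1L)
    model$train_seed <- config$seed + f - 1L
    fit <- train_fold(model, inputs, labels, folds, f, config)
    vi <- which(folds$fold == f)
    rows[[f]] <- data.frame(
      fold = f,
      train_accuracy = model_accuracy(fit$model, slice_inputs(inputs, -vi),
                                      labels[-vi]),
      validation_accuracy = model_accuracy(fit$model, slice_inputs(inputs, vi),
                                           labels[vi]))
  }
  res <- do.call(rbind, rows)
  list(folds = res,
       mean_validation_accuracy = mean(res$validation_accuracy),
       mean_train_accuracy = mean(res$train_accuracy))
}

#' Progressive hidden-unit adaptation
#'
#' Grows the LSTM hidden width through a fixed schedule, evaluating
#' held-out accuracy at each width, and stops when the accuracy gain
#' drops below `config$adapt_tolerance` (keeping the previous width) or
#' the schedule is exhausted (keeping the last width).
#'
#' @inheritParams train_fold
#' @param config a [classifier_config()].
#' @param schedule increasing widths to try.
#' @return A list with `hidden_units` (chosen width) and `trace` (data
#'   frame of width and held-out accuracy for every width attempted).
#' @export
adapt_hidden_units <- function(inputs, labels, config = classifier_config(),
                               schedule = c(8L, 16L, 32L, 64L, 128L)) {
  val_idx <- holdout_indices(labels, config$validation_fraction, config$seed)
  widths <- vapply(inputs, ncol, integer(1))
  trace <- data.frame(hidden_units = integer(), accuracy = numeric())
  prev_acc <- -Inf
  chosen <- schedule[1]
  for (i in seq_along(schedule)) {
    cfg <- config
    cfg$lstm_hidden_units <- schedule[i]
    model <- build_model(cfg, widths, seed = cfg$seed)
    model$train_seed <- cfg$seed
    fit <- nn_train(model, inputs, labels, cfg, val_idx = val_idx)
    acc <- model_accuracy(fit$model, slice_inputs(inputs, val_idx),
                          labels[val_idx])
    trace <- rbind(trace, data.frame(hidden_units = schedule[i], accuracy = acc))
    if (i > 1L && acc - prev_acc < config$adapt_tolerance) {
      chosen <- schedule[i - 1L]
      return(list(hidden_units = chosen, trace = trace))
    }
    prev_acc <- acc
    chosen <- schedule[i]
  }
  list(hidden_units = chosen, trace = trace)
}

#' Subset ablation study
#'
#' Evaluates each omics subset alone and all subsets together, each under
#' the full k-fold protocol, reporting mean train and validation accuracy
#' per switching configuration.
#'
#' @inheritParams train_fold
#' @param config a [classifier_config()].
#' @return A data frame of class `ablation_result` with one row per
#'   configuration (each single subset, then `"all"`).
#' @export
ablate_subsets <- function(inputs, labels, config = classifier_config()) {
  subsets <- names(inputs)
  if (length(subsets) < 2L) stop("need at least 2 subsets to ablate", call. = FALSE)
  configs <- c(lapply(subsets, function(s) setNames(subsets == s, subsets)),
               list(setNames(rep(TRUE, length(subsets)), subsets)))
  names(configs) <- c(subsets, "all")
  rows <- lapply(names(configs), function(nm) {
    cfg <- config
    cfg$subset_switches <- configs[[nm]]
    cv <- cv_vitalnet(inputs, labels, cfg)
    data.frame(configuration = nm,
               accuracy = cv$mean_validation_accuracy,
               train_accuracy = cv$mean_train_accuracy,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("ablation_result", "data.frame"))
}

#' Predict vital status from a built or trained model
#'
#' @param object a `vitalnet_model`.
#' @param newdata named list of samples-by-width matrices matching the
#'   model's input widths.
#' @param ... unused.
#' @return A data frame with `prob_dead` (positive-class probability) and
#'   `label` (`"dead"` when `prob_dead >= 0.5`: a tie is classed dead).
#'   Dropout is disabled at inference, so predictions are deterministic.
#' @export
predict.vitalnet_model <- function(object, newdata, ...) {
  fw <- nn_forward(object, newdata)
  p <- fw$prob[, 2L]
  data.frame(prob_dead = p,
             label = ifelse(p >= 0.5, "dead", "alive"),
             stringsAsFactors = FALSE)
}
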