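test_that("built models have the closed-form parameter count and are seeded", {
  H <- 4L; B <- 8L; d1 <- 6L; d2 <- 4L
  cfg <- classifier_config(lstm_hidden_units = H, block_length = B,
                           ff_hidden_widths = c(d1, d2), seed = 9)
  m <- build_model(cfg, c(A = 10L, B = 7L))
  per_branch <- 4 * H * (B + H) + 4 * H + H + 1
  ff <- d1 * 2 + d1 + d2 * d1 + d2 + 2 * d2 + 2
  expect_equal(n_parameters(m), 2 * per_branch + ff)

  m2 <- build_model(cfg, c(A = 10L, B = 7L))
  expect_identical(m$theta, m2$theta)
  expect_identical(m$act, m2$act)
  m3 <- build_model(cfg, c(A = 10L, B = 7L), seed = 10)
  expect_false(identical(m$theta, m3$theta))

  cfg_off <- classifier_config(subset_switches = c(A = FALSE, B = FALSE))
  expect_error(build_model(cfg_off, c(A = 10L, B = 7L)), "switched off")
})

test_that("a switched-off subset is exactly disconnected", {
  cfg <- classifier_config(lstm_hidden_units = 4, block_length = 8,
                           ff_hidden_widths = c(6, 4),
                           subset_switches = c(A = TRUE, B = FALSE), seed = 2)
  m <- build_model(cfg, c(A = 10L, B = 7L))
  set.seed(1)
  inputs <- list(A = matrix(rnorm(50), 5, 10), B = matrix(rnorm(35), 5, 7))
  perturbed <- inputs
  perturbed$B <- perturbed$B * 1e6 + 42
  expect_identical(predict(m, inputs), predict(m, perturbed))
  rep <- compute_weight_sensitivities(m, inputs)
  off_idx <- with(rep$slices, {
    sel <- grepl("^lstm\\.B\\.", component)
    unlist(mapply(seq, start[sel], end[sel]))
  })
  expect_true(all(rep$sensitivity[off_idx] == 0))
})

test_that("k-fold splits are balanced partitions, deterministic under seed", {
  f <- kfold_split(letters[1:10], 5, seed = 4)
  expect_equal(unname(table(f$fold)), rep(2L, 5), ignore_attr = TRUE)
  f2 <- kfold_split(letters[1:7], 5, seed = 4)
  expect_equal(sort(unname(table(f2$fold)), decreasing = TRUE),
               c(2L, 2L, 1L, 1L, 1L), ignore_attr = TRUE)
  expect_setequal(f2$sample_id, letters[1:7])
  expect_identical(kfold_split(letters[1:7], 5, seed = 4), f2)
  expect_error(kfold_split(letters[1:3], 5), "at least")
})

test_that("weight sensitivities agree with central finite differences", {
  cfg <- classifier_config(lstm_hidden_units = 4, block_length = 8,
                           ff_hidden_widths = c(6, 4), dropout_rate = 0,
                           init_scale = 0.3, seed = 9)
  m <- build_model(cfg, c(A = 10L, B = 7L))
  expect_lte(n_parameters(m), 500)
  set.seed(42)
  n <- 6
  inputs <- list(A = matrix(rnorm(n * 10), n, 10),
                 B = matrix(rnorm(n * 7), n, 7))
  rep <- compute_weight_sensitivities(m, inputs)
  # oracle: central differences of the positive-class logit, per sample
  h <- 1e-5
  pos_logit <- function(theta, i) {
    m2 <- m; m2$theta <- theta
    xi <- lapply(inputs, function(x) x[i, , drop = FALSE])
    vitalnet:::nn_forward(m2, xi)$logits[1, 2]
  }
  num <- numeric(n_parameters(m))
  for (i in seq_len(n)) {
    num <- num + abs(vapply(seq_along(m$theta), function(j) {
      tp <- m$theta; tp[j] <- tp[j] + h
      tm <- m$theta; tm[j] <- tm[j] - h
      (pos_logit(tp, i) - pos_logit(tm, i)) / (2 * h)
    }, numeric(1)))
  }
  num <- num / n
  rel <- abs(rep$sensitivity - num) / pmax(abs(num), 1e-8)
  expect_lt(max(rel[num > 1e-6]), 1e-4)
  # structurally disconnected weights have exactly zero derivative
  expect_true(all(rep$sensitivity[!rep$active] == 0))
  # single linear path sanity: sensitivities are non-negative everywhere
  expect_true(all(rep$sensitivity >= 0))
})

test_that("training separates two clusters and stays at chance on noise", {
  sep <- separable_inputs(n_per_class = 40, width = 20, seed = 3)
  # dropout off: with a single branch the fusion input is one-dimensional
  # and dropping it removes the whole signal for half of each batch
  cfg <- classifier_config(lstm_hidden_units = 8, block_length = 20,
                           epochs = 80, learning_rate = 0.05, patience = 30,
                           init_scale = 0.05, dropout_rate = 0,
                           k_folds = 4, seed = 1)
  folds <- kfold_split(seq_along(sep$labels), 4, seed = 1)
  model <- build_model(cfg, c(main = 20L))
  fit <- train_fold(model, sep$inputs, sep$labels, folds, held_out = 1, cfg)
  vi <- which(folds$fold == 1)
  acc <- mean((predict(fit$model, lapply(sep$inputs, function(x)
    x[vi, , drop = FALSE]))$prob_dead >= 0.5) == sep$labels[vi])
  expect_gte(acc, 0.95)
  expect_true(all(c("train_accuracy", "validation_accuracy") %in% names(fit$log)))

  # determinism: identical seeds give identical weights
  fit2 <- train_fold(build_model(cfg, c(main = 20L)), sep$inputs, sep$labels,
                     folds, held_out = 1, cfg)
  expect_identical(fit$model$theta, fit2$model$theta)

  # permuted labels: chance-level held-out accuracy
  set.seed(6); perm <- sample(sep$labels)
  fitp <- train_fold(build_model(cfg, c(main = 20L)), sep$inputs, perm,
                     folds, held_out = 1, cfg)
  accp <- mean((predict(fitp$model, lapply(sep$inputs, function(x)
    x[vi, , drop = FALSE]))$prob_dead >= 0.5) == perm[vi])
  expect_gte(accp, 0.3)
  expect_lte(accp, 0.7)
})

test_that("prediction is a proper softmax with the dead tie-break", {
  cfg <- classifier_config(lstm_hidden_units = 4, block_length = 8,
                           ff_hidden_widths = c(5, 3), seed = 7)
  m <- build_model(cfg, c(A = 8L))
  set.seed(2)
  inputs <- list(A = matrix(rnorm(40), 5, 8))
  fw <- vitalnet:::nn_forward(m, inputs)
  expect_equal(rowSums(fw$prob), rep(1, 5), tolerance = 1e-12)
  expect_identical(predict(m, inputs), predict(m, inputs))  # dropout off
  p <- predict(m, inputs)
  expect_identical(p$label, ifelse(p$prob_dead >= 0.5, "dead", "alive"))
  expect_error(predict(m, list(A = matrix(0, 2, 5))), "width mismatch")
})

test_that("the restart rule honours its termination contract", {
  sep <- separable_inputs(n_per_class = 20, width = 12, seed = 5)
  base <- classifier_config(lstm_hidden_units = 4, block_length = 12,
                            ff_hidden_widths = c(5, 3), epochs = 10,
                            learning_rate = 0.02, patience = 5,
                            max_restarts = 3, seed = 2)
  # vacuous threshold: one run, accepted
  cfg0 <- base; cfg0$sensitivity_threshold <- 0
  r0 <- train_with_sensitivity_restart(sep$inputs, sep$labels, cfg0)
  expect_equal(r0$restarts, 1L)
  expect_true(r0$converged)
  # unattainable threshold: exactly max_restarts runs, flagged
  cfg_inf <- base; cfg_inf$sensitivity_threshold <- 1e12
  rinf <- train_with_sensitivity_restart(sep$inputs, sep$labels, cfg_inf)
  expect_equal(rinf$restarts, 3L)
  expect_false(rinf$converged)
  # default epsilon: terminates within the cap; acceptance implies the bound
  r <- train_with_sensitivity_restart(sep$inputs, sep$labels, base)
  expect_lte(r$restarts, base$max_restarts)
  if (r$converged) {
    expect_gt(r$report$min_sensitivity, base$sensitivity_threshold)
    expect_true(all(r$report$sensitivity[r$report$active] >
                      base$sensitivity_threshold))
  } else {
    expect_equal(r$restarts, base$max_restarts)
  }
})

test_that("hidden-unit adaptation follows the accuracy-gain criterion", {
  sep <- separable_inputs(n_per_class = 25, width = 12, seed = 9)
  cfg <- classifier_config(lstm_hidden_units = 8, block_length = 12,
                           ff_hidden_widths = c(5, 3), epochs = 8,
                           learning_rate = 0.02, patience = 4,
                           adapt_hidden = TRUE, adapt_tolerance = 1.0, seed = 3)
  # a gain of 1.0 is impossible: stops after the second width, keeps the first
  res <- adapt_hidden_units(sep$inputs, sep$labels, cfg,
                            schedule = c(4L, 8L, 16L))
  expect_equal(nrow(res$trace), 2L)
  expect_equal(res$hidden_units, 4L)
  # an always-satisfied tolerance exhausts the schedule and keeps the last
  cfg$adapt_tolerance <- -1
  res2 <- adapt_hidden_units(sep$inputs, sep$labels, cfg,
                             schedule = c(2L, 4L))
  expect_equal(res2$hidden_units, 4L)
  expect_equal(res2$trace$hidden_units, c(2L, 4L))
  expect_true(all(is.finite(res2$trace$accuracy)))
})

test_that("ablation evaluates each subset and all subsets together", {
  co <- signal_cohort(n_per_group = 80, seed = 21, subsets_size = 60)
  asm <- assemble_model_inputs(co)
  cfg <- tiny_config(k_folds = 3L)
  ab <- ablate_subsets(asm$inputs, asm$labels, cfg)
  expect_equal(nrow(ab), length(asm$inputs) + 1L)
  expect_identical(ab$configuration, c(names(asm$inputs), "all"))
  expect_true(all(ab$accuracy >= 0 & ab$accuracy <= 1))
  # the planted subset dominates the noise subsets
  acc <- setNames(ab$accuracy, ab$configuration)
  expect_gt(acc[["RNA-seq"]], max(acc[["DNA-seq"]], acc[["Methylation"]]))
  expect_gte(acc[["all"]], acc[["RNA-seq"]] - 0.05)
  expect_error(ablate_subsets(asm$inputs["RNA-seq"], asm$labels, cfg),
               "at least 2")
})
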