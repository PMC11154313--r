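# Fixtures shared across the suite. Everything is generated in code; sizes
# are kept small so single tests run in seconds.

# Assign positional feature/sample ids to a bare matrix.
name_mat <- function(v) {
  rownames(v) <- sprintf("g%03d", seq_len(nrow(v)))
  colnames(v) <- sprintf("s%03d", seq_len(ncol(v)))
  v
}

# A feature_matrix from a plain matrix, with generated ids.
make_fm <- function(values, subset = "RNA-seq") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  feature_matrix(values, subset_name = subset)
}

# Desk-scale training configuration: tiny model, short schedule.
tiny_config <- function(...) {
  defaults <- list(lstm_hidden_units = 8L, block_length = 32L,
                   epochs = 40L, batch_size = 32L, learning_rate = 0.01,
                   patience = 10L, k_folds = 3L, max_restarts = 3L, seed = 1L)
  do.call(classifier_config, utils::modifyList(defaults, list(...)))
}

# Two-subset cohort with signal only in RNA-seq, full protein coverage.
signal_cohort <- function(n_per_group = 60L, seed = 5L, subsets_size = 60L) {
  generate_cohort(cohort_spec(
    n_alive = n_per_group, n_dead = n_per_group, seed = seed,
    features_per_subset = c("DNA-seq" = subsets_size, "RNA-seq" = subsets_size,
                            "Methylation" = subsets_size),
    planted_amplifications = NULL,
    subset_coverage = c("DNA-seq" = 1, "RNA-seq" = 1, "Methylation" = 1)))
}

# Separable two-cluster inputs for direct classifier checks.
separable_inputs <- function(n_per_class = 40L, width = 20L, seed = 3L,
                             shift = 6) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    x1 <- matrix(rnorm(n_per_class * width), n_per_class, width)
    x2 <- matrix(rnorm(n_per_class * width, mean = shift), n_per_class, width)
    list(inputs = list(main = rbind(x1, x2)),
         labels = rep(c(0L, 1L), each = n_per_class))
  })
}
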