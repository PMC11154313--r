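test_that("zero-prevalence filter applies a strictly-greater rule", {
  # five features with zero fractions 0, .1, .2, .3, 1 over ten samples
  v <- matrix(1, 5, 10)
  v[2, 1] <- 0
  v[3, 1:2] <- 0
  v[4, 1:3] <- 0
  v[5, ] <- 0
  m <- make_fm(v)
  kept <- filter_features_by_zeros(m, 0.20)
  expect_identical(feature_ids(kept), c("g001", "g002", "g003"))

  # threshold near one keeps everything without an all-zero feature
  m2 <- make_fm(v[1:4, , drop = FALSE])
  expect_identical(filter_features_by_zeros(m2, 0.999)$values, m2$values)

  expect_error(filter_features_by_zeros(make_fm(matrix(numeric(), 0, 0))),
               "empty")
})

test_that("zero filter matches a brute-force per-feature recount", {
  set.seed(41)
  v <- name_mat(matrix(rlnorm(50 * 40), 50, 40))
  zero_cells <- sample(length(v), 300)
  v[zero_cells] <- 0
  absent_cells <- sample(setdiff(seq_along(v), zero_cells), 150)
  v[absent_cells] <- NA
  m <- make_fm(v)
  kept <- filter_features_by_zeros(m, 0.20)
  # oracle: literal counting per feature
  keep_oracle <- vapply(seq_len(nrow(v)), function(i) {
    present <- !is.na(v[i, ])
    sum(present) > 0 && sum(v[i, present] == 0) / sum(present) <= 0.20
  }, logical(1))
  expect_identical(feature_ids(kept), rownames(v)[keep_oracle])
})

test_that("missing-sample filter is exact at the 20% boundary", {
  v <- matrix(1, 100, 4)
  v[1:20, 2] <- NA  # exactly 20%: stays
  v[1:21, 3] <- NA  # 21%: removed
  m <- make_fm(v)
  expect_identical(filter_samples_by_missing(m, 0.20)$values,
                   m$values[, c(1, 2, 4)])
  # identity with no absent entries
  m0 <- make_fm(matrix(1:12, 3, 4) * 1.0)
  expect_identical(filter_samples_by_missing(m0, 0.20), m0)
  # random mask equals a per-sample recount
  set.seed(17)
  v2 <- name_mat(matrix(rnorm(30 * 25), 30, 25))
  v2[sample(length(v2), 150)] <- NA
  m2 <- make_fm(v2)
  keep_oracle <- colSums(is.na(v2)) / nrow(v2) <= 0.20
  expect_identical(sample_ids(filter_samples_by_missing(m2, 0.20)),
                   colnames(v2)[keep_oracle])
  expect_error(filter_samples_by_missing(make_fm(matrix(NA_real_, 4, 3))),
               "nothing left")
})

test_that("k-nearest-sample imputation matches a hand-rolled oracle", {
  m0 <- make_fm(matrix(1:12 * 1.0, 3, 4))
  expect_identical(impute_missing(m0, 2), m0)

  # identical samples: the imputed value is the shared value
  v <- matrix(rep(c(1, 2, 5), 6), 3, 6)
  v[2, 4] <- NA
  out <- impute_missing(make_fm(v), 3)
  expect_equal(out$values[2, 4], 2)
  expect_false(any(out$absent))

  # one absent entry in a random 10 x 8 matrix, k = 3
  set.seed(8)
  v2 <- matrix(rnorm(80), 10, 8)
  v2[4, 2] <- NA
  got <- impute_missing(make_fm(v2), 3)$values[4, 2]
  # oracle: explicit distances over mutually present features
  d <- sapply(seq_len(8), function(t) {
    if (t == 2) return(Inf)
    shared <- !is.na(v2[, 2]) & !is.na(v2[, t])
    sqrt(mean((v2[shared, 2] - v2[shared, t])^2))
  })
  nn <- order(d)[1:3]
  expect_equal(got, mean(v2[4, nn]))

  v3 <- matrix(1, 3, 6)
  v3[1, ] <- NA
  expect_error(impute_missing(make_fm(v3), 2), "drop_null_features")
  expect_error(impute_missing(make_fm(v2), 8), "neighbors")
})

test_that("null features are dropped exactly", {
  v <- name_mat(matrix(rlnorm(40), 8, 5))
  v[c(2, 6), ] <- 0
  v[4, ] <- NA  # absent everywhere counts as null too
  out <- drop_null_features(make_fm(v))
  expect_identical(feature_ids(out), rownames(v)[-c(2, 4, 6)])
  m0 <- make_fm(matrix(rlnorm(20), 4, 5))
  expect_identical(drop_null_features(m0), m0)
})

test_that("filters are idempotent and commute with permutation", {
  set.seed(23)
  v <- name_mat(matrix(rlnorm(30 * 20), 30, 20))
  v[sample(length(v), 120)] <- 0
  v[sample(which(v != 0), 60)] <- NA
  m <- make_fm(v)
  for (f in list(function(x) filter_features_by_zeros(x, 0.2),
                 function(x) filter_samples_by_missing(x, 0.2),
                 drop_null_features)) {
    once <- f(m)
    expect_identical(f(once), once)
  }
  # permuting rows first gives the same surviving set, permuted
  perm <- sample(nrow(v))
  mp <- make_fm(v[perm, , drop = FALSE])
  a <- filter_features_by_zeros(m, 0.2)
  b <- filter_features_by_zeros(mp, 0.2)
  expect_setequal(feature_ids(a), feature_ids(b))
  expect_identical(b$values[feature_ids(a)[feature_ids(a) %in% feature_ids(b)], ],
                   a$values[feature_ids(a)[feature_ids(a) %in% feature_ids(b)], ])
})

test_that("assembly pads with zeros and passes values through unscaled", {
  co <- generate_cohort(cohort_spec(
    n_alive = 15, n_dead = 10, seed = 19,
    features_per_subset = c("RNA-seq" = 5L, "Methylation" = 3L),
    planted_amplifications = NULL, planted_degs = NULL,
    zero_fraction = 0, missing_fraction = 0))
  asm <- assemble_model_inputs(co, subsets = c("RNA-seq", "Methylation"))
  expect_equal(unname(vapply(asm$inputs, ncol, integer(1))), c(5L, 5L))
  # the narrow block ends in two zero columns
  expect_true(all(asm$inputs[["Methylation"]][, 4:5] == 0))
  # unpadded entries equal the stored values, elementwise, in feature order
  m <- co$subsets[["RNA-seq"]]
  ord <- order(feature_ids(m))
  expect_identical(unname(asm$inputs[["RNA-seq"]]),
                   unname(t(m$values[ord, asm$sample_ids])))
  # labels aligned with the sheet, dead = 1
  sheet <- co$samples[match(asm$sample_ids, co$samples$sample_id), ]
  expect_identical(asm$labels, as.integer(sheet$vital_status == "dead"))
  # single subset: no padding at all
  asm1 <- assemble_model_inputs(co, subsets = "RNA-seq")
  expect_equal(asm1$pad_width, 5L)
})

test_that("the full cascade removes exactly the designed features and samples", {
  # 50 x 40 constructed matrix exercising every stage at the 20% boundary
  set.seed(77)
  v <- name_mat(matrix(rlnorm(50 * 40, meanlog = 2), 50, 40))
  zero_feats <- 3:7        # > 20% zeros: removed at stage one
  for (i in zero_feats) v[i, 1:9] <- 0       # 9/40 = 22.5%
  v[8, 1:8] <- 0                             # exactly 20% of present: stays
  bad_samples <- c(5, 11, 19)
  for (j in bad_samples) v[31:43, j] <- NA   # 13/50 = 26% absent: removed
  v[20, 10] <- NA                            # a stray absent entry: imputed
  # features observed only in the doomed samples: null after stage two
  null_feats <- c(44, 45)
  v[null_feats, ] <- NA
  v[null_feats, bad_samples] <- 7
  m <- make_fm(v)
  res <- preprocess_matrix(m, preprocess_config())
  expect_setequal(res$report$removed_zero_features, rownames(v)[zero_feats])
  expect_setequal(res$report$removed_missing_samples, colnames(v)[bad_samples])
  expect_setequal(res$report$removed_null_features, rownames(v)[null_feats])
  expect_false(any(res$matrix$absent))
  expect_equal(n_features(res$matrix), 50 - length(zero_feats) - length(null_feats))
  expect_equal(n_samples(res$matrix), 40 - length(bad_samples))
  # feature 8 (exactly 20% zeros) and the imputed entry survived
  expect_true("g008" %in% feature_ids(res$matrix))
  expect_true(is.finite(res$matrix$values["g020", "s010"]))
})
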