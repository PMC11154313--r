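# Published group means used as exact anchors (2 d.p. ratios): a matrix pair
# whose row means equal the printed means reproduces the printed ratios.
two_sample_groups <- function(means_dead, means_alive, genes) {
  spread <- function(m) cbind(m - 0.01, m + 0.01)
  d <- spread(means_dead); a <- spread(means_alive)
  rownames(d) <- rownames(a) <- genes
  list(dead = d, alive = a)
}

test_that("relative amplification reproduces the printed copy-number ratios", {
  g <- two_sample_groups(c(5.34, 5.42, 5.65), c(1.30, 1.32, 1.30),
                         c("FLT3", "GPC3", "HIF1A"))
  tab <- relative_amplification_table(g$dead, g$alive, threshold = 4)
  expect_equal(setNames(tab$ratio_2dp, tab$gene_id),
               c(FLT3 = 4.11, GPC3 = 4.11, HIF1A = 4.35))
  expect_true(all(tab$amplified))
  expect_identical(tab$gene_id, sort(tab$gene_id))

  # identical groups: ratio one, never flagged at threshold 4
  same <- two_sample_groups(c(2, 3), c(2, 3), c("A", "B"))
  tab2 <- relative_amplification_table(same$dead, same$alive, threshold = 4)
  expect_equal(tab2$relative_amplification, c(1, 1))
  expect_false(any(tab2$amplified))

  # zero alive mean: undefined flagged record, excluded from flagging
  g0 <- list(dead = matrix(c(4, 4), 1, 2, dimnames = list("Z", NULL)),
             alive = matrix(c(0, 0), 1, 2, dimnames = list("Z", NULL)))
  tab3 <- relative_amplification_table(g0$dead, g0$alive)
  expect_true(tab3$undefined)
  expect_false(tab3$amplified)
})

test_that("ratios are scale-equivariant", {
  set.seed(6)
  d <- matrix(rlnorm(40, 1), 4, 10, dimnames = list(LETTERS[1:4], NULL))
  a <- matrix(rlnorm(40, 1), 4, 10, dimnames = list(LETTERS[1:4], NULL))
  base <- relative_amplification_table(d, a)$relative_amplification
  scaled <- relative_amplification_table(d * 3, a)$relative_amplification
  expect_equal(scaled, base * 3, tolerance = 1e-12)
  inv <- relative_amplification_table(d, a * 2)$relative_amplification
  expect_equal(inv, base / 2, tolerance = 1e-12)
  fc0 <- fold_change_table(d, a, threshold = 0, pseudocount = 0)$fold_change
  fc3 <- fold_change_table(d * 3, a, threshold = 0, pseudocount = 0)$fold_change
  expect_equal(sort(fc3), sort(base * 3), tolerance = 1e-12)
  expect_equal(sort(fc3), sort(fc0 * 3), tolerance = 1e-12)
})

test_that("fold-change ranking filters, orders and truncates", {
  genes <- c("UP1", "UP2", "UP3", "FLAT")
  d <- matrix(rep(c(26.06, 16.81, 9.18, 2.0) * 10, 3), 4, 3,
              dimnames = list(genes, NULL))
  a <- matrix(rep(10, 12), 4, 3, dimnames = list(genes, NULL))
  fc <- fold_change_table(d, a, threshold = 8.5)
  expect_identical(fc$gene_id, c("UP1", "UP2", "UP3"))
  expect_equal(fc$fold_change, c(26.06, 16.81, 9.18), tolerance = 1e-9)
  # equal group means: nothing passes
  expect_equal(nrow(fold_change_table(a, a, threshold = 8.5)), 0)
  # top_n truncation
  expect_equal(nrow(fold_change_table(d, a, threshold = 0, top_n = 2)), 2)
  # zero denominator is guarded by the pseudocount and flagged
  d0 <- matrix(5, 1, 2, dimnames = list("G", NULL))
  a0 <- matrix(0, 1, 2, dimnames = list("G", NULL))
  fc0 <- fold_change_table(d0, a0, threshold = 8.5)
  expect_true(is.finite(fc0$fold_change))
  expect_true(fc0$guarded)
})

test_that("protein group tests are calibrated and preserve the NR convention", {
  # identical samples: t-test cannot reject
  x <- matrix(rep(c(1.5, 2.0, 2.5, 3.0), 2), 2, 4, byrow = TRUE,
              dimnames = list(c("P1", "P2"), NULL))
  tab <- protein_group_tests(x, x)
  expect_equal(tab$t_test_p, c(1, 1))
  expect_identical(tab$data_status, c("complete", "complete"))
  expect_true(all(tab$dead_ci_lower <= tab$dead_mean &
                    tab$dead_mean <= tab$dead_ci_upper))

  # too few observations: not-reported, never an error
  d <- matrix(c(1, NA, NA, NA), 1, 4, dimnames = list("Q", NULL))
  a <- matrix(rnorm(4), 1, 4, dimnames = list("Q", NULL))
  nr <- protein_group_tests(d, a)
  expect_identical(nr$data_status, "not-reported")
  expect_true(is.na(nr$t_test_p))

  # power: a 3-pooled-SD shift is detected nearly always
  set.seed(21)
  hits <- 0L
  for (r in 1:60) {
    xd <- matrix(rnorm(30, 3, 1), 1, 30, dimnames = list("S", NULL))
    xa <- matrix(rnorm(30, 0, 1), 1, 30, dimnames = list("S", NULL))
    if (protein_group_tests(xd, xa)$t_test_p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.95)
})

test_that("target triage applies every exclusion rule with flags", {
  fc <- structure(data.frame(
    gene_id = c("RPL30", "RPS28P7", "Metazoa_SRP", "H3F3B", "OAZ1"),
    dead_mean_expression = c(260, 168, 103, 98, 95),
    alive_mean_expression = rep(10, 5),
    fold_change = c(26.06, 16.81, 10.33, 9.77, 9.52),
    guarded = FALSE), class = c("fold_change_table", "data.frame"))
  amp <- structure(data.frame(gene_id = c("FLT3", "RPL30"),
                              relative_amplification = c(4.11, 4.2)),
                   class = c("amplification_table", "data.frame"))
  prot <- structure(data.frame(
    protein_id = c("OAZ1", "H3F3B"), t_test_p = c(0.003, 0.4),
    data_status = c("complete", "complete")),
    class = c("protein_comparison_table", "data.frame"))
  known <- c("RPL30", "H3F3B")
  tri <- triage_drug_targets(amp, fc, prot, known_markers = known)
  # survivors: RPS28P7 and Metazoa_SRP, ranked by fold change
  expect_identical(tri$candidates$gene_id, c("RPS28P7", "Metazoa_SRP"))
  expect_true("known-marker" %in% tri$flags[["RPL30"]])
  expect_true("protein-informative" %in% tri$flags[["OAZ1"]])
  expect_true("cnv-only" %in% tri$flags[["FLT3"]])
  expect_true(all(lengths(tri$flags) >= 1))

  # every gene known: empty candidate list, all flagged known-marker
  tri2 <- triage_drug_targets(NULL, fc, NULL, known_markers = fc$gene_id)
  expect_equal(nrow(tri2$candidates), 0)
  expect_true(all(vapply(tri2$flags, function(f) "known-marker" %in% f, TRUE)))

  # a huge fold change cannot rescue a protein-informative gene
  tri3 <- triage_drug_targets(NULL, fc, prot, known_markers = character())
  expect_false("OAZ1" %in% tri3$candidates$gene_id)

  # determinism: identical inputs, identical output
  expect_identical(tri, triage_drug_targets(amp, fc, prot, known_markers = known))
})
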