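test_that("simulation is reproducible and truth bookkeeping is exact", {
  cfg <- sim_config(n_genes = 50, n_clusters = 2, subjects_per_group = 3,
                    cells_per_subject_cluster = 20, seed = 5)
  s1 <- simulate_patterns(cfg)
  s2 <- simulate_patterns(cfg)
  expect_identical(s1$cm$values, s2$cm$values)
  expect_identical(s1$truth, s2$truth)
  # round(0.1 * 50) = 5 differential genes per cluster, split exactly
  for (cl in unique(s1$truth$cluster)) {
    tr <- s1$truth[s1$truth$cluster == cl, ]
    expect_equal(sum(tr$pattern != "null"), 5)
    expect_equal(as.vector(table(factor(tr$pattern[tr$pattern != "null"],
                                        levels = c("DE", "DP", "DM", "DB", "DV")))),
                 c(1L, 1L, 1L, 1L, 1L))
  }
  expect_equal(nrow(s1$cm$values), 2 * 6 * 20)
  expect_equal(length(s1$design$subjects), 6)
})

test_that("null simulation shows only sampling-noise group differences", {
  cfg <- sim_config(n_genes = 60, n_clusters = 1, subjects_per_group = 3,
                    cells_per_subject_cluster = 100, subject_sd = 0,
                    seed = 8)
  sim <- simulate_null(cfg)
  expect_true(all(sim$truth$pattern == "null"))
  grp <- sim$design$y[match(as.character(sim$cm$subject_id),
                            sim$design$subjects)]
  n_per_group <- sum(grp == 0)
  std_diff <- vapply(seq_len(60), function(g) {
    v <- sim$cm$values[, g]
    abs(mean(v[grp == 0]) - mean(v[grp == 1])) / sd(v)
  }, numeric(1))
  expect_true(all(std_diff < 4 / sqrt(n_per_group)))
})

test_that("pooled moments recover the generating parameters within 3 SE", {
  cfg <- sim_config(n_genes = 12, n_clusters = 1, subjects_per_group = 1,
                    cells_per_subject_cluster = 5000, subject_sd = 0,
                    frac_differential = 0, seed = 21)
  sim <- simulate_patterns(cfg)
  for (g in seq_len(12)) {
    v <- sim$cm$values[, g]
    n <- length(v)
    m_true <- sim$params$mean_g1[g]
    v_true <- sim$params$var_g1[g]
    se_mean <- sd(v) / sqrt(n)
    m4 <- mean((v - mean(v))^4)
    se_var <- sqrt((m4 - var(v)^2) / n)
    expect_lt(abs(mean(v) - m_true), 3 * se_mean + 1e-12)
    expect_lt(abs(var(v) - v_true), 3 * se_var + 1e-12)
  }
})

test_that("DB genes have equal group means by construction", {
  cfg <- sim_config(n_genes = 5, n_clusters = 1, subjects_per_group = 1,
                    cells_per_subject_cluster = 10000, subject_sd = 0,
                    frac_differential = 1,
                    pattern_mix = c(DE = 0, DP = 0, DM = 0, DB = 1, DV = 0),
                    seed = 33)
  sim <- simulate_patterns(cfg)
  expect_equal(sim$params$mean_g1, sim$params$mean_g2, tolerance = 1e-12)
  grp <- sim$design$y[match(as.character(sim$cm$subject_id),
                            sim$design$subjects)]
  for (g in 1:5) {
    v <- sim$cm$values[, g]
    dmean <- abs(mean(v[grp == 0]) - mean(v[grp == 1]))
    expect_lt(dmean, 0.02 * sd(v) * 3)  # 3 SE-scale slack at 1e4 cells
  }
  # zero mode separation is rejected at configuration time
  expect_error(sim_config(effect_size = list(de_fold = 2,
                                             dp_props = c(0.3, 0.7),
                                             dm_fold = 2, db_sep = 0,
                                             dv_ratio = 4)),
               class = "kernelde_structural_error")
})

test_that("DV genes carry the configured variance ratio at equal means", {
  cfg <- sim_config(n_genes = 5, n_clusters = 1, subjects_per_group = 1,
                    cells_per_subject_cluster = 10000, subject_sd = 0,
                    frac_differential = 1,
                    pattern_mix = c(DE = 0, DP = 0, DM = 0, DB = 0, DV = 1),
                    seed = 34)
  sim <- simulate_patterns(cfg)
  expect_equal(sim$params$var_g2 / sim$params$var_g1, rep(4, 5),
               tolerance = 1e-10)
  grp <- sim$design$y[match(as.character(sim$cm$subject_id),
                            sim$design$subjects)]
  for (g in 1:5) {
    v <- sim$cm$values[, g]
    ratio <- var(v[grp == 1]) / var(v[grp == 0])
    expect_lt(abs(ratio - 4) / 4, 0.30)  # heavy-tailed variance estimate
    rel_mean <- abs(mean(v[grp == 1]) - mean(v[grp == 0])) / mean(v)
    expect_lt(rel_mean, 0.1)
  }
})

test_that("cell-type-specific batch effects follow the confounded layout and are recoverable", {
  cfg <- sim_config(n_genes = 10, n_clusters = 2, subjects_per_group = 3,
                    cells_per_subject_cluster = 30, seed = 44)
  sim <- simulate_patterns(cfg)
  assign <- default_batch_assignment(sim$design)
  # group 1 = {b1, b1, b2}; group 2 = {b2, b2, b1}
  expect_equal(unname(assign[c("g1_s1", "g1_s2", "g1_s3")]),
               c("b1", "b1", "b2"))
  expect_equal(unname(assign[c("g2_s1", "g2_s2", "g2_s3")]),
               c("b2", "b2", "b1"))
  shifts <- matrix(c(1.5, 0.6, 0.8, 2.0), 2, 2,
                   dimnames = list(c("cluster1", "cluster2"), c("b1", "b2")))
  cm2 <- add_batch_effect(sim$cm, assign, shifts)
  # each (cluster, batch) shift is exactly recoverable from cell-wise ratios
  cell_batch <- assign[as.character(sim$cm$subject_id)]
  for (cl in rownames(shifts)) for (b in colnames(shifts)) {
    idx <- sim$cm$cluster_id == cl & cell_batch == b & sim$cm$values[, 1] > 0
    expect_equal(unique(round(cm2$values[idx, 1] / sim$cm$values[idx, 1], 10)),
                 shifts[cl, b])
  }
  # zero-magnitude (unit) shifts leave the matrix unchanged
  ones <- matrix(1, 2, 2, dimnames = dimnames(shifts))
  expect_identical(add_batch_effect(sim$cm, assign, ones)$values,
                   sim$cm$values)
  expect_error(add_batch_effect(sim$cm, assign[-1], ones),
               class = "kernelde_structural_error")
})

test_that("simulations round-trip through the on-disk writers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 8, n_clusters = 1, subjects_per_group = 2,
                    cells_per_subject_cluster = 10, seed = 9)
  sim <- simulate_patterns(cfg)
  write_simulation(sim, dir, format = "csv")
  cm2 <- load_expression(file.path(dir, "matrix.csv"),
                         file.path(dir, "cells.csv"))
  expect_equal(unname(cm2$values), unname(sim$cm$values))
  d2 <- read_subject_design(file.path(dir, "design.csv"))
  expect_equal(d2$y, sim$design$y)
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(truth), 8)
})
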