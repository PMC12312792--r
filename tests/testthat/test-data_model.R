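test_that("CSV and MTX round trips preserve values and annotations", {
  set.seed(101)
  cm <- cell_matrix(matrix(c(0.5, 1.25, 3, 0, 2, 7), 3, 2),
                    c("s1", "s1", "s2"), c("c1", "c1", "c1"),
                    c("gA", "gB"))
  rownames(cm$values) <- paste0("cell", 1:3)
  for (fmt in c("csv", "mtx")) {
    dir <- withr::local_tempdir()
    write_expression(cm, dir, format = fmt)
    mat_file <- file.path(dir, if (fmt == "csv") "matrix.csv" else "matrix.mtx")
    cm2 <- load_expression(mat_file, file.path(dir, "cells.csv"))
    expect_equal(unname(cm2$values), unname(cm$values))
    expect_equal(as.character(cm2$subject_id), as.character(cm$subject_id))
    expect_equal(as.character(cm2$cluster_id), as.character(cm$cluster_id))
    expect_equal(cm2$feature_names, cm$feature_names)
  }
})

test_that("MatrixMarket read matches direct coordinate expansion", {
  # 5 cells x 4 genes with explicit zeros, written in 10x orientation
  dir <- withr::local_tempdir()
  triplets <- data.frame(gene = c(1, 1, 2, 3, 4, 4),
                         cell = c(1, 3, 2, 5, 1, 4),
                         val = c(2.5, 0, 1, 4, 0, 3.25))
  lines <- c("%%MatrixMarket matrix coordinate real general",
             "4 5 6",
             sprintf("%d %d %g", triplets$gene, triplets$cell, triplets$val))
  writeLines(lines, file.path(dir, "matrix.mtx"))
  writeLines(paste0("g", 1:4), file.path(dir, "features.tsv"))
  writeLines(paste0("cell", 1:5), file.path(dir, "barcodes.tsv"))
  ann <- data.frame(cell_id = paste0("cell", 1:5),
                    subject_id = c("s1", "s1", "s2", "s2", "s2"),
                    cluster_id = rep("c1", 5))
  cm <- load_expression(file.path(dir, "matrix.mtx"), ann)
  dense <- matrix(0, 5, 4)
  for (k in seq_len(nrow(triplets))) {
    dense[triplets$cell[k], triplets$gene[k]] <- triplets$val[k]
  }
  expect_equal(unname(cm$values), dense)
})

test_that("annotation/matrix length mismatch is a structural error", {
  dir <- withr::local_tempdir()
  cm <- tiny_cell_matrix(n_subj = 1, n_cells = 5, n_genes = 2)
  rownames(cm$values) <- paste0("cell", 1:5)
  write_expression(cm, dir, format = "csv")
  bad_ann <- data.frame(cell_id = paste0("cell", 1:4),
                        subject_id = "s1", cluster_id = "c1")
  expect_error(load_expression(file.path(dir, "matrix.csv"), bad_ann),
               class = "kernelde_structural_error")
  expect_error(cell_matrix(matrix(1, 5, 2), rep("s1", 4), rep("c1", 4)),
               class = "kernelde_structural_error")
})

test_that("h5 input is rejected with an informative format error", {
  f <- withr::local_tempfile(fileext = ".h5")
  writeLines("", f)
  expect_error(load_expression(f, data.frame()), class = "kernelde_format_error")
})

test_that("non-zero filter keeps a pair iff every subject clears the threshold", {
  # two subjects x 40 cells; gene g1 has exactly 20 non-zero cells per
  # subject, g2 has 19 for subject s2, g3 is expressed once per subject
  vals <- matrix(0, 80, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  subj <- rep(c("s1", "s2"), each = 40)
  vals[c(1:20, 41:60), 1] <- 1                  # 20 and 20
  vals[c(1:20, 41:59), 2] <- 1                  # 20 and 19
  vals[c(1, 41), 3] <- 1                        # 1 and 1
  cm <- cell_matrix(vals, subj, rep("c1", 80))
  des <- subject_design(c("s1", "s2"), c(0, 1))
  kept <- filter_gene_cluster_pairs(cm, des, min_nonzero = 20)
  expect_equal(kept$feature, "g1")
  kept1 <- filter_gene_cluster_pairs(cm, des, min_nonzero = 1)
  expect_setequal(kept1$feature, c("g1", "g2", "g3"))
})

test_that("a subject absent from a cluster drops the pair without error", {
  vals <- matrix(1, 20, 1, dimnames = list(NULL, "g1"))
  cm <- cell_matrix(vals, rep("s1", 20), rep("c1", 20))
  des <- subject_design(c("s1", "s2"), c(0, 1))
  expect_equal(nrow(filter_gene_cluster_pairs(cm, des, min_nonzero = 1)), 0)
})

test_that("filter is monotone in min_nonzero", {
  set.seed(42)
  cm <- tiny_cell_matrix(n_subj = 4, n_cells = 30, n_genes = 12)
  cm$values[cm$values < 1.5] <- 0    # induce per-gene sparsity
  des <- subject_design(paste0("s", 1:4), c(0, 0, 1, 1))
  prev <- NULL
  for (thr in c(1, 5, 10, 20)) {
    keys <- filter_gene_cluster_pairs(cm, des, min_nonzero = thr)
    ids <- paste(keys$feature, keys$cluster)
    if (!is.null(prev)) expect_true(all(ids %in% prev))
    prev <- ids
  }
})

test_that("pseudobulk aggregates per subject and matches a brute-force loop", {
  cm <- cell_matrix(matrix(c(1, 3, 5, 1, 2, 100), 3, 2),
                    c("sA", "sA", "sB"), rep("c1", 3), c("g1", "g2"))
  des <- subject_design(c("sA", "sB"), c(0, 1))
  expect_equal(unname(pseudobulk(cm, "g1", "c1", des, "mean")), c(2, 5))
  expect_equal(unname(pseudobulk(cm, "g2", "c1", des, "median")), c(1.5, 100))
  # single-cell subject returns that cell's value under any aggregation
  for (agg in c("mean", "median", "sum")) {
    expect_equal(unname(pseudobulk(cm, "g1", "c1", des, agg))[2], 5)
  }
  set.seed(7)
  cm2 <- tiny_cell_matrix(n_subj = 5, n_cells = 13, n_genes = 4)
  des2 <- subject_design(paste0("s", 1:5), c(0, 0, 0, 1, 1))
  for (g in cm2$feature_names) {
    manual <- vapply(des2$subjects, function(s) {
      mean(cm2$values[cm2$subject_id == s, g])
    }, numeric(1))
    expect_equal(pseudobulk(cm2, g, "c1", des2, "mean"), manual)
  }
})

test_that("min-max scaling maps pooled values onto [0,1]", {
  expect_equal(minmax_scale(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(0, 0.25, 0.7, 1)
  expect_equal(minmax_scale(x), x)
  expect_error(minmax_scale(rep(3, 10)), class = "kernelde_degenerate_error")
})

test_that("subject_design validates outcome and covariates", {
  expect_error(subject_design(c("a", "b"), c(1, 1)),
               class = "kernelde_structural_error")
  expect_error(subject_design(c("a", "b", "c"), c(0, 1, 1),
                              X = cbind(1, c(2, 2, 2))),
               class = "kernelde_structural_error")
  d <- subject_design(c("a", "b", "c"), c(0, 1, 1), X = cbind(age = 1:3))
  expect_equal(colnames(d$X)[1], "(Intercept)")
  expect_equal(d$outcome_type, "binary")
})
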