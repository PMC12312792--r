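#' Construct a cell-level expression matrix with subject and cluster annotations
#'
#' The central input container: a cells x features matrix of non-negative,
#' already-normalized expression values together with a subject ID and a
#' cluster (cell type) label for every cell. Group membership is *not* stored
#' per cell; it lives at the subject level in a [subject_design()] and cells
#' inherit it through their subject ID, because the tests performed here
#' treat subjects, not cells, as the experimental unit.
#'
#' @param values numeric matrix, cells in rows, features (genes or protein
#'   markers) in columns. Must be finite with no missing values.
#' @param subject_id character or factor of length `nrow(values)`.
#' @param cluster_id character or factor of length `nrow(values)`.
#' @param feature_names character of length `ncol(values)`; defaults to
#'   `colnames(values)`.
#' @return An object of class `cell_matrix`: a list with elements `values`,
#'   `subject_id`, `cluster_id`, `feature_names`.
#' @examples
#' cm <- cell_matrix(matrix(rpois(20, 5), 10, 2), rep(c("s1", "s2"), each = 5),
#'                   rep("c1", 10), c("gA", "gB"))
#' @export
cell_matrix <- function(values, subject_id, cluster_id,
                        feature_names = colnames(values)) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_structural("`values` must be a numeric matrix (cells x features)")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_structural("`values` contains missing or non-finite entries")
  }
  if (is.null(feature_names)) {
    feature_names <- paste0("feature", seq_len(ncol(values)))
  }
  if (length(feature_names) != ncol(values)) {
    stop_structural("`feature_names` length does not match ncol(values)")
  }
  if (length(subject_id) != nrow(values)) {
    stop_structural(sprintf(
      "annotation length (%d) does not match number of cells (%d)",
      length(subject_id), nrow(values)))
  }
  if (length(cluster_id) != nrow(values)) {
    stop_structural(sprintf(
      "cluster annotation length (%d) does not match number of cells (%d)",
      length(cluster_id), nrow(values)))
  }
  if (anyNA(subject_id) || anyNA(cluster_id)) {
    stop_structural("cells with missing subject or cluster annotation are not allowed")
  }
  colnames(values) <- feature_names
  out <- list(
    values = values,
    subject_id = factor(as.character(subject_id)),
    cluster_id = factor(as.character(cluster_id)),
    feature_names = as.character(feature_names)
  )
  class(out) <- "cell_matrix"
  out
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf(
    "<cell_matrix> %d cells x %d features | %d subjects | %d clusters\n",
    nrow(x$values), ncol(x$values),
    nlevels(x$subject_id), nlevels(x$cluster_id)))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

#' Construct a subject-level design
#'
#' Holds the per-subject outcome (binary group label or continuous trait) and
#' a covariate matrix. An intercept column is appended automatically if `X`
#' does not already contain a constant column.
#'
#' @param subjects character vector of subject IDs; its order fixes the
#'   subject ordering of every distance and kernel matrix built from the
#'   same study.
#' @param y outcome per subject: binary in \{0, 1\} or continuous.
#' @param X optional numeric covariate matrix (subjects x covariates). If
#'   `NULL` an intercept-only design is used.
#' @param outcome_type `"auto"` (default) infers `"binary"` when `y` takes
#'   only the values 0 and 1.
#' @return An object of class `subject_design` with elements `subjects`,
#'   `y`, `X` (including intercept) and `outcome_type`.
#' @export
subject_design <- function(subjects, y, X = NULL,
                           outcome_type = c("auto", "binary", "continuous")) {
  outcome_type <- match.arg(outcome_type)
  subjects <- as.character(subjects)
  n <- length(subjects)
  if (anyDuplicated(subjects)) stop_structural("duplicated subject IDs")
  if (length(y) != n) stop_structural("`y` length does not match `subjects`")
  y <- as.numeric(y)
  if (anyNA(y)) stop_structural("`y` contains missing values")
  if (outcome_type == "auto") {
    outcome_type <- if (all(y %in% c(0, 1))) "binary" else "continuous"
  }
  if (outcome_type == "binary") {
    if (!all(y %in% c(0, 1))) stop_structural("binary outcome must be coded 0/1")
    if (length(unique(y)) < 2) stop_structural("binary outcome must contain both classes")
  }
  if (is.null(X)) {
    X <- matrix(1, n, 1, dimnames = list(subjects, "(Intercept)"))
  } else {
    X <- as.matrix(X)
    if (nrow(X) != n) stop_structural("`X` rows do not match subjects")
    if (anyNA(X)) stop_structural("`X` contains missing values")
    has_const <- any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
    if (!has_const) {
      X <- cbind(`(Intercept)` = 1, X)
    }
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    rownames(X) <- subjects
  }
  if (qr(X)$rank < ncol(X)) {
    stop_structural("covariate matrix X is rank deficient")
  }
  structure(list(subjects = subjects, y = y, X = X,
                 outcome_type = outcome_type),
            class = "subject_design")
}

#' @export
print.subject_design <- function(x, ...) {
  cat(sprintf("<subject_design> %d subjects | outcome: %s | %d covariate column(s)\n",
              length(x$subjects), x$outcome_type, ncol(x$X)))
  invisible(x)
}

has_covariates <- function(design) ncol(design$X) > 1L

# classed error helpers so callers/tests can distinguish failure modes
stop_structural <- function(msg) {
  stop(errorCondition(msg, class = c("kernelde_structural_error", "error")))
}
stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("kernelde_format_error", "error")))
}
stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("kernelde_degenerate_error", "error")))
}

#' Read an expression matrix with cell annotations
#'
#' Supported formats: MatrixMarket (`.mtx` with `features.tsv` and
#' `barcodes.tsv` sidecars in the same directory, genes-in-rows 10x
#' orientation, transposed on read to cells-in-rows) and dense CSV
#' (cells in rows, first column `cell_id`). Cell annotations (columns
#' `cell_id`, `subject_id`, `cluster_id`) come from a companion CSV or a
#' data frame. An HDF5 single-cell container reader is not provided in this
#' build; requesting `format = "h5"` raises an informative error.
#'
#' @param path path to the matrix file.
#' @param annotations path to the per-cell annotation CSV, or a data frame
#'   with columns `cell_id`, `subject_id`, `cluster_id`.
#' @param format `"auto"` (from extension), `"mtx"` or `"csv"`.
#' @return A [cell_matrix()].
#' @export
load_expression <- function(path, annotations,
                            format = c("auto", "mtx", "csv", "h5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", tsv = "csv",
                     h5 = "h5", h5ad = "h5",
                     stop_format(sprintf("cannot infer format of '%s'", path)))
  }
  if (format == "h5") {
    stop_format(paste0(
      "HDF5 input is not supported by this build (no HDF5 R binding ",
      "available); convert to MatrixMarket or CSV"))
  }
  if (format == "mtx") {
    m <- tryCatch(Matrix::readMM(path), error = function(e) {
      stop_format(sprintf("malformed MatrixMarket file '%s': %s",
                          path, conditionMessage(e)))
    })
    dirn <- dirname(path)
    fpath <- file.path(dirn, "features.tsv")
    bpath <- file.path(dirn, "barcodes.tsv")
    if (!file.exists(fpath) || !file.exists(bpath)) {
      stop_format("MatrixMarket input requires features.tsv and barcodes.tsv sidecars")
    }
    feats <- read.delim(fpath, header = FALSE, stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(bpath, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (length(feats) != nrow(m)) {
      stop_structural(sprintf(
        "features.tsv lists %d features but matrix has %d rows",
        length(feats), nrow(m)))
    }
    if (length(cells) != ncol(m)) {
      stop_structural(sprintf(
        "barcodes.tsv lists %d cells but matrix has %d columns",
        length(cells), ncol(m)))
    }
    values <- t(as.matrix(m))           # convert to cells-in-rows
    rownames(values) <- cells
    colnames(values) <- feats
  } else {
    df <- tryCatch(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
                   error = function(e) {
                     stop_format(sprintf("malformed CSV '%s': %s",
                                         path, conditionMessage(e)))
                   })
    if (ncol(df) < 2 || names(df)[1] != "cell_id") {
      stop_format("dense CSV must have a leading 'cell_id' column")
    }
    cells <- as.character(df$cell_id)
    values <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(values)) stop_format("non-numeric expression values in CSV")
    rownames(values) <- cells
  }
  ann <- if (is.data.frame(annotations)) {
    annotations
  } else {
    if (!file.exists(annotations)) {
      stop_format(sprintf("annotation file not found: %s", annotations))
    }
    read.csv(annotations, stringsAsFactors = FALSE)
  }
  need <- c("cell_id", "subject_id", "cluster_id")
  if (!all(need %in% names(ann))) {
    stop_format("annotations must contain columns cell_id, subject_id, cluster_id")
  }
  if (nrow(ann) != nrow(values)) {
    stop_structural(sprintf(
      "annotation lists %d cells but matrix has %d", nrow(ann), nrow(values)))
  }
  idx <- match(rownames(values), ann$cell_id)
  if (anyNA(idx)) stop_structural("annotation cell_id set does not match matrix cells")
  ann <- ann[idx, ]
  cell_matrix(values, ann$subject_id, ann$cluster_id, colnames(values))
}

#' Write a cell matrix (plus annotation sidecars) to disk
#'
#' Inverse of [load_expression()]: `"csv"` writes a dense `matrix.csv` with a
#' `cell_id` column; `"mtx"` writes `matrix.mtx` (genes in rows) with
#' `features.tsv` / `barcodes.tsv`. Both write `cells.csv` with the
#' annotations.
#'
#' @param cm a [cell_matrix()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_expression <- function(cm, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cell_ids <- rownames(cm$values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(cm$values)))
  if (format == "csv") {
    df <- data.frame(cell_id = cell_ids, cm$values, check.names = FALSE)
    write.csv(df, file.path(dir, "matrix.csv"), row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(t(cm$values), sparse = TRUE),
                    file.path(dir, "matrix.mtx"))
    writeLines(cm$feature_names, file.path(dir, "features.tsv"))
    writeLines(cell_ids, file.path(dir, "barcodes.tsv"))
  }
  write.csv(data.frame(cell_id = cell_ids,
                       subject_id = as.character(cm$subject_id),
                       cluster_id = as.character(cm$cluster_id)),
            file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a subject-level design CSV
#'
#' Expects columns `subject_id`, `y`, and optionally further covariate
#' columns, which become the covariate matrix.
#'
#' @param path CSV path.
#' @return A [subject_design()].
#' @export
read_subject_design <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "y") %in% names(df))) {
    stop_format("design CSV must contain columns subject_id and y")
  }
  covars <- setdiff(names(df), c("subject_id", "y"))
  X <- if (length(covars)) as.matrix(df[, covars, drop = FALSE]) else NULL
  subject_design(df$subject_id, df$y, X)
}

#' Filter gene-cluster pairs by per-subject non-zero cell counts
#'
#' A (gene, cluster) pair is retained if and only if, within that cluster,
#' *every* subject of the design has at least `min_nonzero` cells with
#' non-zero expression of that gene. A subject with no cells at all in the
#' cluster counts as zero non-zero cells, so the pair is dropped rather than
#' erroring. The filter is monotone: raising `min_nonzero` never adds pairs.
#'
#' @param cm a [cell_matrix()].
#' @param design a [subject_design()]; defines the subject set.
#' @param min_nonzero minimum non-zero cell count per subject (default 20,
#'   the threshold used for real-data analyses of this kind).
#' @return A data frame with columns `feature` and `cluster`, one row per
#'   retained pair.
#' @export
filter_gene_cluster_pairs <- function(cm, design, min_nonzero = 20) {
  stopifnot(min_nonzero >= 1)
  subj <- design$subjects
  out <- list()
  for (cl in levels(cm$cluster_id)) {
    idx <- cm$cluster_id == cl
    if (!any(idx)) next
    nz <- rowsum((cm$values[idx, , drop = FALSE] > 0) + 0,
                 group = as.character(cm$subject_id[idx]))
    # subjects absent from this cluster contribute zero non-zero cells
    counts <- matrix(0, length(subj), ncol(cm$values),
                     dimnames = list(subj, cm$feature_names))
    present <- intersect(rownames(nz), subj)
    counts[present, ] <- nz[present, , drop = FALSE]
    keep <- colSums(counts >= min_nonzero) == length(subj)
    if (any(keep)) {
      out[[cl]] <- data.frame(feature = cm$feature_names[keep],
                              cluster = cl, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(feature = character(), cluster = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate one gene-cluster pair to a per-subject pseudo-bulk scalar
#'
#' @param cm a [cell_matrix()].
#' @param feature feature (gene) name.
#' @param cluster cluster label.
#' @param design a [subject_design()]; fixes the subject order of the result.
#' @param agg aggregation: `"mean"`, `"median"` or `"sum"`.
#' @return Named numeric vector, one value per design subject; `NA` for a
#'   subject with no cells in the cluster.
#' @export
pseudobulk <- function(cm, feature, cluster, design,
                       agg = c("mean", "median", "sum")) {
  agg <- match.arg(agg)
  if (!feature %in% cm$feature_names) {
    stop_structural(sprintf("unknown feature '%s'", feature))
  }
  idx <- cm$cluster_id == cluster
  v <- cm$values[idx, feature]
  s <- as.character(cm$subject_id[idx])
  f <- switch(agg, mean = mean, median = median, sum = sum)
  agg_by <- vapply(split(v, s), f, numeric(1))
  out <- agg_by[design$subjects]
  names(out) <- design$subjects
  out
}

#' Min-max scale pooled cell values onto [0, 1]
#'
#' One affine map computed from the *pooled* cells of all subjects for a
#' gene-cluster pair, so that every subject's density lives on the same
#' common support. The minimum maps to 0 and the maximum to 1.
#'
#' @param x numeric vector with at least two distinct values.
#' @return Rescaled vector in `[0, 1]`.
#' @export
minmax_scale <- function(x) {
  r <- range(x)
  if (r[1] == r[2]) {
    stop_degenerate("constant input: no distributional comparison possible")
  }
  (x - r[1]) / (r[2] - r[1])
}
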