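#' Run configuration for the differential-expression pipeline
#'
#' @param mode `"psrF"` (default; square-root pseudo-F with hierarchical
#'   adaptive permutation), `"score_pb"` (kernel score test on pseudo-bulk
#'   Euclidean distances) or `"score_sc"` (kernel score test on sqrt-JSD
#'   distances between subject densities).
#' @param aggregation pseudo-bulk aggregation for `score_pb`.
#' @param R density grid size (default 1024).
#' @param plan a [permutation_plan()] for the psrF mode, or `NULL` to skip
#'   permutation inference and report observed statistics only.
#' @param fdr_method `"BH"` (default) or `"BY"` (for dependent gene sets).
#' @param fdr_scope `"joint"` adjusts across all gene-cluster rows,
#'   `"per_cluster"` within each cluster.
#' @param alpha nominal adjusted-p threshold recorded in the output
#'   (default 0.1).
#' @param min_nonzero per-subject non-zero cell filter threshold
#'   (default 20).
#' @param seed master seed; per-pair RNG substreams are derived from it so
#'   results do not depend on processing order.
#' @param eps_h fallback KDE bandwidth for degenerate subjects.
#' @param boot_B bootstrap/permutation replicates for the
#'   covariate-adjusted psrF paths.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("psrF", "score_pb", "score_sc"),
                       aggregation = c("mean", "median", "sum"),
                       R = 1024,
                       plan = permutation_plan(),
                       fdr_method = c("BH", "BY"),
                       fdr_scope = c("joint", "per_cluster"),
                       alpha = 0.1,
                       min_nonzero = 20,
                       seed = 1,
                       eps_h = 1e-3,
                       boot_B = 1000) {
  mode <- match.arg(mode)
  if (!is.null(plan)) stopifnot(inherits(plan, "permutation_plan"))
  structure(list(mode = mode, aggregation = match.arg(aggregation),
                 R = as.integer(R), plan = plan,
                 fdr_method = match.arg(fdr_method),
                 fdr_scope = match.arg(fdr_scope),
                 alpha = alpha, min_nonzero = min_nonzero,
                 seed = as.integer(seed), eps_h = eps_h,
                 boot_B = as.integer(boot_B)),
            class = "run_config")
}

#' Adjust p-values for multiple testing
#'
#' Step-up false-discovery-rate adjustment: Benjamini-Hochberg (`"BH"`) or
#' Benjamini-Yekutieli (`"BY"`, valid under arbitrary dependence — the BH
#' values inflated by `sum(1/k)`). Missing p-values are passed through.
#'
#' @param p vector of p-values in `[0, 1]` (NAs allowed).
#' @param method `"BH"` or `"BY"`.
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_structural("p-values must lie in [0, 1]")
  p.adjust(p, method = method)
}

#' Mann-Whitney ranking AUC
#'
#' Area under the ROC curve of a score that should rank positives above
#' negatives, computed exactly from mid-ranks (ties handled by averaging).
#'
#' @param score numeric ranking score (larger = more likely positive).
#' @param positive logical truth labels.
#' @return AUC in `[0, 1]`.
#' @export
ranking_auc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  ok <- !is.na(score)
  score <- score[ok]; positive <- as.logical(positive[ok])
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop_structural("need both positive and negative labels")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# observed + permuted F_sqrt for one pair via the compiled engine;
# stat_fn continues the RNG stream across adaptive stages
psrf_pair_test <- function(z, assign0, n_subj, H, config) {
  obs <- psrf_engine(z, assign0, n_subj, H, config$R, config$eps_h,
                     0L, TRUE)$observed
  if (!is.finite(obs)) return(list(observed = NA_real_, p = NA_real_, P = 0L))
  if (is.null(config$plan)) {
    return(list(observed = obs, p = NA_real_, P = 0L))
  }
  res <- adaptive_permutation_test(
    obs,
    function(n) psrf_engine(z, assign0, n_subj, H, config$R, config$eps_h,
                            as.integer(n), FALSE)$perms,
    plan = config$plan)
  list(observed = obs, p = res$p, P = res$P)
}

# covariate-adjusted psrF: distances are fixed; only the projection built
# from null-model residuals changes across bootstrap/permutation replicates
psrf_residual_test <- function(z_by_subject, design, config) {
  prof <- density_profile(z_by_subject, R = config$R, eps_h = config$eps_h)
  D <- jsd_distance_matrix(prof)
  B <- psd_sqrt(gower_center(D))
  stat_fn <- function(r) {
    pseudo_F(B, hat_matrix(design, y_override = r))
  }
  res <- if (design$outcome_type == "binary") {
    logistic_residual_bootstrap(design, stat_fn, B = config$boot_B)
  } else {
    freedman_lane(design, stat_fn, B = config$boot_B)
  }
  list(observed = res$observed, p = res$p, P = config$boot_B)
}

#' Differential expression analysis across gene-cluster pairs
#'
#' For every gene-cluster pair passing the non-zero filter: pool the
#' cluster's cells, min-max scale the pooled values to `[0, 1]`, estimate
#' one density per subject on a shared `R`-point grid, form the pairwise
#' sqrt-JSD distance matrix, and test group association. In `psrF` mode
#' the statistic is the square-root pseudo-F of the Gower-centered
#' distances with hierarchical adaptive cell-level permutation (or, when
#' covariates are present / the outcome is continuous, residual
#' bootstrap / Freedman-Lane resampling of the design side). In the score
#' modes a Gaussian kernel of the distances (median-heuristic bandwidth)
#' feeds the kernel score test with a weighted-chi-square null.
#'
#' Results are deterministic given `config$seed`: each pair gets its own
#' RNG substream, so p-values do not depend on the order in which pairs
#' are processed.
#'
#' @param cm a [cell_matrix()].
#' @param design a [subject_design()] covering the same subjects.
#' @param config a [run_config()].
#' @return A data frame of class `de_table` with one row per
#'   filter-passing pair: `gene`, `cluster`, `method`, `statistic`, `p`,
#'   `permutations`, `p_adj`, `n_subjects`, `flag` (`"ok"` or
#'   `"degenerate"`).
#' @export
run_de <- function(cm, design, config = run_config()) {
  stopifnot(inherits(cm, "cell_matrix"), inherits(design, "subject_design"))
  if (!setequal(levels(cm$subject_id), design$subjects)) {
    stop_structural("subject sets of the cell matrix and the design differ")
  }
  n_subj <- length(design$subjects)
  if (min(table(design$y)) < 3 && design$outcome_type == "binary") {
    warning("fewer than 3 subjects in a group: permutation inference will be coarse")
  }
  keys <- filter_gene_cluster_pairs(cm, design, config$min_nonzero)
  keys <- keys[order(keys$cluster, keys$feature), , drop = FALSE]
  n_keys <- nrow(keys)
  out <- data.frame(gene = keys$feature, cluster = keys$cluster,
                    method = config$mode, statistic = NA_real_,
                    p = NA_real_, permutations = 0L, p_adj = NA_real_,
                    n_subjects = n_subj, flag = "ok",
                    stringsAsFactors = FALSE)
  if (!n_keys) {
    class(out) <- c("de_table", "data.frame")
    return(out)
  }
  set.seed(config$seed)
  pair_seeds <- sample.int(.Machine$integer.max - 1L, n_keys)
  use_residual_path <- config$mode == "psrF" &&
    (has_covariates(design) || design$outcome_type == "continuous")
  H <- if (config$mode == "psrF" && !use_residual_path) {
    hat_matrix(design)
  } else NULL

  for (cl in unique(keys$cluster)) {
    cidx <- cm$cluster_id == cl
    vals <- cm$values[cidx, , drop = FALSE]
    assign0 <- match(as.character(cm$subject_id[cidx]), design$subjects) - 1L
    rows <- which(keys$cluster == cl)
    for (k in rows) {
      v <- vals[, keys$feature[k]]
      set.seed(pair_seeds[k])
      res <- tryCatch({
        z <- minmax_scale(v)
        switch(config$mode,
          psrF = if (use_residual_path) {
            psrf_residual_test(
              split(z, factor(design$subjects[assign0 + 1L],
                              levels = design$subjects)),
              design, config)
          } else {
            psrf_pair_test(z, assign0, n_subj, H, config)
          },
          score_pb = {
            zstar <- pseudobulk(cm, keys$feature[k], cl, design,
                                agg = config$aggregation)
            if (anyNA(zstar)) stop_degenerate("subject without cells in cluster")
            D <- abs(outer(zstar, zstar, "-"))
            st <- kernel_score_test(design,
                                    gaussian_kernel(D, median_heuristic(D)))
            list(observed = st$Q, p = st$p, P = 0L)
          },
          score_sc = {
            prof <- density_profile(
              split(z, factor(design$subjects[assign0 + 1L],
                              levels = design$subjects)),
              R = config$R, eps_h = config$eps_h)
            D <- jsd_distance_matrix(prof)
            st <- kernel_score_test(design,
                                    gaussian_kernel(D, median_heuristic(D)))
            list(observed = st$Q, p = st$p, P = 0L)
          })
      }, kernelde_degenerate_error = function(e) NULL)
      if (is.null(res) || is.na(res$observed)) {
        out$flag[k] <- "degenerate"
      } else {
        out$statistic[k] <- res$observed
        out$p[k] <- res$p
        out$permutations[k] <- res$P
      }
    }
  }
  if (config$fdr_scope == "joint") {
    out$p_adj <- adjust_pvalues(out$p, config$fdr_method)
  } else {
    for (cl in unique(out$cluster)) {
      i <- out$cluster == cl
      out$p_adj[i] <- adjust_pvalues(out$p[i], config$fdr_method)
    }
  }
  class(out) <- c("de_table", "data.frame")
  attr(out, "alpha") <- config$alpha
  out
}

#' @export
print.de_table <- function(x, ...) {
  cat(sprintf("<de_table> %d gene-cluster pairs (%d degenerate)\n",
              nrow(x), sum(x$flag != "ok")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10), ...)
  invisible(x)
}

#' Write a DE table as TSV
#'
#' @param x a `de_table` from [run_de()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
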