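#' Configuration for the multi-subject single-cell simulator
#'
#' Describes a two-group, multi-cluster single-cell benchmark in which a
#' fraction of genes per cluster carries one of the five
#' differential-distribution archetypes:
#' \describe{
#'   \item{DE}{location shift of the whole distribution (fold change
#'     `de_fold` on the expression scale for the case group);}
#'   \item{DP}{two shared modes whose mixing proportions differ between
#'     groups (`dp_props` gives the high-mode proportion in control and
#'     case group);}
#'   \item{DM}{unimodal in one group, bimodal (second mode at
#'     `dm_fold` times the first) in the other;}
#'   \item{DB}{unimodal versus an equal mixture of two modes at
#'     `(1 - db_sep)` and `(1 + db_sep)` times the base mean, so the group
#'     means agree exactly by symmetry;}
#'   \item{DV}{equal means but a variance ratio of `dv_ratio` between
#'     groups.}
#' }
#' Values are drawn on the normalized-expression scale from lognormal
#' components parametrized by their mean, or from negative-binomial counts.
#' Each subject receives a per-gene multiplicative jitter
#' (`exp(N(0, subject_sd))` on the mean) so cells within a subject are
#' correlated and subjects — not cells — are the exchangeable unit.
#'
#' @param n_genes genes per cluster.
#' @param n_clusters number of cell clusters.
#' @param subjects_per_group subjects in each of the two groups; either a
#'   single count (equal groups) or a length-2 vector such as `c(4, 3)`.
#' @param cells_per_subject_cluster cells per subject in each cluster.
#' @param frac_differential fraction of genes per cluster carrying a
#'   pattern (default 0.10).
#' @param pattern_mix named proportions over `DE, DP, DM, DB, DV`; must
#'   sum to 1.
#' @param effect_size list with elements `de_fold`, `dp_props` (length-2),
#'   `dm_fold`, `db_sep`, `dv_ratio`.
#' @param noise_family `"lognormal"` (default) or `"negative_binomial"`.
#' @param base_mean_range range of per-gene base means (uniform draw).
#' @param sigma_log_range range of per-gene lognormal shape parameters.
#' @param nb_size negative-binomial size (inverse dispersion) when
#'   `noise_family = "negative_binomial"`.
#' @param subject_sd standard deviation of the per-subject log-scale mean
#'   jitter (0 disables subject random effects).
#' @param dropout per-cell probability of zeroing a value (zero inflation).
#' @param seed optional RNG seed applied at generation time.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500,
                       n_clusters = 3,
                       subjects_per_group = 3,
                       cells_per_subject_cluster = 50,
                       frac_differential = 0.10,
                       pattern_mix = c(DE = 0.2, DP = 0.2, DM = 0.2,
                                       DB = 0.2, DV = 0.2),
                       effect_size = list(de_fold = 2, dp_props = c(0.3, 0.7),
                                          dm_fold = 2, db_sep = 0.5,
                                          dv_ratio = 4),
                       noise_family = c("lognormal", "negative_binomial"),
                       base_mean_range = c(1, 8),
                       sigma_log_range = c(0.3, 0.6),
                       nb_size = 2,
                       subject_sd = 0.1,
                       dropout = 0,
                       seed = NULL) {
  noise_family <- match.arg(noise_family)
  if (length(subjects_per_group) == 1) {
    subjects_per_group <- rep(subjects_per_group, 2)
  }
  stopifnot(length(subjects_per_group) == 2,
            n_genes >= 1, n_clusters >= 1, all(subjects_per_group >= 1),
            cells_per_subject_cluster >= 1,
            frac_differential >= 0, frac_differential <= 1,
            dropout >= 0, dropout < 1, subject_sd >= 0)
  if (abs(sum(pattern_mix) - 1) > 1e-8) {
    stop_structural("pattern_mix must sum to 1")
  }
  if (is.null(names(pattern_mix)) ||
      !all(names(pattern_mix) %in% c("DE", "DP", "DM", "DB", "DV"))) {
    stop_structural("pattern_mix must be named over DE, DP, DM, DB, DV")
  }
  es <- effect_size
  if (!is.null(es$db_sep) && (es$db_sep <= 0 || es$db_sep >= 1)) {
    stop_structural("db_sep must lie in (0, 1): zero mode separation makes DB infeasible")
  }
  structure(list(n_genes = n_genes, n_clusters = n_clusters,
                 subjects_per_group = subjects_per_group,
                 cells_per_subject_cluster = cells_per_subject_cluster,
                 frac_differential = frac_differential,
                 pattern_mix = pattern_mix, effect_size = es,
                 noise_family = noise_family,
                 base_mean_range = base_mean_range,
                 sigma_log_range = sigma_log_range, nb_size = nb_size,
                 subject_sd = subject_sd, dropout = dropout, seed = seed),
            class = "sim_config")
}

# exact integer partition of n_diff across patterns (largest remainder)
partition_patterns <- function(n_diff, mix) {
  raw <- mix * n_diff
  base <- floor(raw)
  rem <- n_diff - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

# lognormal parametrized by its mean m and log-scale sd; NB by mean and size
draw_component_values <- function(n, m, sdlog, family, nb_size) {
  if (family == "lognormal") {
    exp(rnorm(n, log(m) - sdlog^2 / 2, sdlog))
  } else {
    rnbinom(n, mu = m, size = nb_size)
  }
}

# mixture specification for one gene in one group:
# list(means = multipliers of the base mean, props, sdlog, nb_size)
pattern_components <- function(pattern, group, es, sdlog, nb_size) {
  case <- group == 2
  switch(pattern,
    null = list(means = 1, props = 1, sdlog = sdlog, size = nb_size),
    DE = list(means = if (case) es$de_fold else 1, props = 1,
              sdlog = sdlog, size = nb_size),
    DP = list(means = c(1, es$dm_fold),
              props = if (case) c(1 - es$dp_props[2], es$dp_props[2])
                      else c(1 - es$dp_props[1], es$dp_props[1]),
              sdlog = c(sdlog, sdlog), size = c(nb_size, nb_size)),
    DM = if (case) list(means = c(1, es$dm_fold), props = c(0.5, 0.5),
                        sdlog = c(sdlog, sdlog), size = c(nb_size, nb_size))
         else list(means = 1, props = 1, sdlog = sdlog, size = nb_size),
    DB = if (case) list(means = c(1 - es$db_sep, 1 + es$db_sep),
                        props = c(0.5, 0.5), sdlog = c(sdlog, sdlog),
                        size = c(nb_size, nb_size))
         else list(means = 1, props = 1, sdlog = sdlog, size = nb_size),
    DV = if (case) list(means = 1, props = 1,
                        sdlog = sqrt(log1p(es$dv_ratio * expm1(sdlog^2))),
                        size = nb_size / es$dv_ratio)
         else list(means = 1, props = 1, sdlog = sdlog, size = nb_size),
    stop_structural(sprintf("unknown pattern '%s'", pattern)))
}

# expected mean/variance of the mixture with base mean M (lognormal family)
component_moments <- function(comp, M) {
  m <- comp$means * M
  mean_ <- sum(comp$props * m)
  second <- sum(comp$props * m^2 * exp(comp$sdlog^2))
  c(mean = mean_, var = second - mean_^2)
}

#' Simulate a five-pattern multi-subject single-cell benchmark
#'
#' Generates a [cell_matrix()] and matching [subject_design()] for two
#' groups of subjects across several clusters, with
#' `round(frac_differential * n_genes)` genes per cluster carrying a
#' differential pattern, split across the archetypes exactly according to
#' `pattern_mix`. Truth labels (and the generating parameters) are
#' returned for benchmarking.
#'
#' @param config a [sim_config()].
#' @return A list of class `kernelde_sim` with elements `cm`
#'   ([cell_matrix()]), `design` ([subject_design()]), `truth` (data frame
#'   `feature`, `cluster`, `pattern`; `"null"` for non-differential genes)
#'   and `params` (per gene-cluster generating parameters: base mean,
#'   sdlog, and exact expected group means/variances under no subject
#'   jitter or dropout).
#' @export
simulate_patterns <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  spg <- config$subjects_per_group
  n_subj <- sum(spg)
  subjects <- c(paste0("g1_s", seq_len(spg[1])),
                paste0("g2_s", seq_len(spg[2])))
  group <- rep(1:2, times = spg)
  y <- as.numeric(group == 2)
  ncells_sc <- config$cells_per_subject_cluster
  genes <- sprintf("gene%04d", seq_len(config$n_genes))
  clusters <- paste0("cluster", seq_len(config$n_clusters))
  n_diff <- round(config$frac_differential * config$n_genes)
  mix_counts <- partition_patterns(n_diff, config$pattern_mix)

  values <- list(); subj_ann <- list(); clus_ann <- list()
  truth <- list(); params <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    n_cells <- n_subj * ncells_sc
    cell_subject <- rep(subjects, each = ncells_sc)
    cell_group <- rep(group, each = ncells_sc)
    M <- runif(config$n_genes, config$base_mean_range[1],
               config$base_mean_range[2])
    sdlog <- runif(config$n_genes, config$sigma_log_range[1],
                   config$sigma_log_range[2])
    pattern <- rep("null", config$n_genes)
    if (n_diff > 0) {
      diff_idx <- sample.int(config$n_genes, n_diff)
      pattern[diff_idx] <- rep(names(mix_counts), mix_counts)
    }
    subj_fac <- matrix(exp(rnorm(n_subj * config$n_genes, 0,
                                 config$subject_sd)),
                       n_subj, config$n_genes)
    vals <- matrix(0, n_cells, config$n_genes)
    mom <- matrix(0, config$n_genes, 4)
    for (g in seq_len(config$n_genes)) {
      col <- numeric(n_cells)
      for (grp in 1:2) {
        comp <- pattern_components(pattern[g], grp, config$effect_size,
                                   sdlog[g], config$nb_size)
        gcells <- which(cell_group == grp)
        k <- if (length(comp$props) > 1) {
          sample.int(length(comp$props), length(gcells),
                     replace = TRUE, prob = comp$props)
        } else rep(1L, length(gcells))
        si <- match(cell_subject[gcells], subjects)
        m_cell <- M[g] * subj_fac[cbind(si, g)] * comp$means[k]
        col[gcells] <- draw_component_values(
          length(gcells), m_cell, comp$sdlog[k], config$noise_family,
          comp$size[k])
        mom[g, (2 * grp - 1):(2 * grp)] <- component_moments(comp, M[g])
      }
      vals[, g] <- col
    }
    if (config$dropout > 0) {
      vals[matrix(runif(length(vals)) < config$dropout,
                  nrow(vals), ncol(vals))] <- 0
    }
    values[[ci]] <- vals
    subj_ann[[ci]] <- cell_subject
    clus_ann[[ci]] <- rep(cl, n_cells)
    truth[[ci]] <- data.frame(feature = genes, cluster = cl,
                              pattern = pattern, stringsAsFactors = FALSE)
    params[[ci]] <- data.frame(feature = genes, cluster = cl,
                               base_mean = M, sdlog = sdlog,
                               mean_g1 = mom[, 1], var_g1 = mom[, 2],
                               mean_g2 = mom[, 3], var_g2 = mom[, 4],
                               stringsAsFactors = FALSE)
  }
  all_values <- do.call(rbind, values)
  rownames(all_values) <- sprintf("cell%06d", seq_len(nrow(all_values)))
  cm <- cell_matrix(all_values, unlist(subj_ann), unlist(clus_ann), genes)
  design <- subject_design(subjects, y)
  structure(list(cm = cm, design = design,
                 truth = do.call(rbind, truth),
                 params = do.call(rbind, params)),
            class = "kernelde_sim")
}

#' Simulate a pure-null benchmark
#'
#' Both groups are drawn from identical per-gene distributions (subject
#' random effects included), i.e. [simulate_patterns()] with
#' `frac_differential = 0`.
#'
#' @param config a [sim_config()]; its `frac_differential` is forced to 0.
#' @return A `kernelde_sim` list; all truth patterns are `"null"`.
#' @export
simulate_null <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  config$frac_differential <- 0
  simulate_patterns(config)
}

#' @export
print.kernelde_sim <- function(x, ...) {
  nd <- sum(x$truth$pattern != "null")
  cat(sprintf("<kernelde_sim> %d cells x %d genes | %d differential gene-cluster pairs\n",
              nrow(x$cm$values), ncol(x$cm$values), nd))
  invisible(x)
}

#' Batch assignment emulating a confounded two-batch layout
#'
#' Group 1 subjects come from batch `b1` except the last, which comes from
#' `b2`; group 2 mirrors this (`b2` except the last, from `b1`). For two
#' groups of three this is the classic 2+1 / 1+2 partially confounded
#' layout.
#'
#' @param design a [subject_design()] with binary outcome.
#' @return Named character vector mapping subject to `"b1"`/`"b2"`.
#' @export
default_batch_assignment <- function(design) {
  g1 <- design$subjects[design$y == 0]
  g2 <- design$subjects[design$y == 1]
  out <- c(rep("b1", length(g1)), rep("b2", length(g2)))
  names(out) <- c(g1, g2)
  out[g1[length(g1)]] <- "b2"
  out[g2[length(g2)]] <- "b1"
  out
}

#' Add a cell-type-specific batch effect
#'
#' Every (cluster, batch) pair receives its own multiplicative shift,
#' applied to all cells of subjects assigned to that batch, so each cell
#' type experiences a different batch-induced change.
#'
#' @param cm a [cell_matrix()].
#' @param assignment named vector mapping every subject to a batch label
#'   (see [default_batch_assignment()]).
#' @param shifts numeric matrix of multiplicative factors, clusters in
#'   rows (rownames = cluster labels), batches in columns (colnames =
#'   batch labels). A matrix of ones leaves the data unchanged.
#' @return The modified [cell_matrix()].
#' @export
add_batch_effect <- function(cm, assignment, shifts) {
  subjects <- levels(cm$subject_id)
  missing <- setdiff(subjects, names(assignment))
  if (length(missing)) {
    stop_structural(sprintf("subjects with no batch assignment: %s",
                            paste(missing, collapse = ", ")))
  }
  shifts <- as.matrix(shifts)
  cell_batch <- assignment[as.character(cm$subject_id)]
  cell_cluster <- as.character(cm$cluster_id)
  for (cl in rownames(shifts)) {
    for (b in colnames(shifts)) {
      idx <- cell_cluster == cl & cell_batch == b
      if (any(idx)) {
        cm$values[idx, ] <- cm$values[idx, ] * shifts[cl, b]
      }
    }
  }
  cm
}

#' Write a simulated benchmark to disk
#'
#' Writes the expression matrix and annotation sidecars (via
#' [write_expression()]), the subject design (`design.csv`) and the truth
#' labels (`truth.tsv`).
#'
#' @param sim a `kernelde_sim` from [simulate_patterns()]/[simulate_null()].
#' @param dir output directory.
#' @param format matrix format, `"csv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, format = c("csv", "mtx")) {
  write_expression(sim$cm, dir, format = format)
  write.csv(data.frame(subject_id = sim$design$subjects, y = sim$design$y),
            file.path(dir, "design.csv"), row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
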