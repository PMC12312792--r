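#' Adaptive permutation plan
#'
#' Staged schedule for the hierarchical permutation test: start with the
#' first stage's permutation count; whenever the current empirical p-value
#' is at or below the next stage's threshold, escalate to that stage's
#' (cumulative) total. The default schedule is 100 permutations, then 500
#' if `p <= 0.1`, 2000 if `p <= 0.01`, and up to 10000 if `p <= 0.001`.
#'
#' @param n_perm increasing integer vector of cumulative permutation
#'   totals per stage.
#' @param thresholds escalation thresholds; `thresholds[1]` is ignored
#'   (stage 1 always runs) and subsequent entries must be strictly
#'   decreasing.
#' @return Object of class `permutation_plan`.
#' @export
permutation_plan <- function(n_perm = c(100L, 500L, 2000L, 10000L),
                             thresholds = c(1, 0.1, 0.01, 0.001)) {
  n_perm <- as.integer(n_perm)
  if (length(n_perm) != length(thresholds)) {
    stop_structural("`n_perm` and `thresholds` must have equal length")
  }
  if (any(diff(n_perm) <= 0)) {
    stop_structural("stage permutation counts must be strictly increasing")
  }
  if (length(thresholds) > 1 && any(diff(thresholds) >= 0)) {
    stop_structural("stage thresholds must be strictly decreasing")
  }
  if (any(n_perm < 1)) stop_structural("permutation counts must be >= 1")
  structure(list(n_perm = n_perm, thresholds = thresholds),
            class = "permutation_plan")
}

#' @export
print.permutation_plan <- function(x, ...) {
  cat("<permutation_plan> stages:",
      paste(sprintf("%d (p<=%g)", x$n_perm, x$thresholds), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Empirical permutation p-value
#'
#' `p = (#\{F_perm >= F_obs\} + 1) / (P + 1)`. Ties count toward the
#' numerator, and the +1 correction keeps the p-value in
#' `[1/(P+1), 1]` — it can never be zero.
#'
#' @param perm_stats numeric vector of permuted statistics.
#' @param observed observed statistic.
#' @return Empirical p-value.
#' @export
empirical_pvalue <- function(perm_stats, observed) {
  P <- length(perm_stats)
  if (P < 1) stop_structural("need at least one permutation")
  (sum(perm_stats >= observed) + 1) / (P + 1)
}

#' Hierarchical cell-level permutation of subject assignments
#'
#' Shuffles individual cells among subjects while every subject keeps its
#' original cell count; the subject-to-group mapping is untouched. This is
#' the resampling unit of the psrF path: the pooled cell values for a
#' gene-cluster pair are reassigned to subjects uniformly at random and the
#' whole statistic (KDE, JSD distances, Gower centering, square-root
#' pseudo-F) is recomputed on the permuted assignment.
#'
#' @param assign vector of subject labels (or indices), one per cell.
#' @return Permuted assignment vector of the same length with the same
#'   label multiset.
#' @export
hierarchical_permute <- function(assign) {
  if (length(unique(assign)) < 2) {
    stop_structural("need at least 2 subjects with cells")
  }
  sample(assign)
}

#' Adaptive staged permutation test
#'
#' Runs the first stage of the plan, then escalates to the next cumulative
#' permutation total whenever the current empirical p-value is at or below
#' that stage's threshold. `stat_fn(n)` must return `n` newly drawn
#' permuted statistics (continuing its RNG stream across calls).
#'
#' @param observed observed statistic.
#' @param stat_fn function of one argument `n` returning `n` permuted
#'   statistics.
#' @param plan a [permutation_plan()].
#' @return List with `p` (empirical p-value), `P` (total permutations
#'   used), `observed`, and `perm_stats`.
#' @export
adaptive_permutation_test <- function(observed, stat_fn,
                                      plan = permutation_plan()) {
  stopifnot(inherits(plan, "permutation_plan"))
  stats <- numeric(0)
  p <- NA_real_
  for (s in seq_along(plan$n_perm)) {
    if (s > 1 && p > plan$thresholds[s]) break
    need <- plan$n_perm[s] - length(stats)
    if (need > 0) {
      new_stats <- stat_fn(need)
      if (length(new_stats) != need || anyNA(new_stats)) {
        stop_structural("permutation statistic function failed (NA or wrong length)")
      }
      stats <- c(stats, new_stats)
    }
    p <- empirical_pvalue(stats, observed)
  }
  list(p = p, P = length(stats), observed = observed, perm_stats = stats)
}

#' Parametric residual bootstrap for a binary outcome with covariates
#'
#' Regresses `y` on the covariates by logistic maximum likelihood, forms
#' residuals `R = y - expit(X gamma_hat)`, and computes the observed
#' statistic from them. Each replicate draws `y*` from Bernoulli with the
#' fitted success probabilities, refits the null model, forms
#' `R* = y* - expit(X gamma_hat*)` and recomputes the statistic; the
#' p-value is the empirical proportion (with +1 correction) of replicate
#' statistics at or above the observed one.
#'
#' @param design a [subject_design()] with binary outcome; the covariate
#'   matrix `design$X` is the null model.
#' @param stat_fn function taking a residual vector and returning the test
#'   statistic (typically a closure around a fixed distance matrix).
#' @param B number of bootstrap replicates.
#' @return List with `p`, `observed`, `boot_stats`, `residuals`.
#' @export
logistic_residual_bootstrap <- function(design, stat_fn, B = 1000) {
  if (design$outcome_type != "binary") {
    stop_structural("logistic residual bootstrap requires a binary outcome")
  }
  X <- design$X
  y <- design$y
  n <- length(y)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
    stop_degenerate("separation in the null logistic fit; use the cell-level permutation path")
  }
  R <- y - mu
  observed <- stat_fn(R)
  boot <- vapply(seq_len(B), function(b) {
    repeat {
      ystar <- rbinom(n, 1, mu)
      if (length(unique(ystar)) > 1) break  # redraw degenerate draws
    }
    refit <- suppressWarnings(glm.fit(X, ystar, family = binomial()))
    stat_fn(ystar - refit$fitted.values)
  }, numeric(1))
  list(p = empirical_pvalue(boot, observed), observed = observed,
       boot_stats = boot, residuals = R)
}

#' Freedman-Lane residual permutation for a continuous outcome
#'
#' Fits the linear null model `y ~ X`, permutes its residuals, rebuilds
#' pseudo-responses `y* = X gamma_hat + R*`, refits, re-residualizes and
#' recomputes the statistic. With an intercept-only null this reduces to
#' permuting the centered outcome.
#'
#' @param design a [subject_design()] with continuous outcome.
#' @param stat_fn function taking a residual vector and returning the test
#'   statistic.
#' @param B number of permutations.
#' @return List with `p`, `observed`, `perm_stats`, `residuals`.
#' @export
freedman_lane <- function(design, stat_fn, B = 1000) {
  X <- design$X
  y <- design$y
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) stop_structural("rank-deficient covariate matrix")
  fitted <- drop(X %*% fit$coefficients)
  R <- y - fitted
  observed <- stat_fn(R)
  perm <- vapply(seq_len(B), function(b) {
    ystar <- fitted + sample(R)
    refit <- lm.fit(X, ystar)
    stat_fn(ystar - drop(X %*% refit$coefficients))
  }, numeric(1))
  list(p = empirical_pvalue(perm, observed), observed = observed,
       perm_stats = perm, residuals = R)
}
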