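#' Silverman rule-of-thumb bandwidth
#'
#' `h = 0.9 * min(sd, IQR/1.34) * n^(-1/5)`, with quartiles computed by the
#' usual linear-interpolation (type-7) rule. For constant input, where both
#' spread estimates vanish, a small fallback bandwidth `eps_h` is returned
#' with a warning so that a degenerate subject still yields a proper
#' (near-point-mass) density row.
#'
#' @param z numeric vector of at least two values (one subject's scaled
#'   cell-level expression).
#' @param eps_h fallback bandwidth for degenerate input (default `1e-3` on
#'   the unit interval).
#' @return Positive bandwidth.
#' @export
silverman_bandwidth <- function(z, eps_h = 1e-3) {
  n <- length(z)
  if (n < 2) stop_structural("bandwidth selection needs at least 2 values")
  spread <- min(sd(z), IQR(z) / 1.34)
  h <- 0.9 * spread * n^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    warning("constant values: falling back to eps_h bandwidth")
    h <- eps_h
  }
  h
}

#' Evaluate a Gaussian KDE on a grid and renormalize to unit mass
#'
#' The kernel density estimate `(1/n) * sum_j w_h(x_r - z_j)` is evaluated
#' at every grid point and then rescaled so the returned row sums to exactly
#' 1, making rows directly comparable as discrete probability vectors. No
#' boundary correction is applied for mass leaking outside `[0, 1]`; the
#' renormalization absorbs it.
#'
#' @param z numeric vector of observations in `[0, 1]`.
#' @param grid ordered grid points (see [density_grid()]).
#' @param h positive bandwidth.
#' @return Non-negative vector of length `length(grid)` summing to 1.
#' @export
kde_profile <- function(z, grid, h) {
  if (!length(z)) stop_structural("empty observation vector")
  if (!is.numeric(h) || h <= 0) stop_structural("bandwidth must be positive")
  f <- colSums(dnorm(outer(z, grid, "-"), sd = h))
  f / sum(f)
}

#' Evenly spaced density grid on the unit interval
#'
#' @param R number of grid points (default 1024), endpoints included.
#' @return Numeric vector of length `R`.
#' @export
density_grid <- function(R = 1024) {
  stopifnot(R >= 2)
  seq(0, 1, length.out = R)
}

#' Per-subject density profiles on a common grid
#'
#' Builds one KDE row per subject from that subject's own cells, each with
#' its own Silverman bandwidth, all evaluated on one shared `R`-point grid
#' in `[0, 1]`.
#'
#' @param values_by_subject named list of numeric vectors (scaled cell
#'   values per subject, all in `[0, 1]`).
#' @param R grid size (default 1024).
#' @param eps_h fallback bandwidth for degenerate subjects.
#' @return An object of class `density_profile`: list with `grid`
#'   (length `R`), `density` (subjects x `R` matrix, rows sum to 1),
#'   `bandwidths`, `R`.
#' @export
density_profile <- function(values_by_subject, R = 1024, eps_h = 1e-3) {
  stopifnot(is.list(values_by_subject), length(values_by_subject) >= 1)
  grid <- density_grid(R)
  bw <- vapply(values_by_subject, silverman_bandwidth,
               numeric(1), eps_h = eps_h)
  dens <- t(vapply(seq_along(values_by_subject), function(i) {
    kde_profile(values_by_subject[[i]], grid, bw[i])
  }, numeric(R)))
  rownames(dens) <- names(values_by_subject)
  structure(list(grid = grid, density = dens, bandwidths = bw, R = R),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %d subjects on %d grid points\n",
              nrow(x$density), x$R))
  invisible(x)
}

#' Jensen-Shannon divergence between two discrete density rows
#'
#' `sum_r p_r log(2 p_r / (p_r + q_r)) + sum_r q_r log(2 q_r / (p_r + q_r))`
#' with natural logarithms and the convention `0 * log(0/.) = 0`. The result
#' lies in `[0, 2 log 2]`; the upper bound is attained for distributions
#' with disjoint support.
#'
#' @param f1,f2 non-negative vectors on the same grid, each summing to 1.
#' @return Divergence value in `[0, 2 log 2]`.
#' @export
jsd <- function(f1, f2) {
  if (length(f1) != length(f2)) stop_structural("density rows are on different grids")
  s <- f1 + f2
  i1 <- f1 > 0
  i2 <- f2 > 0
  d <- sum(f1[i1] * log(2 * f1[i1] / s[i1])) +
       sum(f2[i2] * log(2 * f2[i2] / s[i2]))
  max(d, 0)  # clamp tiny negative rounding for near-identical rows
}

#' Pairwise sqrt-JSD distance matrix between subjects
#'
#' `D[i, j] = sqrt(jsd(f_i, f_j))`. The square root of the Jensen-Shannon
#' divergence is a true metric (identity, symmetry, triangle inequality)
#' and is conditionally negative definite, which is what later licenses
#' Gaussian-kernel and Gower-centered constructions on `D`.
#'
#' @param profile a [density_profile()].
#' @return Symmetric `n x n` matrix with zero diagonal and entries bounded
#'   by `sqrt(2 log 2)`; dimnames carry the subject IDs.
#' @export
jsd_distance_matrix <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  dens <- profile$density
  n <- nrow(dens)
  D <- matrix(0, n, n, dimnames = list(rownames(dens), rownames(dens)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- sqrt(jsd(dens[i, ], dens[j, ]))
    }
  }
  D
}
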