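#' Gower double-centering of a distance matrix
#'
#' `G = H A H` with `A = -D^2 / 2` (elementwise square) and centering
#' matrix `H = I - E/n`. For Euclidean distances this recovers the centered
#' Gram matrix of the underlying configuration (classical MDS); for a
#' conditionally negative definite distance such as sqrt-JSD the result is
#' positive semi-definite up to numerical noise. Row and column sums of the
#' result are zero.
#'
#' @param D symmetric distance matrix.
#' @return Centered Gram matrix with attribute `centered = TRUE`.
#' @export
gower_center <- function(D) {
  D <- as.matrix(D)
  A <- -0.5 * D^2
  rm <- rowMeans(A)
  mm <- mean(A)
  G <- A - outer(rm, rep(1, ncol(A))) - outer(rep(1, nrow(A)), rm) + mm
  attr(G, "centered") <- TRUE
  G
}

#' Hat (projection) matrix of the outcome-augmented design
#'
#' Builds `X* = [y, X]` (or just `X` when `augment_with_y = FALSE`) and
#' returns the projection `H = X* (X*'X*)^{-1} X*'`. With covariates
#' present the permutation machinery replaces `y` by null-model residuals
#' before calling this; see [run_de()].
#'
#' @param design a [subject_design()].
#' @param augment_with_y prepend the outcome to the covariates
#'   (default `TRUE`).
#' @param y_override optional vector used in place of `design$y` (e.g.
#'   null-model residuals for the covariate-adjusted permutation paths).
#' @return Symmetric idempotent projection matrix.
#' @export
hat_matrix <- function(design, augment_with_y = TRUE, y_override = NULL) {
  yv <- if (is.null(y_override)) design$y else y_override
  Xs <- if (augment_with_y) cbind(y = yv, design$X) else design$X
  qx <- qr(Xs)
  if (qx$rank < ncol(Xs)) {
    bad <- colnames(Xs)[qx$pivot[(qx$rank + 1):ncol(Xs)]]
    stop_structural(sprintf("rank-deficient design; collinear column(s): %s",
                            paste(bad, collapse = ", ")))
  }
  Q1 <- qr.Q(qx)
  tcrossprod(Q1)
}

#' Pseudo-F statistic for distance-matrix regression
#'
#' `F = tr(H G H) / tr((I - H) G (I - H))`: the share of the (centered)
#' Gram matrix explained by the design projection relative to the residual
#' share. Scale-invariant in `D` and invariant under simultaneous subject
#' relabeling.
#'
#' @param G centered Gram matrix from [gower_center()].
#' @param H projection matrix from [hat_matrix()].
#' @param tol relative tolerance below which the denominator is treated as
#'   zero (saturated design).
#' @return Scalar statistic.
#' @export
pseudo_F <- function(G, H, tol = 1e-10) {
  G <- as.matrix(G)
  # H idempotent => tr(HGH) = tr(GH); both matrices symmetric
  num <- sum(G * H)
  den <- sum(diag(G)) - num
  scale <- max(abs(diag(G)), 1e-300)
  if (den <= tol * scale) {
    stop_degenerate("saturated design: residual trace is zero")
  }
  num / den
}

#' Positive semi-definite matrix square root
#'
#' Eigendecomposes a symmetric matrix, clips eigenvalues below
#' `clip * lambda_max` (numerical negatives from centering a conditionally
#' negative definite distance) to zero, and reconstructs
#' `B = V diag(sqrt(lambda)) V'`. A substantially negative spectrum
#' signals a distance that is not conditionally negative definite and
#' raises an error.
#'
#' @param G symmetric matrix.
#' @param clip relative eigenvalue clipping threshold (default `1e-10`).
#' @param neg_tol relative threshold beyond which negative eigenvalues are
#'   an error rather than noise (default `1e-6`).
#' @return Symmetric PSD matrix `B` with `B %*% B` equal to the clipped `G`.
#' @export
psd_sqrt <- function(G, clip = 1e-10, neg_tol = 1e-6) {
  G <- as.matrix(G)
  e <- eigen(G, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (min(e$values) < -neg_tol * max(lmax, 1e-300)) {
    stop_structural("substantially negative spectrum: distance is not conditionally negative definite")
  }
  lam <- ifelse(e$values < clip * lmax, 0, e$values)
  B <- e$vectors %*% (sqrt(lam) * t(e$vectors))
  (B + t(B)) / 2
}

#' Square-root pseudo-F statistic
#'
#' The pseudo-F computed on the PSD square root of the centered Gram
#' matrix: `F_sqrt = tr(H G^(1/2) H) / tr((I - H) G^(1/2) (I - H))`.
#' Replacing eigenvalues `lambda` by `sqrt(lambda)` flattens the spectrum,
#' down-weighting a dominant eigen-direction and up-weighting moderate
#' ones, which raises power when the signal is spread over several
#' directions (correlated features). The square root is taken of the
#' centered Gram matrix itself, before any projection.
#'
#' @inheritParams pseudo_F
#' @return Scalar statistic.
#' @export
sqrt_pseudo_F <- function(G, H, tol = 1e-10) {
  pseudo_F(psd_sqrt(G), H, tol = tol)
}
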