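#' Median-heuristic bandwidth for a distance-based Gaussian kernel
#'
#' The median of the `n(n-1)/2` off-diagonal pairwise distances (not
#' squared distances; set `squared = TRUE` for the squared variant).
#'
#' @param D symmetric distance matrix.
#' @param squared take the median of squared distances instead.
#' @return Positive bandwidth `rho`.
#' @export
median_heuristic <- function(D, squared = FALSE) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop_structural("need at least 2 subjects")
  d <- D[upper.tri(D)]
  if (squared) d <- d^2
  rho <- median(d)
  if (rho <= 0) stop_degenerate("all pairwise distances are zero: no scale for the kernel")
  rho
}

#' Distance-based Gaussian kernel matrix
#'
#' `K[i, j] = exp(-D[i, j]^2 / rho)`. For a metric whose square is
#' conditionally negative definite (Euclidean distances of pseudo-bulk
#' values, or sqrt-JSD between subject densities) the result is positive
#' semi-definite with unit diagonal.
#'
#' @param D symmetric distance matrix.
#' @param rho positive bandwidth, typically from [median_heuristic()].
#' @return Symmetric kernel matrix with unit diagonal.
#' @export
gaussian_kernel <- function(D, rho) {
  if (!is.numeric(rho) || length(rho) != 1 || rho <= 0) {
    stop_structural("`rho` must be a positive scalar")
  }
  exp(-as.matrix(D)^2 / rho)
}

#' Kernel score statistic for a binary outcome
#'
#' Fits the null logistic model of `y` on the covariates `X` (intercept
#' only in the simplest case), forms residuals `r = y - mu_hat`, and
#' returns `Q = r' K r / sigma2_hat` together with the eigenvalue weights
#' of its weighted-chi-square null distribution. `sigma2_hat` is the mean
#' of the null binomial variances `mu_hat * (1 - mu_hat)`. The weights are
#' the eigenvalues of `P0 K / sigma2_hat`, where
#' `P0 = V - V X (X' V X)^{-1} X' V` is the null covariance of the
#' residuals; the p-value itself comes from [weighted_chisq_pvalue()].
#'
#' @param design a [subject_design()] with binary outcome.
#' @param K kernel (Gram) matrix aligned with `design$subjects`.
#' @return List of class `score_test` with `Q`, `weights`, `sigma2`,
#'   `residuals`, `mu`.
#' @export
score_statistic <- function(design, K) {
  if (design$outcome_type != "binary") {
    stop_structural("the kernel score test requires a binary outcome")
  }
  K <- as.matrix(K)
  y <- design$y
  X <- design$X
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) {
    stop_degenerate(paste0(
      "separation in the null logistic fit; ",
      "use the permutation-based psrF path instead"))
  }
  r <- y - mu
  v <- mu * (1 - mu)
  sigma2 <- mean(v)
  Q <- drop(crossprod(r, K %*% r)) / sigma2
  VX <- X * v
  P0 <- diag(v) - VX %*% solve(crossprod(X, VX), t(VX))
  w <- Re(eigen(P0 %*% K, only.values = TRUE)$values) / sigma2
  w[abs(w) < 1e-12 * max(abs(w), 1)] <- 0
  structure(list(Q = Q, weights = w, sigma2 = sigma2,
                 residuals = r, mu = mu),
            class = "score_test")
}

#' Tail probability of a weighted sum of chi-square(1) variables
#'
#' Computes `P(sum_k w_k chi2_1k > Q)`, the null tail of the kernel score
#' statistic. The default route numerically inverts the characteristic
#' function (Imhof's integral, the same tail probability the Davies
#' algorithm targets) via adaptive quadrature; `method = "liu"` uses the
#' Liu-Tang-Zhang moment-matched chi-square approximation as a fallback.
#'
#' @param Q observed statistic.
#' @param weights non-negative eigenvalue weights (small negatives from
#'   finite-precision eigendecompositions are clipped; substantial
#'   negatives indicate a non-PSD kernel and raise an error).
#' @param method `"integration"` (default) or `"liu"`.
#' @return p-value in `[0, 1]`.
#' @export
weighted_chisq_pvalue <- function(Q, weights, method = c("integration", "liu")) {
  method <- match.arg(method)
  w <- weights
  wmax <- max(abs(w), 0)
  if (wmax == 0) stop_structural("all weights are zero")
  if (any(w < -1e-6 * wmax)) {
    stop_structural("substantially negative weights: kernel is not positive semi-definite")
  }
  w <- w[w > 1e-12 * wmax]
  if (Q <= 0) return(1)
  if (method == "liu") return(liu_pvalue(Q, w))
  # Imhof inversion: P(T > q) = 1/2 + (1/pi) * int_0^Inf sin(theta(u)) / (u rho(u)) du
  theta <- function(u) 0.5 * colSums(atan(outer(w, u))) - Q * u / 2
  rho <- function(u) exp(0.25 * colSums(log1p(outer(w^2, u^2))))
  integrand <- function(u) sin(theta(u)) / (u * rho(u))
  # envelope 1/(u * rho(u)) is monotone decreasing; choose a finite upper
  # limit where it drops below 1e-13, then integrate adaptively
  upper <- 1
  while (1 / (upper * prod((1 + w^2 * upper^2)^0.25)) > 1e-13 && upper < 1e8) {
    upper <- upper * 2
  }
  val <- tryCatch(
    integrate(integrand, lower = 0, upper = upper,
              subdivisions = 5000L, rel.tol = 1e-10, abs.tol = 1e-12)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(liu_pvalue(Q, w))
  min(max(0.5 + val / pi, 0), 1)
}

# Liu-Tang-Zhang moment matching: approximate the null by a scaled
# noncentral chi-square with matched cumulants.
liu_pvalue <- function(Q, w) {
  c1 <- sum(w); c2 <- sum(w^2); c3 <- sum(w^3); c4 <- sum(w^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- c2^3 / c3^2
  }
  tstar <- (Q - c1) / sqrt(2 * c2)
  q <- tstar * sqrt(2) * sqrt(l + 2 * delta) + l + delta
  pchisq(q, df = l, ncp = delta, lower.tail = FALSE)
}

#' Kernel score test (pseudo-bulk or single-cell distance source)
#'
#' Convenience wrapper: builds the score statistic from a design and a
#' kernel matrix and attaches the weighted-chi-square p-value. The same
#' code path serves both the pseudo-bulk variant (kernel from Euclidean
#' distances between per-subject aggregates) and the single-cell variant
#' (kernel from sqrt-JSD distances between subject densities); only the
#' distance source differs.
#'
#' @param design a [subject_design()] with binary outcome.
#' @param K kernel matrix.
#' @param method p-value method, see [weighted_chisq_pvalue()].
#' @return `score_test` object with elements `Q`, `weights`, `sigma2`, `p`.
#' @export
kernel_score_test <- function(design, K, method = c("integration", "liu")) {
  res <- score_statistic(design, K)
  res$p <- weighted_chisq_pvalue(res$Q, res$weights, method = method)
  res
}

#' @export
print.score_test <- function(x, ...) {
  cat(sprintf("<score_test> Q = %.4g", x$Q))
  if (!is.null(x$p)) cat(sprintf(", p = %.4g", x$p))
  cat("\n")
  invisible(x)
}
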