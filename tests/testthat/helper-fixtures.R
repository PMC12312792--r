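# Small fixture builders shared across test files.

# random discrete density rows on a common grid (normalized positives)
random_density <- function(R = 64) {
  f <- runif(R)^2 + 1e-6
  f / sum(f)
}

# a density row from a smooth Gaussian-mixture KDE, for metric tests
smooth_density <- function(R = 256) {
  z <- c(rnorm(40, runif(1, 0.2, 0.5), 0.05),
         rnorm(40, runif(1, 0.5, 0.8), 0.08))
  z <- pmin(pmax(z, 0), 1)
  kde_profile(z, density_grid(R), silverman_bandwidth(z))
}

# tiny cell matrix: n_subj subjects x n_cells cells each, one cluster
tiny_cell_matrix <- function(n_subj = 4, n_cells = 25, n_genes = 3,
                             cluster = "c1") {
  n <- n_subj * n_cells
  vals <- matrix(rlnorm(n * n_genes, 1, 0.5), n, n_genes)
  cell_matrix(vals, rep(paste0("s", seq_len(n_subj)), each = n_cells),
              rep(cluster, n), paste0("g", seq_len(n_genes)))
}

# Euclidean distance matrix from a numeric vector or point matrix
euclid_dist <- function(x) {
  as.matrix(stats::dist(x))
}
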