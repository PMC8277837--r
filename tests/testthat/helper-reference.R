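# Independent reference implementations used as oracles.

# Literal PCIT definition: pair (x, y) is eliminated if there exists a
# third gene z whose trio tolerance eps satisfies
# |r_xy| < |eps r_xz| and |r_xy| < |eps r_yz|.
pcit_reference <- function(r) {
  n <- nrow(r)
  cap <- 1 - 1e-12
  clip <- function(v) min(max(v, -cap), cap)
  keep <- matrix(TRUE, n, n)
  for (x in seq_len(n - 1L)) {
    for (y in (x + 1L):n) {
      rxy <- r[x, y]
      for (z in setdiff(seq_len(n), c(x, y))) {
        rxz <- r[x, z]; ryz <- r[y, z]
        cxy <- clip(rxy); cxz <- clip(rxz); cyz <- clip(ryz)
        pxy <- (cxy - cxz * cyz) / sqrt((1 - cxz * cxz) * (1 - cyz * cyz))
        pxz <- (cxz - cxy * cyz) / sqrt((1 - cxy * cxy) * (1 - cyz * cyz))
        pyz <- (cyz - cxy * cxz) / sqrt((1 - cxy * cxy) * (1 - cxz * cxz))
        t1 <- if (cxy != 0) pxy / cxy else 0
        t2 <- if (cxz != 0) pxz / cxz else 0
        t3 <- if (cyz != 0) pyz / cyz else 0
        eps <- (t1 + t2 + t3) / 3
        if (abs(rxy) < abs(eps) * abs(rxz) &&
            abs(rxy) < abs(eps) * abs(ryz)) {
          keep[x, y] <- FALSE
          keep[y, x] <- FALSE
          break
        }
      }
    }
  }
  keep
}

# correlation matrix of a random expression draw with some structure
random_corr <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  f <- matrix(rnorm(3 * n_samples), 3)
  load <- matrix(rnorm(n_genes * 3, sd = 0.7), n_genes)
  x <- load %*% f + matrix(rnorm(n_genes * n_samples), n_genes)
  cor(t(x))
}

# row-wise Pearson correlation of paired matrices
rowwise_cor <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  rowSums(a * b) / sqrt(rowSums(a^2) * rowSums(b^2))
}

# small simulated experiment reused across tests
small_sim <- function(seed = 5, ...) {
  simulate_counts(sim_config(n_genes = 120, n_tfs = 10, n_per_group = 10,
                             n_modules = 3, module_size = 8,
                             rewired_fraction = 1 / 3, de_fraction = 0.1,
                             seed = seed, ...))
}
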