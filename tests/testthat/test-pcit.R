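test_that("correlation_matrix handles toy vectors and flat genes", {
  x <- rbind(a = c(1, 2, 3), b = c(3, 2, 1), a2 = c(2, 4, 6))
  r <- correlation_matrix(x)
  expect_equal(r["a", "b"], -1)
  expect_equal(r["a", "a2"], 1)
  y <- rbind(p = c(1, 2, 3, 4), q = c(1, 2, 4, 3))
  expect_equal(correlation_matrix(y)["p", "q"], 0.8)
  expect_error(correlation_matrix(y[, 1:2]), "3 samples")
  z <- rbind(u = c(1, 2, 3, 4), flat = c(5, 5, 5, 5))
  expect_warning(rz <- correlation_matrix(z), "zero-variance")
  expect_equal(rz["u", "flat"], 0)
  expect_equal(diag(rz), c(u = 1, flat = 1))
})

test_that("partial correlation matches the closed form", {
  expect_equal(partial_correlation(0.9, 0.9, 0.81),
               (0.9 - 0.9 * 0.81) / sqrt((1 - 0.81) * (1 - 0.81^2)),
               tolerance = 1e-12)
  expect_equal(round(partial_correlation(0.9, 0.9, 0.81), 3), 0.669)
  # degenerate |r| = 1 leg stays finite
  expect_true(is.finite(partial_correlation(0.5, 1, 1)))
})

test_that("PCIT equals the literal trio-elimination oracle on seeded matrices", {
  for (seed in 1:10) {
    r <- random_corr(30, 20, seed)
    expect_identical(unname(pcit_edges(r)), pcit_reference(r),
                     label = sprintf("seed %d", seed))
  }
})

test_that("PCIT handles the diagonal-only matrix like the oracle", {
  r <- diag(5)
  expect_identical(unname(pcit_edges(r)), pcit_reference(r))
})

test_that("PCIT is equivariant under gene reordering", {
  r <- random_corr(20, 15, seed = 77)
  rownames(r) <- colnames(r) <- paste0("g", 1:20)
  set.seed(1)
  perm <- sample(20)
  a <- pcit_edges(r)
  b <- pcit_edges(r[perm, perm])
  expect_identical(unname(b), unname(a[perm, perm]))
})

test_that("build_network applies the r, p and anchor filters", {
  genes <- c("A", "B", "C", "D")
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- 0.99   # anchored, strong
  r[3, 4] <- r[4, 3] <- 0.99   # strong but unanchored
  r[1, 3] <- r[3, 1] <- 0.80   # anchored but below r_min
  dimnames(r) <- list(genes, genes)
  attr(r, "n_samples") <- 5
  mask <- matrix(TRUE, 4, 4, dimnames = dimnames(r))
  edges <- build_network(r, mask, anchor_genes = c("A"))
  expect_identical(edges$gene_a, "A")
  expect_identical(edges$gene_b, "B")
  # p-value is the correlation t-test tail
  tt <- 0.99 * sqrt((5 - 2) / (1 - 0.99^2))
  expect_equal(edges$p, 2 * pt(-tt, 3), tolerance = 1e-10)
  expect_lt(edges$p, 0.05)
  # PCIT mask is honoured
  mask[1, 2] <- mask[2, 1] <- FALSE
  expect_identical(nrow(build_network(r, mask, "A")), 0L)
  expect_error(build_network(r, mask, character(0)), "anchors")
  expect_error(build_network(r, mask, "A", r_min = 1.5), "r_min")
})

test_that("edge retention is monotone in r_min", {
  r <- random_corr(25, 8, seed = 5)
  rownames(r) <- colnames(r) <- paste0("g", 1:25)
  attr(r, "n_samples") <- 8
  mask <- pcit_edges(r)
  anchors <- paste0("g", 1:5)
  lax <- build_network(r, mask, anchors, r_min = 0.5)
  strict <- build_network(r, mask, anchors, r_min = 0.8)
  key <- function(e) paste(e$gene_a, e$gene_b)
  expect_true(all(key(strict) %in% key(lax)))
})

test_that("hub rule: strict exceedance of mean + 2 sample SD", {
  mk <- function(degs) {
    # star-like edge lists realizing the given degree sequence
    do.call(rbind, lapply(seq_along(degs), function(i)
      if (degs[i] == 0) NULL else
        data.frame(gene_a = sprintf("n%02d", i),
                   gene_b = sprintf("x%02d_%03d", i, seq_len(degs[i])))))
  }
  h1 <- hub_genes(mk(c(5, 5, 5)))  # all leaves degree 1, centers equal
  # centers all 5, leaves all 1: nobody exceeds mean + 2SD by symmetry?
  thr1 <- attr(h1, "threshold")
  expect_true(all(h1$is_hub == (h1$degree > thr1)))

  # the documented arithmetic cases (degrees of the named nodes)
  d1 <- c(1, 1, 1, 1, 10)
  expect_equal(mean(d1) + 2 * sd(d1), 10.85, tolerance = 1e-3)
  expect_false(any(d1 > mean(d1) + 2 * sd(d1)))
  d2 <- c(1, 1, 1, 1, 20)
  expect_gt(mean(d2) + 2 * sd(d2), 20)   # still no hub
  d3 <- c(rep(1, 9), 30)
  expect_lt(mean(d3) + 2 * sd(d3), 30)   # genuine hub
  # equal degrees: SD 0, strict inequality, no hubs
  ring <- data.frame(gene_a = paste0("r", 1:4),
                     gene_b = paste0("r", c(2:4, 1)))
  expect_false(any(hub_genes(ring)$is_hub))
  # star K_{1,50}: the center is the unique hub
  star <- data.frame(gene_a = "hub", gene_b = sprintf("leaf%02d", 1:50))
  hs <- hub_genes(star)
  expect_identical(hs$gene_id[hs$is_hub], "hub")
  expect_error(hub_genes(star[0, ]), "empty")
})

test_that("scale-free fit is exact on a power law and poor on random graphs", {
  # degrees on a log-spaced grid with frequencies proportional to k^-2:
  # exactly linear in log-log coordinates
  k <- 2^(0:5)
  freq <- (32 / k)^2
  degs <- rep(k, freq)
  expect_equal(scale_free_fit(degs, n_bins = 6), 1, tolerance = 1e-9)
  # Erdos-Renyi degrees are binomial, far from a power law
  set.seed(10)
  n <- 500; p <- 0.05
  adj <- matrix(runif(n * n) < p, n, n)
  adj[lower.tri(adj, diag = TRUE)] <- FALSE
  degs_er <- tabulate(c(row(adj)[adj], col(adj)[adj]), nbins = n)
  r2 <- scale_free_fit(degs_er)
  expect_lt(r2, 0.9)
  # degenerate input flags NaN
  expect_warning(out <- scale_free_fit(rep(3, 10)), "undefined")
  expect_true(is.nan(out))
})
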