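sim_for_rif <- function(seed = 2) {
  sim <- simulate_counts(sim_config(n_genes = 120, n_tfs = 20,
                                    n_per_group = 20, n_modules = 1,
                                    module_size = 11, rho_within = 0.9,
                                    rewired_fraction = 1,
                                    de_fraction = 10 / 120, lfc_magnitude = 2,
                                    de_placement = "rewired_targets",
                                    de_sign = "up", baseline_log2_mean = 6,
                                    baseline_log2_sd = 1.5, seed = seed))
  list(sim = sim, expr = normalize_log_cpm(sim$counts))
}

test_that("z-standardization and the significance rule hold", {
  s <- sim_for_rif()
  rt <- rif_scores(s$expr, s$sim$samples$condition, s$sim$tf_ids,
                   s$sim$truth$de_genes$gene_id)
  expect_equal(mean(rt$rif1_z), 0, tolerance = 1e-12)
  expect_equal(sd(rt$rif1_z), 1, tolerance = 1e-12)
  expect_equal(mean(rt$rif2_z), 0, tolerance = 1e-12)
  expect_equal(sd(rt$rif2_z), 1, tolerance = 1e-12)
  expect_identical(rt$significant,
                   abs(rt$rif1_z) >= 2 | abs(rt$rif2_z) >= 2)
})

test_that("raw scores match a direct per-TF loop over the definition", {
  s <- sim_for_rif()
  cond <- s$sim$samples$condition
  deg <- s$sim$truth$de_genes$gene_id
  tfs <- s$sim$tf_ids
  rt <- rif_scores(s$expr, cond, tfs, deg)
  E1 <- s$expr[, cond == "case"]
  E2 <- s$expr[, cond == "control"]
  for (tf in tfs[c(1, 5, 20)]) {
    r1v <- rep(0, length(deg)); r2v <- rep(0, length(deg))
    acc1 <- 0; acc2 <- 0
    for (j in seq_along(deg)) {
      if (deg[j] == tf) next  # self-pair excluded
      e1 <- mean(E1[deg[j], ]); e2 <- mean(E2[deg[j], ])
      r1 <- cor(E1[tf, ], E1[deg[j], ])
      r2 <- cor(E2[tf, ], E2[deg[j], ])
      acc1 <- acc1 + ((e1 + e2) / 2) * (e1 - e2) * (r1 - r2)^2
      acc2 <- acc2 + (e1 * r1)^2 - (e2 * r2)^2
    }
    expect_equal(rt$rif1_raw[rt$tf_id == tf], acc1 / length(deg))
    expect_equal(rt$rif2_raw[rt$tf_id == tf], acc2 / length(deg))
  }
})

test_that("the planted rewired regulator attains the largest |RIF1|", {
  s <- sim_for_rif(seed = 4)
  rt <- rif_scores(s$expr, s$sim$samples$condition, s$sim$tf_ids,
                   s$sim$truth$de_genes$gene_id)
  planted <- unname(s$sim$truth$regulator_of["1"])
  expect_identical(rt$tf_id[which.max(abs(rt$rif1_raw))], planted)
})

test_that("swapping condition labels negates both raw scores exactly", {
  s <- sim_for_rif(seed = 9)
  cond <- s$sim$samples$condition
  swapped <- ifelse(cond == "case", "control", "case")
  deg <- s$sim$truth$de_genes$gene_id
  a <- rif_scores(s$expr, cond, s$sim$tf_ids, deg)
  b <- rif_scores(s$expr, swapped, s$sim$tf_ids, deg)
  expect_equal(b$rif1_raw, -a$rif1_raw, tolerance = 0)
  expect_equal(b$rif2_raw, -a$rif2_raw, tolerance = 0)
})

test_that("scores are invariant to sample order within a condition", {
  s <- sim_for_rif(seed = 12)
  cond <- s$sim$samples$condition
  deg <- s$sim$truth$de_genes$gene_id
  a <- rif_scores(s$expr, cond, s$sim$tf_ids, deg)
  set.seed(1)
  ord <- c(sample(which(cond == "control")), sample(which(cond == "case")))
  b <- rif_scores(s$expr[, ord], cond[ord], s$sim$tf_ids, deg)
  expect_equal(a$rif1_raw, b$rif1_raw)
  expect_equal(a$rif2_raw, b$rif2_raw)
})

test_that("degenerate inputs are rejected or dropped as documented", {
  s <- sim_for_rif()
  cond <- s$sim$samples$condition
  deg <- s$sim$truth$de_genes$gene_id
  expect_error(rif_scores(s$expr, cond, s$sim$tf_ids, character(0)), "DE")
  expect_error(rif_scores(s$expr, cond, s$sim$tf_ids[1], deg), "2 scorable")
  flat <- s$expr
  flat[s$sim$tf_ids[1], ] <- 3
  expect_warning(rt <- rif_scores(flat, cond, s$sim$tf_ids, deg),
                 "zero within-condition variance")
  expect_false(s$sim$tf_ids[1] %in% rt$tf_id)
})

test_that("a TF with equal correlations and abundances on both sides scores zero", {
  # construct case/control expression where every DE gene has identical
  # mean and identical correlation to the TF in the two conditions
  set.seed(7)
  n <- 10
  base <- matrix(rnorm(6 * n, mean = 5), nrow = 6,
                 dimnames = list(c("TF1", "TF2", paste0("D", 1:4)), NULL))
  expr <- cbind(base, base)  # case block identical to control block
  colnames(expr) <- paste0("s", 1:(2 * n))
  cond <- rep(c("case", "control"), each = n)
  rt <- rif_scores(expr, cond, c("TF1", "TF2"), paste0("D", 1:4))
  expect_equal(rt$rif1_raw, c(0, 0))
  expect_equal(rt$rif2_raw, c(0, 0))
})
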