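test_that("cpm matches direct ratios and the edgeR implementation", {
  m <- matrix(c(1, 0, 3), ncol = 1)
  expect_equal(as.vector(cpm_matrix(m)), c(250000, 0, 750000))
  m2 <- matrix(c(5, 0, 5, 10, 0, 10), nrow = 3)
  expect_equal(cpm_matrix(m2),
               matrix(c(5e5, 0, 5e5, 5e5, 0, 5e5), nrow = 3))
  u <- matrix(7, nrow = 10, ncol = 2)
  expect_true(all(cpm_matrix(u) == 1e5))
  # columns of nonzero libraries sum to 1e6
  set.seed(1)
  x <- matrix(rpois(200, 30), 20)
  expect_equal(colSums(cpm_matrix(x)), rep(1e6, 10), ignore_attr = TRUE)
  skip_if_not_installed("edgeR")
  expect_equal(cpm_matrix(x), edgeR::cpm(x, normalized.lib.sizes = FALSE),
               ignore_attr = TRUE)
})

test_that("cpm rejects all-zero libraries by name", {
  m <- matrix(c(1, 2, 0, 0), nrow = 2,
              dimnames = list(NULL, c("good", "empty")))
  expect_error(cpm_matrix(m), "empty")
})

test_that("CPM filter keeps a gene expressed in exactly half the samples", {
  # 10 samples with equal libraries of 1e6: counts are CPM directly
  n <- 10
  counts <- rbind(
    boundary = c(rep(1, 5), rep(0, 5)),   # CPM >= 0.5 in exactly 5/10
    allzero  = rep(0, n),
    high     = rep(50, n)
  )
  counts <- counts + 0
  colnames(counts) <- paste0("s", 1:n)
  # pad the library so CPM of a count of 1 is 1e6/lib ~ 1 (>= 0.5)
  counts <- rbind(counts, filler = rep(1e6, n))
  kept <- suppressMessages(filter_low_expression(counts))
  expect_true("boundary" %in% rownames(kept))
  expect_false("allzero" %in% rownames(kept))
  expect_true(all(c("high", "filler") %in% rownames(kept)))
})

test_that("CPM filter agrees with brute-force rule enumeration and is idempotent", {
  set.seed(42)
  counts <- matrix(rnbinom(60, mu = 2, size = 1), nrow = 6,
                   dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  counts[1, ] <- counts[1, ] + 200
  cp <- cpm_matrix(counts)
  # oracle: per-gene counting of the rule
  expected <- vapply(seq_len(6), function(g)
    sum(cp[g, ] >= 0.5) >= 0.5 * 10, logical(1))
  kept <- suppressMessages(filter_low_expression(counts))
  expect_identical(rownames(kept), rownames(counts)[expected])
  again <- suppressMessages(filter_low_expression(kept))
  expect_identical(again, kept)
})

test_that("log2-CPM normalization has the documented anchors", {
  counts <- matrix(c(99, 1), ncol = 1, dimnames = list(c("a", "b"), "s1"))
  e <- normalize_log_cpm(counts)
  expect_equal(as.vector(e), c(log2(990000.5), log2(10000.5)))
  z <- matrix(c(0, 10), ncol = 1)
  expect_equal(normalize_log_cpm(z)[1, 1], log2(0.5))
  # doubling all counts in a sample leaves values unchanged
  expect_equal(normalize_log_cpm(counts * 2), e)
})

test_that("BH adjustment reproduces the step-up and its guards", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, NaN)), "NA")
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  # permutation invariance
  set.seed(3)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # padj >= pvalue component-wise
  expect_true(all(bh_adjust(p) >= p))
})

test_that("linear-model DE recovers planted genes and guards degenerate input", {
  cfg <- sim_config(n_genes = 400, n_tfs = 5, n_per_group = 20,
                    n_modules = 0, de_fraction = 0.05, lfc_magnitude = 3,
                    baseline_log2_mean = 6, baseline_log2_sd = 2, seed = 17)
  sim <- simulate_counts(cfg)
  expr <- normalize_log_cpm(sim$counts)
  de <- differential_expression(expr, sim$samples)
  planted <- sim$truth$de_genes
  called <- de$status[match(planted$gene_id, de$gene_id)]
  expect_gte(mean(called != "ns"), 0.9)
  # signs match the planted direction for the called genes
  hit <- called != "ns"
  expect_true(all((called[hit] == "up") == (planted$sign[hit] > 0)))

  # identical values in both groups: log2FC 0, p 1
  flat <- expr
  flat["G00001", ] <- 5
  de2 <- differential_expression(flat, sim$samples, covariates = character(0))
  row <- de2[de2$gene_id == "G00001", ]
  expect_equal(row$log2FC, 0)
  expect_equal(row$pvalue, 1)
})

test_that("DE agrees with stats::lm gene by gene", {
  sim <- small_sim()
  expr <- normalize_log_cpm(sim$counts)[1:8, ]
  de <- differential_expression(expr, sim$samples)
  dat0 <- data.frame(condition = factor(sim$samples$condition,
                                        c("control", "case")),
                     age = sim$samples$age - mean(sim$samples$age),
                     sex = factor(sim$samples$sex))
  for (g in rownames(expr)) {
    fit <- summary(lm(expr[g, ] ~ condition + age + sex, data = dat0))
    expect_equal(de$log2FC[de$gene_id == g],
                 unname(coef(fit)["conditioncase", "Estimate"]))
    expect_equal(de$pvalue[de$gene_id == g],
                 unname(coef(fit)["conditioncase", "Pr(>|t|)"]))
  }
})

test_that("collinear designs are rejected with the offending term named", {
  sim <- small_sim()
  expr <- normalize_log_cpm(sim$counts)[1:5, ]
  ss <- sim$samples
  ss$age <- ifelse(ss$condition == "case", 50, 30)  # aliased with condition
  expect_error(differential_expression(expr, ss, covariates = "age"),
               "collinear.*age")
})

test_that("under the global null the DE call rate stays near alpha", {
  rates <- vapply(1:3, function(s) {
    sim <- simulate_counts(sim_config(n_genes = 500, n_tfs = 5,
                                      n_per_group = 10, n_modules = 0,
                                      de_fraction = 0, seed = 30 + s))
    de <- differential_expression(normalize_log_cpm(sim$counts), sim$samples,
                                  covariates = character(0))
    mean(de$status != "ns")
  }, numeric(1))
  expect_lte(mean(rates), 0.1)
})
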