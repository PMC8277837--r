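#' Configuration for the two-condition count simulator
#'
#' Assembles and validates the parameters of the synthetic RNA-seq
#' experiment produced by [simulate_counts()]. The defaults emulate a
#' small two-group bulk RNA-seq study of case vs control tissue
#' (5 samples per group), with TF-centred co-expression modules a subset
#' of which is rewired (their TF--target correlation destroyed) in the
#' case condition, and a planted fraction of differentially expressed
#' genes.
#'
#' @param n_genes total number of genes in the simulated universe.
#' @param n_tfs number of genes flagged as transcription factors (the
#'   first `n_tfs` gene IDs). Must be at least `n_modules`.
#' @param n_per_group samples per condition.
#' @param n_modules number of TF-regulated co-expression modules.
#' @param module_size genes per module, counting the regulator TF
#'   itself (so each module has `module_size - 1` target genes).
#' @param rho_within latent within-module correlation in (0, 1): targets
#'   load on the module factor with weight `sqrt(rho_within)`, so the
#'   latent TF--target correlation is `sqrt(rho_within)` and the latent
#'   target--target correlation is `rho_within`.
#' @param rewired_fraction fraction of modules whose target loadings are
#'   destroyed (or sign-flipped, see `rewiring_mode`) in the case
#'   condition.
#' @param de_fraction fraction of genes given a planted expression shift.
#' @param lfc_magnitude absolute log2 fold change of planted DE genes.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param lib_size_mean expected library size (sum of gene means) per
#'   sample before the per-sample size factor.
#' @param lib_size_sigma log-normal sigma of the per-sample library-size
#'   factors.
#' @param baseline_log2_mean,baseline_log2_sd log2-normal parameters of
#'   the per-gene baseline means; the left tail supplies genuinely
#'   low-expressed genes for the CPM filter to remove.
#' @param rewiring_mode `"loss"` sets the target loading to zero in the
#'   rewired case modules; `"sign_flip"` negates it.
#' @param de_placement `"random"` plants DE genes anywhere in the
#'   universe; `"rewired_targets"` plants them first on the targets of
#'   rewired modules (the scenario in which a differential regulator is
#'   recoverable by RIF).
#' @param de_sign `"both"` draws the DE sign per gene; `"up"`/`"down"`
#'   force a common direction.
#' @param seed integer seed; the whole simulation is deterministic given
#'   the config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L, n_tfs = 50L, n_per_group = 5L,
                       n_modules = 10L, module_size = 10L,
                       rho_within = 0.9, rewired_fraction = 0.3,
                       de_fraction = 0.05, lfc_magnitude = 2,
                       nb_dispersion = 0.1, lib_size_mean = 3e5,
                       lib_size_sigma = 0.2,
                       baseline_log2_mean = 3, baseline_log2_sd = 4,
                       rewiring_mode = c("loss", "sign_flip"),
                       de_placement = c("random", "rewired_targets"),
                       de_sign = c("both", "up", "down"),
                       seed = 1L) {
  rewiring_mode <- match.arg(rewiring_mode)
  de_placement <- match.arg(de_placement)
  de_sign <- match.arg(de_sign)
  int_pos <- function(x, nm, min = 1L) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
        x != as.integer(x)) {
      stop(sprintf("'%s' must be a single integer >= %d", nm, min),
           call. = FALSE)
    }
    as.integer(x)
  }
  prop <- function(x, nm) {
    if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
      stop(sprintf("'%s' must be a proportion in [0, 1]", nm), call. = FALSE)
    as.numeric(x)
  }
  cfg <- list(
    n_genes = int_pos(n_genes, "n_genes"),
    n_tfs = int_pos(n_tfs, "n_tfs"),
    n_per_group = int_pos(n_per_group, "n_per_group"),
    n_modules = int_pos(n_modules, "n_modules", min = 0L),
    module_size = int_pos(module_size, "module_size"),
    rho_within = rho_within,
    rewired_fraction = prop(rewired_fraction, "rewired_fraction"),
    de_fraction = prop(de_fraction, "de_fraction"),
    lfc_magnitude = as.numeric(lfc_magnitude),
    nb_dispersion = as.numeric(nb_dispersion),
    lib_size_mean = as.numeric(lib_size_mean),
    lib_size_sigma = as.numeric(lib_size_sigma),
    baseline_log2_mean = as.numeric(baseline_log2_mean),
    baseline_log2_sd = as.numeric(baseline_log2_sd),
    rewiring_mode = rewiring_mode,
    de_placement = de_placement,
    de_sign = de_sign,
    seed = int_pos(seed, "seed", min = 0L)
  )
  if (!is.numeric(rho_within) || rho_within <= 0 || rho_within >= 1)
    stop("'rho_within' must lie in (0, 1)", call. = FALSE)
  if (cfg$nb_dispersion <= 0) stop("'nb_dispersion' must be positive", call. = FALSE)
  if (cfg$lib_size_mean <= 0) stop("'lib_size_mean' must be positive", call. = FALSE)
  if (cfg$n_modules * cfg$module_size > cfg$n_genes)
    stop("n_modules * module_size must not exceed n_genes", call. = FALSE)
  if (cfg$n_tfs < cfg$n_modules)
    stop("need at least one TF per module (n_tfs >= n_modules)", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a two-condition RNA-seq count matrix with planted truth
#'
#' Draws negative-binomial counts for `2 * n_per_group` samples via a
#' latent Gaussian copula: each sample receives one latent factor per
#' module; a module's targets get latent value
#' `sqrt(rho_within) * factor + sqrt(1 - rho_within) * noise` and the
#' module's TF gets the factor itself; in the case condition the targets
#' of rewired modules lose (or sign-flip) the factor loading. The latent
#' value is mapped through its normal CDF onto the gene's
#' negative-binomial marginal (`qnbinom`), whose mean is the per-gene
#' baseline times `2^lfc` for planted DE genes in the case condition,
#' times a log-normal per-sample library-size factor. Quantile matching
#' preserves the planted rank correlations under the count likelihood.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `asm_simulation` with elements
#'   \describe{
#'     \item{counts}{integer gene x sample matrix,}
#'     \item{samples}{sample sheet (`sample_id`, `condition`, `age`,
#'       `sex`; the covariates carry no planted effect),}
#'     \item{tf_ids}{character vector of TF gene IDs,}
#'     \item{truth}{planted-truth tables: `de_genes` (gene, sign, lfc),
#'       `module_map` (gene, module, role), `rewired_modules`,
#'       `regulator_of` (module -> TF),}
#'     \item{latent}{the latent Gaussian matrix (diagnostics only),}
#'     \item{config}{the config echo.}
#'   }
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 200, n_tfs = 10,
#'                                   n_modules = 4, module_size = 10,
#'                                   seed = 42))
#' dim(sim$counts)
#' @export
simulate_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ng <- config$n_genes
  npg <- config$n_per_group
  ns <- 2L * npg
  gene_ids <- sprintf("G%05d", seq_len(ng))
  tf_ids <- gene_ids[seq_len(config$n_tfs)]

  # per-gene baselines, rescaled so the expected library is lib_size_mean
  base <- 2^rnorm(ng, config$baseline_log2_mean, config$baseline_log2_sd)
  base <- base * (config$lib_size_mean / sum(base))

  # module assignment: module m is regulated by TF m; targets drawn from
  # the non-TF pool
  nmod <- config$n_modules
  module_map <- data.frame(gene_id = character(0), module = integer(0),
                           role = character(0), stringsAsFactors = FALSE)
  regulator_of <- character(0)
  target_pool <- setdiff(gene_ids, tf_ids)
  if (nmod > 0L) {
    n_targets <- config$module_size - 1L
    if (nmod * n_targets > length(target_pool))
      stop("not enough non-TF genes to populate the module targets", call. = FALSE)
    picked <- sample(target_pool, nmod * n_targets)
    regulator_of <- setNames(tf_ids[seq_len(nmod)], as.character(seq_len(nmod)))
    module_map <- data.frame(
      gene_id = c(tf_ids[seq_len(nmod)], picked),
      module = c(seq_len(nmod), rep(seq_len(nmod), each = n_targets)),
      role = c(rep("tf", nmod), rep("target", nmod * n_targets)),
      stringsAsFactors = FALSE
    )
  }
  n_rewired <- if (nmod > 0L) as.integer(round(config$rewired_fraction * nmod)) else 0L
  rewired_modules <- if (n_rewired > 0L) sort(sample(seq_len(nmod), n_rewired)) else integer(0)

  # planted DE genes
  n_de <- as.integer(round(config$de_fraction * ng))
  rewired_targets <- module_map$gene_id[module_map$module %in% rewired_modules &
                                          module_map$role == "target"]
  de_ids <- character(0)
  if (n_de > 0L) {
    if (config$de_placement == "rewired_targets" && length(rewired_targets) > 0L) {
      take <- min(n_de, length(rewired_targets))
      de_ids <- sample(rewired_targets, take)
      if (n_de > take)
        de_ids <- c(de_ids, sample(setdiff(gene_ids, de_ids), n_de - take))
    } else {
      de_ids <- sample(gene_ids, n_de)
    }
  }
  de_sign <- switch(config$de_sign,
                    both = sample(c(-1, 1), n_de, replace = TRUE),
                    up = rep(1, n_de),
                    down = rep(-1, n_de))
  truth_de <- data.frame(gene_id = de_ids, sign = de_sign,
                         lfc = de_sign * config$lfc_magnitude,
                         stringsAsFactors = FALSE)

  # sample sheet: controls first, then cases; covariates have no effect
  condition <- rep(c("control", "case"), each = npg)
  samples <- data.frame(
    sample_id = sprintf("S%02d_%s", seq_len(ns), condition),
    condition = condition,
    age = round(runif(ns, 25, 65)),
    sex = sample(c("F", "M"), ns, replace = TRUE),
    stringsAsFactors = FALSE
  )
  size_factor <- exp(rnorm(ns, 0, config$lib_size_sigma))

  # latent Gaussian layer
  loading <- sqrt(config$rho_within)
  noise_w <- sqrt(1 - config$rho_within)
  factors <- matrix(rnorm(max(nmod, 1L) * ns), nrow = max(nmod, 1L), ncol = ns)
  latent <- matrix(rnorm(ng * ns), nrow = ng, ncol = ns,
                   dimnames = list(gene_ids, samples$sample_id))
  is_case <- condition == "case"
  if (nmod > 0L) {
    for (m in seq_len(nmod)) {
      tf_row <- match(regulator_of[[as.character(m)]], gene_ids)
      tgt_rows <- match(module_map$gene_id[module_map$module == m &
                                             module_map$role == "target"],
                        gene_ids)
      latent[tf_row, ] <- factors[m, ]
      w <- rep(loading, ns)
      if (m %in% rewired_modules) {
        w[is_case] <- if (config$rewiring_mode == "loss") 0 else -loading
      }
      for (s in seq_len(ns)) {
        latent[tgt_rows, s] <- w[s] * factors[m, s] +
          sqrt(1 - w[s]^2) * latent[tgt_rows, s]
      }
    }
  }

  # NB marginals via quantile matching
  mu <- matrix(base, nrow = ng, ncol = ns)
  if (n_de > 0L) {
    rows <- match(de_ids, gene_ids)
    mu[rows, is_case] <- mu[rows, is_case] * 2^truth_de$lfc
  }
  mu <- sweep(mu, 2L, size_factor, `*`)
  size <- 1 / config$nb_dispersion
  counts <- matrix(qnbinom(pnorm(latent), size = size, mu = mu),
                   nrow = ng, ncol = ns,
                   dimnames = dimnames(latent))
  storage.mode(counts) <- "integer"

  structure(list(counts = counts, samples = samples, tf_ids = tf_ids,
                 truth = list(de_genes = truth_de, module_map = module_map,
                              rewired_modules = rewired_modules,
                              regulator_of = regulator_of),
                 latent = latent, config = config),
            class = "asm_simulation")
}

#' Write a simulated experiment to disk
#'
#' Emits the plain-text inputs the pipeline stages consume: a counts TSV
#' (gene_id + one column per sample), a sample sheet TSV, a TF list, and
#' the planted-truth tables.
#'
#' @param sim an `asm_simulation` from [simulate_counts()].
#' @param outdir output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "asm_simulation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(outdir, "counts.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    tfs = file.path(outdir, "tfs.txt"),
    truth_de = file.path(outdir, "truth_de_genes.tsv"),
    truth_modules = file.path(outdir, "truth_module_map.tsv"),
    truth_rewired = file.path(outdir, "truth_rewired_modules.tsv")
  )
  write_matrix_tsv(sim$counts, paths[["counts"]], id_col = "gene_id")
  write_tsv(sim$samples, paths[["samples"]])
  writeLines(sim$tf_ids, paths[["tfs"]])
  write_tsv(sim$truth$de_genes, paths[["truth_de"]])
  write_tsv(sim$truth$module_map, paths[["truth_modules"]])
  write_tsv(data.frame(module = sim$truth$rewired_modules,
                       regulator = unname(sim$truth$regulator_of[
                         as.character(sim$truth$rewired_modules)])),
            paths[["truth_rewired"]])
  invisible(paths)
}
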