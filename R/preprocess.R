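#' Counts per million
#'
#' Scales each library (column) to one million: `cpm[g, s] =
#' counts[g, s] / sum_g counts[g, s] * 1e6`.
#'
#' @param counts non-negative gene x sample matrix.
#' @return matrix of CPM values, same dimnames.
#' @export
cpm_matrix <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  zero <- which(lib == 0)
  if (length(zero)) {
    nm <- colnames(counts)[zero]
    if (is.null(nm)) nm <- as.character(zero)
    stop("all-zero library for sample(s): ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  sweep(counts, 2L, lib, `/`) * 1e6
}

#' Filter low-expression genes by CPM
#'
#' Keeps gene g iff its CPM is at least `cpm_threshold` in at least
#' `sample_fraction` of the samples (i.e. removes genes with
#' CPM < threshold in more than half the samples at the defaults),
#' the conventional reading of edgeR-style low-count filtering.
#'
#' @param counts gene x sample count matrix.
#' @param cpm_threshold CPM cutoff (default 0.5).
#' @param sample_fraction minimum fraction of samples that must meet the
#'   cutoff (default 0.5).
#' @return the row-subset count matrix; numbers of genes before/after
#'   are reported via `message()`.
#' @export
filter_low_expression <- function(counts, cpm_threshold = 0.5,
                                  sample_fraction = 0.5) {
  if (cpm_threshold <= 0 || sample_fraction <= 0)
    stop("thresholds must be positive", call. = FALSE)
  counts <- as.matrix(counts)
  cp <- cpm_matrix(counts)
  need <- sample_fraction * ncol(counts)
  keep <- rowSums(cp >= cpm_threshold) >= need
  out <- counts[keep, , drop = FALSE]
  message(sprintf("CPM filter: kept %d of %d genes (CPM >= %g in >= %g%% of samples)",
                  nrow(out), nrow(counts), cpm_threshold, 100 * sample_fraction))
  if (nrow(out) == 0L) warning("CPM filter removed every gene", call. = FALSE)
  out
}

#' Log2-CPM normalization
#'
#' `log2(CPM + prior_count)`; monotone in counts within a sample and
#' invariant to library-size rescaling.
#'
#' @param counts gene x sample count matrix (normally CPM-filtered).
#' @param prior_count pseudocount added on the CPM scale (default 0.5,
#'   so a zero count maps to -1).
#' @return gene x sample matrix of log2-CPM values.
#' @export
normalize_log_cpm <- function(counts, prior_count = 0.5) {
  log2(cpm_matrix(counts) + prior_count)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`padj_(i) = min_(j>=i) m p_(j) / j`, clipped
#' at 1, mapped back to input order); delegated to
#' [stats::p.adjust()] with input validation.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)))
    stop("NA/NaN p-values are not allowed", call. = FALSE)
  if (any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Per-gene linear-model differential expression
#'
#' Fits, for every gene, an ordinary least-squares model of log2-CPM
#' expression on condition (case vs control) plus optional covariates
#' (age, centred; sex, as an indicator). The condition coefficient is
#' reported as the log2 fold change, with a two-sided t-test p-value and
#' BH adjustment across all tested genes. Genes are called `up` / `down`
#' when `padj <= alpha_de` with positive / negative log2FC, else `ns`.
#'
#' @param expr gene x sample matrix of log2-scale expression
#'   (see [normalize_log_cpm()]).
#' @param samples sample sheet with `sample_id`, `condition`, and
#'   optionally `age` and/or `sex`; rows are matched to `colnames(expr)`.
#' @param alpha_de BH-adjusted significance cutoff (default 0.1).
#' @param covariates character vector of covariate columns to adjust
#'   for; defaults to those present among `age`, `sex`.
#' @return data.frame with `gene_id`, `log2FC`, `pvalue`, `padj`,
#'   `status`.
#' @export
differential_expression <- function(expr, samples, alpha_de = 0.1,
                                    covariates = intersect(c("age", "sex"),
                                                           names(samples))) {
  expr <- as.matrix(expr)
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$sample_id)))
    stop("expression columns missing from the sample sheet", call. = FALSE)
  cond <- factor(samples$condition, levels = c("control", "case"))
  if (any(table(cond) < 2L))
    stop("need at least 2 samples per condition", call. = FALSE)

  dat <- data.frame(condition = cond)
  for (cv in covariates) {
    v <- samples[[cv]]
    dat[[cv]] <- if (is.numeric(v)) v - mean(v) else factor(v)
  }
  X <- model.matrix(~ ., data = dat)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("collinear design; offending term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X); df <- n - p
  if (df < 1L) stop("no residual degrees of freedom", call. = FALSE)

  Y <- t(expr)
  beta <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  sigma2 <- colSums(res^2) / df
  cjj <- chol2inv(qr.R(qx))[2L, 2L]  # condition coefficient ("conditioncase")
  lfc <- beta["conditioncase", ]
  se <- sqrt(sigma2 * cjj)
  tstat <- lfc / se
  pval <- 2 * pt(-abs(tstat), df)
  # (near-)zero residual variance: no evidence when the coefficient is
  # also numerically zero, overwhelming evidence otherwise
  degenerate <- !is.finite(tstat) | sigma2 < 1e-20
  pval[degenerate] <- ifelse(abs(lfc[degenerate]) < 1e-8, 1, 0)
  padj <- bh_adjust(pval)
  status <- rep("ns", length(pval))
  status[padj <= alpha_de & lfc > 0] <- "up"
  status[padj <= alpha_de & lfc < 0] <- "down"
  data.frame(gene_id = rownames(expr), log2FC = unname(lfc),
             pvalue = unname(pval), padj = unname(padj), status = status,
             stringsAsFactors = FALSE)
}
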