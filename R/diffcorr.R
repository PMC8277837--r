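#' Fisher z-test for a difference between two correlations
#'
#' Variance-stabilizes both correlations with the Fisher transform
#' `z = atanh(r)` and tests their difference with the standard-normal
#' statistic
#' `z_diff = (z_case - z_control) / sqrt(1/(n_case - 3) + 1/(n_control - 3))`,
#' two-sided.
#'
#' @param r_case,r_control Pearson correlations (vectorized).
#' @param n_case,n_control per-condition sample sizes (>= 4).
#' @return list with numeric vectors `z_diff` and `pval_diff`.
#' @export
fisher_z_difference <- function(r_case, n_case, r_control, n_control) {
  if (n_case < 4L || n_control < 4L)
    stop("Fisher z-test needs at least 4 samples per condition", call. = FALSE)
  cap <- 1 - 1e-12
  if (any(abs(c(r_case, r_control)) >= 1))
    warning("|r| = 1 clipped to 1 - 1e-12 before atanh", call. = FALSE)
  zc <- atanh(pmin(pmax(r_case, -cap), cap))
  zk <- atanh(pmin(pmax(r_control, -cap), cap))
  se <- sqrt(1 / (n_case - 3) + 1 / (n_control - 3))
  z <- (zc - zk) / se
  list(z_diff = z, pval_diff = 2 * pnorm(-abs(z)))
}

#' Nine-class correlation taxonomy
#'
#' Labels a gene pair's correlation status per condition as positive
#' (`+`: r > 0 and correlation p <= `class_alpha`), negative (`-`:
#' r < 0 and p <= `class_alpha`) or not significant (`0`), and returns
#' the combined `case/control` label — one of the nine classes
#' `+/+`, `+/-`, `+/0`, `-/+`, `-/0`, `-/-`, `0/+`, `0/0`, `0/-`.
#'
#' @param r_case,p_case,r_control,p_control correlations and their
#'   per-condition correlation-test p-values (vectorized).
#' @param class_alpha per-condition significance cutoff (default 0.05).
#' @return character vector of class labels.
#' @export
classify_pair <- function(r_case, p_case, r_control, p_control,
                          class_alpha = 0.05) {
  sgn <- function(r, p) ifelse(p <= class_alpha & r > 0, "+",
                               ifelse(p <= class_alpha & r < 0, "-", "0"))
  paste(sgn(r_case, p_case), sgn(r_control, p_control), sep = "/")
}

#' Differential co-expression scan over gene pairs
#'
#' For every pair in the chosen universe, computes the per-condition
#' Pearson correlations and correlation-test p-values, the Fisher
#' z-difference statistic and p-value ([fisher_z_difference()]), a BH
#' adjustment across all tested pairs, and the nine-class label
#' ([classify_pair()]). Correlations are evaluated in row blocks so the
#' full all-pairs scan stays memory-bounded.
#'
#' @param expr gene x sample matrix of normalized expression.
#' @param condition `"case"`/`"control"` label per column of `expr`.
#' @param universe `"anchored"` (default; pairs with at least one
#'   endpoint in `anchors`) or `"all"`.
#' @param anchors anchor gene IDs (required for the anchored universe).
#' @param alpha_adj cutoff on the BH-adjusted difference p-value for
#'   the `significant` flag (default 0.05).
#' @param class_alpha per-condition alpha for class labels (default 0.05).
#' @param block_size rows per correlation block (default 512).
#' @return data.frame `gene_a`, `gene_b`, `r_case`, `r_control`,
#'   `z_diff`, `pval_diff`, `pval_diff_adj`, `class`, `significant`.
#' @export
diffcorr_scan <- function(expr, condition, universe = c("anchored", "all"),
                          anchors = NULL, alpha_adj = 0.05,
                          class_alpha = 0.05, block_size = 512L) {
  universe <- match.arg(universe)
  expr <- as.matrix(expr)
  condition <- as.character(condition)
  case <- condition == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 4L || n2 < 4L)
    stop("need at least 4 samples per condition", call. = FALSE)
  if (n1 < 10L || n2 < 10L)
    warning("fewer than 10 samples per condition: the Fisher z-test has ",
            "little power at this sample size", call. = FALSE)

  # constant genes cannot be correlated: drop with a logged count
  v1 <- apply(expr[, case, drop = FALSE], 1L, var)
  v2 <- apply(expr[, !case, drop = FALSE], 1L, var)
  flat <- v1 == 0 | v2 == 0
  if (any(flat)) {
    message(sprintf("diffcorr: skipping %d constant gene(s)", sum(flat)))
    expr <- expr[!flat, , drop = FALSE]
  }
  genes <- rownames(expr)
  if (length(genes) < 2L) stop("fewer than 2 variable genes", call. = FALSE)

  if (universe == "anchored") {
    if (is.null(anchors) || !length(intersect(anchors, genes)))
      stop("anchored universe requires anchors present in 'expr'", call. = FALSE)
    rows <- which(genes %in% anchors)
  } else {
    rows <- seq_along(genes)
  }

  X1 <- t(expr[, case, drop = FALSE])
  X2 <- t(expr[, !case, drop = FALSE])
  anchor_set <- if (universe == "anchored") rows else integer(0)
  res <- vector("list", ceiling(length(rows) / block_size))
  bi <- 0L
  for (start in seq(1L, length(rows), by = block_size)) {
    blk <- rows[start:min(start + block_size - 1L, length(rows))]
    r1 <- cor(X1[, blk, drop = FALSE], X1)  # |blk| x n_genes
    r2 <- cor(X2[, blk, drop = FALSE], X2)
    ia <- rep(blk, times = length(genes))
    ib <- rep(seq_along(genes), each = length(blk))
    # enumerate each unordered pair exactly once: the ia < ib copy of an
    # anchor-anchor pair comes from the smaller anchor's block; a pair
    # with a non-anchor partner is emitted from the anchor's block
    # whichever side the partner's index falls on
    keep <- if (universe == "all") ia < ib
            else ia < ib | (ib < ia & !(ib %in% anchor_set))
    sel <- which(keep)
    bi <- bi + 1L
    res[[bi]] <- data.frame(
      ia = ia[sel], ib = ib[sel],
      r_case = as.vector(r1)[sel], r_control = as.vector(r2)[sel]
    )
  }
  d <- do.call(rbind, res[seq_len(bi)])
  rm(res)
  # canonical order within the pair (correlations are symmetric)
  ii <- pmin(d$ia, d$ib); jj <- pmax(d$ia, d$ib)
  d$ia <- ii; d$ib <- jj
  d <- d[order(d$ia, d$ib), , drop = FALSE]

  fz <- fisher_z_difference(d$r_case, n1, d$r_control, n2)
  p1 <- correlation_pvalue(d$r_case, n1)
  p2 <- correlation_pvalue(d$r_control, n2)
  padj <- bh_adjust(fz$pval_diff)
  out <- data.frame(
    gene_a = genes[d$ia], gene_b = genes[d$ib],
    r_case = d$r_case, r_control = d$r_control,
    z_diff = fz$z_diff, pval_diff = fz$pval_diff, pval_diff_adj = padj,
    class = classify_pair(d$r_case, p1, d$r_control, p2, class_alpha),
    significant = padj <= alpha_adj,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
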