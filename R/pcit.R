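#' Within-condition Pearson correlation matrix
#'
#' Pairwise Pearson correlations over the given samples. Zero-variance
#' genes get r = 0 off-diagonal with a warning (they carry no
#' co-expression signal and are inert in PCIT trios).
#'
#' @param expr gene x sample matrix of normalized expression.
#' @param samples optional column names/indices selecting one
#'   condition's samples; defaults to all columns.
#' @return correlation matrix with attribute `n_samples`.
#' @export
correlation_matrix <- function(expr, samples = NULL) {
  expr <- as.matrix(expr)
  if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
  if (ncol(expr) < 3L) stop("need at least 3 samples", call. = FALSE)
  r <- suppressWarnings(cor(t(expr)))
  if (anyNA(r)) {
    flat <- rownames(expr)[apply(expr, 1L, var) == 0]
    warning("zero-variance gene(s) set to r = 0: ",
            paste(head(flat, 5L), collapse = ", "),
            if (length(flat) > 5L) ", ...", call. = FALSE)
    r[is.na(r)] <- 0
    diag(r) <- 1
  }
  attr(r, "n_samples") <- ncol(expr)
  r
}

#' Partial correlation of x and y given z
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, the
#' correlation of x and y after removing the linear effect of z. Inputs
#' are clipped to |r| <= 1 - 1e-12 so the formula stays defined on
#' degenerate (|r| = 1) legs.
#'
#' @param r_xy,r_xz,r_yz Pearson correlations (vectorized).
#' @return partial correlation(s).
#' @export
partial_correlation <- function(r_xy, r_xz, r_yz) {
  cap <- 1 - 1e-12
  cxy <- pmin(pmax(r_xy, -cap), cap)
  cxz <- pmin(pmax(r_xz, -cap), cap)
  cyz <- pmin(pmax(r_yz, -cap), cap)
  (cxy - cxz * cyz) / sqrt((1 - cxz * cxz) * (1 - cyz * cyz))
}

#' PCIT significance mask
#'
#' Runs the partial correlation and information theory (PCIT)
#' trio-elimination test on a correlation matrix. For every gene trio
#' (x, y, z) the three first-order partial correlations are computed and
#' the information-theoretic tolerance
#' `eps = (r_xy.z / r_xy + r_xz.y / r_xz + r_yz.x / r_yz) / 3`
#' is formed (a ratio with a zero denominator contributes 0). The pair
#' (x, y) is eliminated if some third gene z satisfies both
#' `|r_xy| < |eps * r_xz|` and `|r_xy| < |eps * r_yz|`; pairs never
#' eliminated are significant. The compiled implementation is exactly
#' equivalent to the brute-force O(n^3) definition.
#'
#' @param corr square symmetric correlation matrix (>= 3 genes).
#' @return logical matrix, TRUE where the pair is PCIT-significant;
#'   `n_samples` attribute propagated from `corr` when present.
#' @export
pcit_edges <- function(corr) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n < 3L) stop("PCIT needs at least 3 genes", call. = FALSE)
  if (ncol(corr) != n || max(abs(corr - t(corr))) > 1e-8)
    stop("'corr' must be a square symmetric matrix", call. = FALSE)
  keep <- .pcit_significance_cpp(corr)
  dimnames(keep) <- dimnames(corr)
  attr(keep, "n_samples") <- attr(corr, "n_samples")
  keep
}

#' Build a filtered co-expression edge list
#'
#' Retains the unordered pair (x, y) iff it is PCIT-significant, its
#' |r| reaches `r_min`, its correlation t-test
#' (`t = r sqrt((n - 2) / (1 - r^2))`, df = n - 2) gives p < `alpha_r`,
#' and at least one endpoint belongs to the anchor set (typically
#' DE genes plus significant TFs).
#'
#' @param corr correlation matrix with `n_samples` attribute (see
#'   [correlation_matrix()]).
#' @param pcit_mask logical significance matrix from [pcit_edges()].
#' @param anchor_genes character vector of anchor gene IDs (nonempty).
#' @param r_min minimum |r| (default 0.95), in (0, 1].
#' @param alpha_r per-edge correlation-test alpha (default 0.05).
#' @param n_samples sample size for the t-test; defaults to the
#'   attribute carried by `corr`.
#' @return data.frame `gene_a`, `gene_b`, `r`, `p` (gene_a < gene_b).
#' @export
build_network <- function(corr, pcit_mask, anchor_genes, r_min = 0.95,
                          alpha_r = 0.05,
                          n_samples = attr(corr, "n_samples")) {
  if (!length(anchor_genes)) stop("empty anchors", call. = FALSE)
  if (r_min <= 0 || r_min > 1) stop("'r_min' must lie in (0, 1]", call. = FALSE)
  if (is.null(n_samples)) stop("sample size unknown; pass 'n_samples'", call. = FALSE)
  genes <- rownames(corr)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(corr)))
  idx <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[idx]
  keep <- as.logical(pcit_mask[idx]) & abs(r) >= r_min
  anchored <- (genes[idx[, 1L]] %in% anchor_genes) |
    (genes[idx[, 2L]] %in% anchor_genes)
  keep <- keep & anchored
  idx <- idx[keep, , drop = FALSE]
  r <- r[keep]
  p <- correlation_pvalue(r, n_samples)
  sig <- p < alpha_r
  data.frame(gene_a = genes[idx[sig, 1L]], gene_b = genes[idx[sig, 2L]],
             r = r[sig], p = p[sig], stringsAsFactors = FALSE)
}

# two-sided p-value of the correlation t-test at df = n - 2
correlation_pvalue <- function(r, n) {
  if (n < 3L) stop("correlation test needs n >= 3", call. = FALSE)
  r2 <- pmin(r * r, 1 - 1e-12)
  tstat <- abs(r) * sqrt((n - 2) / (1 - r2))
  2 * pt(-tstat, df = n - 2)
}

# degree per node from an edge list
edge_degrees <- function(edges) {
  if (!nrow(edges)) return(integer(0))
  tab <- table(c(edges$gene_a, edges$gene_b))
  setNames(as.integer(tab), names(tab))
}

#' Hub genes by the mean + 2 SD degree rule
#'
#' A gene is a hub when its degree strictly exceeds the mean degree
#' plus two sample standard deviations, computed over the network's
#' nodes.
#'
#' @param edges edge list data.frame (`gene_a`, `gene_b`).
#' @return data.frame `gene_id`, `degree`, `is_hub`, sorted by
#'   decreasing degree, with attribute `threshold`.
#' @export
hub_genes <- function(edges) {
  k <- edge_degrees(edges)
  if (!length(k)) stop("empty network", call. = FALSE)
  if (length(k) == 1L) {
    warning("single-node network: no hubs", call. = FALSE)
    thr <- Inf
  } else {
    thr <- mean(k) + 2 * sd(k)
  }
  out <- data.frame(gene_id = names(k), degree = unname(k),
                    is_hub = unname(k > thr), stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  out
}

#' Scale-free topology fit
#'
#' Bins the degree distribution into `n_bins` equal-width bins on the
#' log10 scale, computes the probability mass P(k) per nonempty bin,
#' and regresses log10 P(k) on the mean log10 degree per bin; returns
#' the R-squared of the fit. A scale-free network (P(k) ~ k^-gamma) is
#' exactly linear in log-log coordinates.
#'
#' @param x an edge list data.frame or a numeric vector of degrees.
#' @param n_bins number of log-spaced bins (default 10).
#' @return R-squared in \[0, 1\], or `NaN` (with a warning) when fewer
#'   than 3 bins are occupied.
#' @export
scale_free_fit <- function(x, n_bins = 10L) {
  k <- if (is.data.frame(x)) edge_degrees(x) else x
  k <- k[k > 0]
  if (length(unique(k)) < 3L) {
    warning("fewer than 3 distinct degrees: scale-free fit undefined",
            call. = FALSE)
    return(NaN)
  }
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = n_bins + 1L)
  bin <- cut(lk, breaks, include.lowest = TRUE, labels = FALSE)
  counts <- tapply(lk, bin, length)
  mids <- tapply(lk, bin, mean)
  nonempty <- !is.na(counts)
  if (sum(nonempty) < 3L) {
    warning("fewer than 3 occupied degree bins: scale-free fit undefined",
            call. = FALSE)
    return(NaN)
  }
  pk <- log10(counts[nonempty] / length(k))
  unname(cor(pk, mids[nonempty])^2)
}
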