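#' Regulatory impact factor (RIF1 / RIF2) scores
#'
#' Scores every transcription factor against the set of differentially
#' expressed genes by aggregating, over DE genes j with per-condition
#' mean abundances `e1` (case) and `e2` (control), average abundance
#' `a = (e1 + e2) / 2`, differential expression `dE = e1 - e2`, and
#' phenotype impact factor `PIF = a * dE`:
#' \deqn{RIF1_i = \frac{1}{n_{de}} \sum_j PIF_j \, (r_{1ij} - r_{2ij})^2}
#' \deqn{RIF2_i = \frac{1}{n_{de}} \sum_j (e_{1j} r_{1ij})^2 - (e_{2j} r_{2ij})^2}
#' where `r1`, `r2` are the within-condition Pearson correlations
#' between TF i and DE gene j. RIF1 rewards TFs most differentially
#' co-expressed with abundant DE genes; RIF2 rewards TFs whose ability
#' to predict DE-gene abundance changes most. Raw scores are
#' z-standardized across TFs (sample SD), and a TF is significant when
#' either |z| reaches `z_thresh`. Genes that are both TF and DE gene
#' contribute in both roles, but self-pairs (i = j) are excluded from
#' the sums. TFs with zero within-condition variance are dropped with a
#' warning. Condition 1 is `case`, condition 2 is `control`, so
#' swapping the labels negates both raw scores exactly.
#'
#' @param expr gene x sample matrix of normalized expression.
#' @param condition character/factor of `"case"` / `"control"` per
#'   column of `expr`.
#' @param tf_ids gene IDs to score (must be rows of `expr`).
#' @param deg_ids DE gene IDs (must be rows of `expr`).
#' @param z_thresh significance threshold on |z| (default 2).
#' @return data.frame `tf_id`, `rif1_raw`, `rif2_raw`, `rif1_z`,
#'   `rif2_z`, `significant`.
#' @export
rif_scores <- function(expr, condition, tf_ids, deg_ids, z_thresh = 2) {
  expr <- as.matrix(expr)
  condition <- as.character(condition)
  if (length(condition) != ncol(expr))
    stop("'condition' must label every column of 'expr'", call. = FALSE)
  if (!all(condition %in% c("case", "control")))
    stop("condition labels must be 'case' or 'control'", call. = FALSE)
  if (!length(deg_ids)) stop("no DE genes supplied", call. = FALSE)
  missing <- setdiff(c(tf_ids, deg_ids), rownames(expr))
  if (length(missing))
    stop("IDs absent from the expression matrix: ",
         paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  case <- condition == "case"
  if (sum(case) < 4L || sum(!case) < 4L)
    stop("need at least 4 samples per condition for correlations",
         call. = FALSE)

  E1 <- expr[, case, drop = FALSE]
  E2 <- expr[, !case, drop = FALSE]
  # drop TFs with zero variance in either condition
  v1 <- apply(E1[tf_ids, , drop = FALSE], 1L, var)
  v2 <- apply(E2[tf_ids, , drop = FALSE], 1L, var)
  dropped <- tf_ids[v1 == 0 | v2 == 0]
  if (length(dropped)) {
    warning("dropping TF(s) with zero within-condition variance: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    tf_ids <- setdiff(tf_ids, dropped)
  }
  if (length(tf_ids) < 2L)
    stop("need at least 2 scorable TFs for z-standardization", call. = FALSE)

  e1 <- rowMeans(E1[deg_ids, , drop = FALSE])
  e2 <- rowMeans(E2[deg_ids, , drop = FALSE])
  a <- (e1 + e2) / 2
  dE <- e1 - e2
  pif <- a * dE

  r1 <- suppressWarnings(cor(t(E1[tf_ids, , drop = FALSE]),
                             t(E1[deg_ids, , drop = FALSE])))
  r2 <- suppressWarnings(cor(t(E2[tf_ids, , drop = FALSE]),
                             t(E2[deg_ids, , drop = FALSE])))
  # zero-variance DE genes yield NA correlations: treat as no co-expression
  r1[is.na(r1)] <- 0
  r2[is.na(r2)] <- 0

  dw2 <- (r1 - r2)^2
  term2 <- sweep(r1^2, 2L, e1^2, `*`) - sweep(r2^2, 2L, e2^2, `*`)
  pifm <- matrix(pif, nrow = length(tf_ids), ncol = length(deg_ids),
                 byrow = TRUE)
  term1 <- pifm * dw2
  # exclude self-pairs (a gene that is both TF and DE gene)
  self <- outer(tf_ids, deg_ids, `==`)
  term1[self] <- 0
  term2[self] <- 0
  n_de <- length(deg_ids)
  rif1 <- rowSums(term1) / n_de
  rif2 <- rowSums(term2) / n_de

  zstd <- function(x) (x - mean(x)) / sd(x)
  z1 <- zstd(rif1)
  z2 <- zstd(rif2)
  data.frame(tf_id = tf_ids, rif1_raw = unname(rif1), rif2_raw = unname(rif2),
             rif1_z = unname(z1), rif2_z = unname(z2),
             significant = abs(z1) >= z_thresh | abs(z2) >= z_thresh,
             stringsAsFactors = FALSE)
}
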