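#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the query list within
#' a declared universe: the p-value is the upper hypergeometric tail
#' `P(X >= overlap)` with `universe_size` balls, `set_size` successes
#' and `query_size` draws, BH-adjusted across terms. Query genes
#' outside the universe are dropped with a logged count; set members
#' are intersected with the universe first.
#'
#' @param query character vector of gene IDs.
#' @param sets gene-set collection (named list, see [read_gmt()]).
#' @param universe character vector of gene IDs (nonempty).
#' @return data.frame `term_id`, `description`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `pvalue`, `padj`, sorted by p-value.
#' @export
hypergeometric_ora <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(sprintf("ORA: dropping %d query gene(s) outside the universe",
                    length(outside)))
    query <- intersect(query, universe)
  }
  nq <- length(query)
  nu <- length(universe)
  rec <- lapply(names(sets), function(tid) {
    members <- intersect(sets[[tid]], universe)
    ov <- length(intersect(query, members))
    p <- phyper(ov - 1L, length(members), nu - length(members), nq,
                lower.tail = FALSE)
    desc <- attr(sets[[tid]], "description")
    data.frame(term_id = tid,
               description = if (is.null(desc)) NA_character_ else desc,
               overlap = ov, set_size = length(members), query_size = nq,
               universe_size = nu, pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rec)
  out$padj <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohen's kappa between two sets over a frame of items
#'
#' Chance-corrected agreement of the two membership indicator vectors
#' over `items`: `kappa = (po - pe) / (1 - pe)`. When chance agreement
#' is 1 (both indicators constant), kappa is 1 for identical vectors
#' and 0 otherwise.
#'
#' @param set_a,set_b character vectors.
#' @param items the frame over which membership is compared.
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(set_a, set_b, items) {
  a <- items %in% set_a
  b <- items %in% set_b
  n <- length(items)
  if (!n) stop("empty item frame", call. = FALSE)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < 1e-12) return(if (po >= 1 - 1e-12) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Kappa grouping of redundant enriched terms
#'
#' Computes Cohen's kappa between every pair of significant terms over
#' their query-gene membership indicators and merges terms by single
#' linkage over the graph of pairs with `kappa >= kappa_min`. Group IDs
#' are numbered by each cluster's first term in the input record order,
#' so the grouping is deterministic and invariant to shuffling.
#'
#' @param records enrichment table from [hypergeometric_ora()].
#' @param sets the gene-set collection the records refer to.
#' @param query the query gene list.
#' @param kappa_min linkage threshold (default 0.4).
#' @param sig_alpha raw-p cutoff selecting the terms to group
#'   (default 0.05).
#' @return `records` with an integer `group_id` column (NA for
#'   non-significant terms).
#' @export
kappa_grouping <- function(records, sets, query, kappa_min = 0.4,
                           sig_alpha = 0.05) {
  query <- unique(query)
  sig <- which(records$pvalue < sig_alpha)
  records$group_id <- NA_integer_
  if (!length(sig)) {
    warning("no significant terms to group", call. = FALSE)
    return(records)
  }
  ids <- sort(records$term_id[sig])
  m <- length(ids)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        k <- cohen_kappa(sets[[ids[i]]], sets[[ids[j]]], query)
        if (k >= kappa_min) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(m), find, 1L)
  gid <- match(roots, unique(roots))
  records$group_id[match(ids, records$term_id)] <- gid
  records
}

#' Intersection of a gene list with a curated marker list
#'
#' Case-normalized exact set intersection (e.g. against a curated
#' ferroptosis regulator/marker resource), reported with both set
#' sizes.
#'
#' @param genes query gene IDs.
#' @param markers marker gene IDs.
#' @return list with `common` (query-side IDs of the intersection),
#'   `n_genes`, `n_markers`, `n_common`.
#' @export
marker_intersection <- function(genes, markers) {
  genes <- unique(genes)
  markers <- unique(markers)
  hit <- toupper(genes) %in% toupper(markers)
  list(common = sort(genes[hit]), n_genes = length(genes),
       n_markers = length(markers), n_common = sum(hit))
}
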