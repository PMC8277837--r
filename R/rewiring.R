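#' Central reference (union) network
#'
#' Merges the case and control edge lists into one network, flagging
#' every node and edge as `case_only`, `control_only` or `shared`.
#'
#' @param case_edges,control_edges edge list data.frames
#'   (`gene_a`, `gene_b`), as produced by [build_network()].
#' @return list of class `union_network` with data.frames `nodes`
#'   (`gene_id`, `presence`) and `edges` (`gene_a`, `gene_b`,
#'   `presence`), edges canonicalized so `gene_a < gene_b`.
#' @export
union_network <- function(case_edges, control_edges) {
  if (!nrow(case_edges) || !nrow(control_edges))
    stop("both edge lists must be nonempty", call. = FALSE)
  canon <- function(e) {
    a <- pmin(e$gene_a, e$gene_b)
    b <- pmax(e$gene_a, e$gene_b)
    unique(paste(a, b, sep = "\r"))
  }
  ek_case <- canon(case_edges)
  ek_ctrl <- canon(control_edges)
  all_keys <- sort(union(ek_case, ek_ctrl))
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  presence_of <- function(key, in_case, in_ctrl)
    ifelse(in_case & in_ctrl, "shared",
           ifelse(in_case, "case_only", "control_only"))
  edges <- data.frame(
    gene_a = vapply(parts, `[`, "", 1L),
    gene_b = vapply(parts, `[`, "", 2L),
    presence = presence_of(all_keys, all_keys %in% ek_case,
                           all_keys %in% ek_ctrl),
    stringsAsFactors = FALSE
  )
  n_case <- unique(c(case_edges$gene_a, case_edges$gene_b))
  n_ctrl <- unique(c(control_edges$gene_a, control_edges$gene_b))
  all_nodes <- sort(union(n_case, n_ctrl))
  nodes <- data.frame(
    gene_id = all_nodes,
    presence = presence_of(all_nodes, all_nodes %in% n_case,
                           all_nodes %in% n_ctrl),
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges), class = "union_network")
}

#' Differential connectivity (DK) over a union network
#'
#' For every gene of the union network, the per-condition degree k is
#' standardized to `K = k / max(k)` within that condition (genes absent
#' from one condition's network get k = 0 there), the differential
#' connectivity is `DK = K_case - K_control`, and DK is z-scored across
#' all union genes. Genes with `z >= z_thresh` are connectivity gains in
#' the case condition; `z <= -z_thresh` are losses.
#'
#' @param union a `union_network` from [union_network()].
#' @param z_thresh two-sided z threshold (default 1.96, the 97.5th
#'   standard-normal percentile).
#' @param center subtract mean(DK) before scaling (default TRUE); set
#'   FALSE to z-score raw DK around 0.
#' @param sd_type `"sample"` (ddof = 1, default) or `"population"`.
#' @return data.frame `gene_id`, `k_case`, `k_control`, `K_case`,
#'   `K_control`, `DK`, `z`, `call` (gain/loss/ns).
#' @export
differential_connectivity <- function(union, z_thresh = 1.96,
                                      center = TRUE,
                                      sd_type = c("sample", "population")) {
  stopifnot(inherits(union, "union_network"))
  sd_type <- match.arg(sd_type)
  e <- union$edges
  genes <- union$nodes$gene_id
  deg_for <- function(presences) {
    sub <- e[e$presence %in% presences, , drop = FALSE]
    k <- edge_degrees(sub)
    out <- setNames(integer(length(genes)), genes)
    out[names(k)] <- k
    out
  }
  k_case <- deg_for(c("case_only", "shared"))
  k_ctrl <- deg_for(c("control_only", "shared"))
  if (max(k_case) == 0L || max(k_ctrl) == 0L)
    stop("each condition must contribute at least one edge", call. = FALSE)
  K_case <- k_case / max(k_case)
  K_ctrl <- k_ctrl / max(k_ctrl)
  DK <- K_case - K_ctrl
  mu <- if (center) mean(DK) else 0
  s <- if (sd_type == "sample") sd(DK) else sqrt(mean((DK - mean(DK))^2))
  if (is.na(s) || s == 0) {
    warning("SD(DK) is zero: all calls set to 'ns'", call. = FALSE)
    z <- rep(0, length(DK))
  } else {
    z <- (DK - mu) / s
  }
  call <- rep("ns", length(z))
  call[z >= z_thresh] <- "gain"
  call[z <= -z_thresh] <- "loss"
  data.frame(gene_id = genes, k_case = unname(k_case),
             k_control = unname(k_ctrl), K_case = unname(K_case),
             K_control = unname(K_ctrl), DK = unname(DK), z = unname(z),
             call = call, stringsAsFactors = FALSE)
}
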