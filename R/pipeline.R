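#' Pipeline configuration
#'
#' Collects the file paths and thresholds driving [run_pipeline()].
#' Defaults are the workflow's canonical cutoffs: DE at padj <= 0.1,
#' RIF significance at |z| >= 2, network edges at |r| >= 0.95 with
#' correlation p < 0.05, rewiring at |z| >= 1.96, differential
#' correlation at adjusted p <= 0.05, and kappa grouping at 0.4.
#'
#' @param counts,samples paths to the counts TSV and sample sheet TSV.
#' @param tfs path to a one-ID-per-line TF list.
#' @param outdir output directory.
#' @param gmt optional GMT collection for over-representation analysis.
#' @param markers optional marker list (e.g. ferroptosis regulators)
#'   for set intersection.
#' @param de_table optional precomputed DE table TSV (columns
#'   `gene_id`, `log2FC`, `pvalue`, `padj`); replaces the built-in
#'   linear-model DE stage.
#' @param cpm,frac CPM filter threshold and sample fraction.
#' @param prior_count log2-CPM pseudocount.
#' @param alpha_de DE padj cutoff.
#' @param rif_z RIF |z| cutoff.
#' @param r_min,alpha_r network edge filters.
#' @param dk_z rewiring z cutoff.
#' @param alpha_adj,class_alpha differential-correlation cutoffs.
#' @param kappa kappa-grouping threshold.
#' @param anchor_tfs `"significant"` anchors RIF-significant TFs
#'   (default); `"all"` anchors the full TF list.
#' @param diffcorr_universe pair universe for the scan.
#' @param seed integer seed echoed into the manifest (the pipeline is
#'   deterministic given its inputs).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, samples, tfs, outdir,
                            gmt = NULL, markers = NULL, de_table = NULL,
                            cpm = 0.5, frac = 0.5, prior_count = 0.5,
                            alpha_de = 0.1, rif_z = 2, r_min = 0.95,
                            alpha_r = 0.05, dk_z = 1.96, alpha_adj = 0.05,
                            class_alpha = 0.05, kappa = 0.4,
                            anchor_tfs = c("significant", "all"),
                            diffcorr_universe = c("anchored", "all"),
                            seed = 1L) {
  anchor_tfs <- match.arg(anchor_tfs)
  diffcorr_universe <- match.arg(diffcorr_universe)
  for (f in c(counts, samples, tfs, gmt, markers, de_table)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1L || x < lo || x > hi)
      stop(sprintf("'%s' must lie in [%g, %g]", nm, lo, hi), call. = FALSE)
    as.numeric(x)
  }
  cfg <- list(counts = counts, samples = samples, tfs = tfs, outdir = outdir,
              gmt = gmt, markers = markers, de_table = de_table,
              cpm = chk(cpm, 1e-9, Inf, "cpm"),
              frac = chk(frac, 1e-9, 1, "frac"),
              prior_count = chk(prior_count, 1e-9, Inf, "prior_count"),
              alpha_de = chk(alpha_de, 0, 1, "alpha_de"),
              rif_z = chk(rif_z, 0, Inf, "rif_z"),
              r_min = chk(r_min, 1e-9, 1, "r_min"),
              alpha_r = chk(alpha_r, 0, 1, "alpha_r"),
              dk_z = chk(dk_z, 0, Inf, "dk_z"),
              alpha_adj = chk(alpha_adj, 0, 1, "alpha_adj"),
              class_alpha = chk(class_alpha, 0, 1, "class_alpha"),
              kappa = chk(kappa, -1, 1, "kappa"),
              anchor_tfs = anchor_tfs,
              diffcorr_universe = diffcorr_universe,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; relative input
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @param outdir optional override of the configured output directory.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, outdir = NULL) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  for (key in c("counts", "samples", "tfs", "gmt", "markers", "de_table")) {
    if (!is.null(y[[key]]) && !file.exists(y[[key]]))
      y[[key]] <- file.path(base, y[[key]])
  }
  if (!is.null(outdir)) y$outdir <- outdir
  do.call(pipeline_config, y)
}

#' Run the full differential co-expression pipeline
#'
#' Executes the stages in order: CPM filtering and log2-CPM
#' normalization; differential expression (or a user-supplied DE
#' table); RIF scoring of the TF list against the DE genes; anchor
#' construction (DE genes plus significant TFs); per-condition PCIT
#' networks with the edge filters; hub detection and scale-free fits;
#' the union network with DK z-scores and gain/loss calls; the
#' differential-correlation scan with nine-class labels; and, when a
#' GMT / marker list is configured, over-representation analysis with
#' kappa grouping and the marker intersection. All tables are written
#' as TSV (networks additionally as SIF) under `outdir`, and a JSON
#' manifest records, per stage, the outputs, row counts and wall time.
#' Re-running with the same inputs reproduces every output byte for
#' byte (the manifest differs only in timings).
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly (also written to
#'   `outdir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)
  manifest <- list(package = "asmnet",
                   version = as.character(packageVersion("asmnet")),
                   config = unclass(config), stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- c(res$info,
                                  list(seconds = round(proc.time()[["elapsed"]] - t0, 3)))
    res$value
  }

  counts <- read_matrix_tsv(config$counts)
  samples <- read_sample_sheet(config$samples)
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  if (any(is.na(samples$sample_id)))
    stop("sample sheet does not cover every counts column", call. = FALSE)
  tf_list <- read_gene_list(config$tfs)
  condition <- samples$condition

  filtered <- stage("filter", {
    fc <- filter_low_expression(counts, config$cpm, config$frac)
    write_matrix_tsv(fc, out("filtered_counts.tsv"))
    list(value = fc, info = list(outputs = "filtered_counts.tsv",
                                 rows = nrow(fc)))
  })
  expr <- stage("normalize", {
    e <- normalize_log_cpm(filtered, config$prior_count)
    write_matrix_tsv(e, out("expression.tsv"))
    list(value = e, info = list(outputs = "expression.tsv", rows = nrow(e)))
  })
  de <- stage("de", {
    d <- if (!is.null(config$de_table)) {
      tab <- read.delim(config$de_table, stringsAsFactors = FALSE)
      need <- c("gene_id", "log2FC", "pvalue", "padj")
      if (!all(need %in% names(tab)))
        stop("DE table must have columns: ", paste(need, collapse = ", "))
      tab$status <- ifelse(tab$padj <= config$alpha_de & tab$log2FC > 0, "up",
                           ifelse(tab$padj <= config$alpha_de & tab$log2FC < 0,
                                  "down", "ns"))
      tab
    } else {
      differential_expression(expr, samples, config$alpha_de)
    }
    write_tsv(d, out("de_table.tsv"))
    list(value = d, info = list(outputs = "de_table.tsv",
                                rows = nrow(d),
                                n_de = sum(d$status != "ns")))
  })
  deg_ids <- de$gene_id[de$status != "ns"]

  rif <- stage("rif", {
    tfs_in <- intersect(tf_list, rownames(expr))
    degs_in <- intersect(deg_ids, rownames(expr))
    r <- if (length(degs_in)) {
      rif_scores(expr, condition, tfs_in, degs_in, z_thresh = config$rif_z)
    } else {
      warning("no DE genes: RIF stage produces an empty table", call. = FALSE)
      data.frame(tf_id = character(0), rif1_raw = numeric(0),
                 rif2_raw = numeric(0), rif1_z = numeric(0),
                 rif2_z = numeric(0), significant = logical(0))
    }
    write_tsv(r, out("rif_table.tsv"))
    list(value = r, info = list(outputs = "rif_table.tsv", rows = nrow(r),
                                n_significant = sum(r$significant)))
  })
  sig_tfs <- rif$tf_id[rif$significant]
  anchors <- union(intersect(deg_ids, rownames(expr)),
                   if (config$anchor_tfs == "all")
                     intersect(tf_list, rownames(expr)) else sig_tfs)
  if (!length(anchors))
    stop("stage 'network' failed: empty anchors (no DE genes and no ",
         "significant TFs at the configured thresholds)", call. = FALSE)

  networks <- list()
  summaries <- list()
  for (cond in c("case", "control")) {
    networks[[cond]] <- stage(paste0("network_", cond), {
      cm <- correlation_matrix(expr, samples$sample_id[condition == cond])
      mask <- pcit_edges(cm)
      edges <- build_network(cm, mask, anchors, config$r_min, config$alpha_r)
      f_tsv <- sprintf("edges_%s.tsv", cond)
      write_tsv(edges, out(f_tsv))
      write_sif(edges, out(sprintf("edges_%s.sif", cond)))
      list(value = edges,
           info = list(outputs = c(f_tsv, sprintf("edges_%s.sif", cond)),
                       rows = nrow(edges),
                       nodes = length(unique(c(edges$gene_a, edges$gene_b)))))
    })
  }
  hubs <- stage("hubs", {
    h <- do.call(rbind, lapply(c("case", "control"), function(cond) {
      if (!nrow(networks[[cond]])) return(NULL)
      hh <- hub_genes(networks[[cond]])
      hh$condition <- cond
      hh
    }))
    write_tsv(h, out("hubs.tsv"))
    list(value = h, info = list(outputs = "hubs.tsv",
                                n_hubs_case = sum(h$is_hub[h$condition == "case"]),
                                n_hubs_control = sum(h$is_hub[h$condition == "control"])))
  })
  fits <- stage("scale_free", {
    r2 <- vapply(c("case", "control"), function(cond)
      suppressWarnings(scale_free_fit(networks[[cond]])), numeric(1))
    s <- list(nodes_case = length(unique(unlist(networks$case[, 1:2]))),
              edges_case = nrow(networks$case),
              nodes_control = length(unique(unlist(networks$control[, 1:2]))),
              edges_control = nrow(networks$control),
              r2_case = r2[["case"]], r2_control = r2[["control"]])
    jsonlite::write_json(s, out("network_summary.json"), auto_unbox = TRUE,
                         digits = NA)
    list(value = r2, info = list(outputs = "network_summary.json"))
  })
  conn <- stage("rewire", {
    un <- union_network(networks$case, networks$control)
    ct <- differential_connectivity(un, z_thresh = config$dk_z)
    write_tsv(un$edges, out("union_edges.tsv"))
    write_sif(un$edges, out("union_edges.sif"))
    write_tsv(un$nodes, out("union_nodes.tsv"))
    write_tsv(ct, out("connectivity.tsv"))
    list(value = ct,
         info = list(outputs = c("union_edges.tsv", "union_edges.sif",
                                 "union_nodes.tsv", "connectivity.tsv"),
                     union_nodes = nrow(un$nodes),
                     union_edges = nrow(un$edges),
                     n_dc = sum(ct$call != "ns"),
                     n_gain = sum(ct$call == "gain"),
                     n_loss = sum(ct$call == "loss")))
  })
  dc <- stage("diffcorr", {
    d <- suppressWarnings(diffcorr_scan(expr, condition,
                                        universe = config$diffcorr_universe,
                                        anchors = anchors,
                                        alpha_adj = config$alpha_adj,
                                        class_alpha = config$class_alpha))
    write_tsv(d, out("diffcorr.tsv"))
    cls <- table(d$class[d$significant])
    jsonlite::write_json(as.list(cls), out("diffcorr_classes.json"),
                         auto_unbox = TRUE)
    list(value = d,
         info = list(outputs = c("diffcorr.tsv", "diffcorr_classes.json"),
                     rows = nrow(d), n_significant = sum(d$significant)))
  })

  dc_genes <- conn$gene_id[conn$call != "ns"]
  if (!is.null(config$gmt)) {
    stage("enrich", {
      sets <- read_gmt(config$gmt)
      query <- union(anchors, dc_genes)
      rec <- hypergeometric_ora(query, sets, rownames(expr))
      rec <- kappa_grouping(rec, sets, query, kappa_min = config$kappa)
      write_tsv(rec, out("enrichment.tsv"))
      list(value = rec, info = list(outputs = "enrichment.tsv",
                                    rows = nrow(rec),
                                    n_significant = sum(rec$pvalue < 0.05)))
    })
  }
  if (!is.null(config$markers)) {
    stage("markers", {
      mk <- read_gene_list(config$markers)
      hit <- marker_intersection(anchors, mk)
      write_tsv(data.frame(gene_id = hit$common), out("marker_overlap.tsv"))
      list(value = hit, info = list(outputs = "marker_overlap.tsv",
                                    n_common = hit$n_common))
    })
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
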