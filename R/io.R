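#' Read a counts (or expression) TSV
#'
#' First column must hold gene IDs; remaining columns are samples.
#'
#' @param path TSV file path.
#' @return numeric matrix with gene IDs as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]])) stop("duplicate gene IDs in ", path, call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Read a sample sheet TSV
#'
#' Requires columns `sample_id` and `condition` (values `case` /
#' `control`); `age` and `sex` are optional covariates.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(df$condition), c("case", "control"))
  if (length(bad))
    stop("condition must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs", call. = FALSE)
  df
}

#' Read a one-ID-per-line gene list
#' @param path text file path.
#' @return character vector (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: term, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors; names are term IDs, each
#'   vector carries a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("malformed GMT line (need term, description, >=1 gene): ", ln,
           call. = FALSE)
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    attr(genes, "description") <- parts[2L]
    sets[[parts[1L]]] <- genes
  }
  if (!length(sets)) stop("empty GMT file: ", path, call. = FALSE)
  sets
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_matrix_tsv <- function(m, path, id_col = "gene_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  write_tsv(df, path)
}

#' Write an edge list in SIF format
#'
#' Emits `gene_a <relation> gene_b` lines importable into Cytoscape.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @param path output path.
#' @param relation interaction label (default `"pcit"`).
#' @return Invisibly, `path`.
#' @export
write_sif <- function(edges, path, relation = "pcit") {
  writeLines(paste(edges$gene_a, relation, edges$gene_b, sep = "\t"), path)
  invisible(path)
}
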