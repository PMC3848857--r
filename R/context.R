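#' @name context_network
#' @title The context-specific miRNA effect matrix
#'
#' @description
#' A miRNA represses its direct targets through 3'UTR binding, but its
#' functional footprint extends to the protein-interaction partners of those
#' targets. The context-specific effect of a miRNA is the union of its
#' direct targets and the one-hop protein-network neighbors of those targets
#' (indirect targets). Arranged as a gene-by-miRNA matrix this footprint
#' becomes the design matrix of the enrichment regression: cell values are 1
#' for direct targets, `w_indirect` (default 1) for indirect-only targets
#' and 0 otherwise, with direct taking precedence when both apply.
NULL

#' Group a target table by miRNA
#'
#' @param table An `interaction_table`.
#' @return Named list: one sorted character vector of direct target genes per
#'   miRNA.
#' @export
direct_target_map <- function(table) {
  stopifnot(inherits(table, "interaction_table"))
  lapply(split(table$edges$gene, table$edges$mirna), function(g) sort(unique(g)))
}

#' Direct and indirect (one-hop partner) targets per miRNA
#'
#' For each miRNA, `direct` is its target set and `indirect` is the union of
#' the protein-interaction neighbors of the direct targets, minus the direct
#' targets themselves. Expansion is one hop only; a gene never appears in
#' both sets.
#'
#' @param table An `interaction_table`.
#' @param ppi A `protein_network`.
#' @return Named list of `list(direct =, indirect =)` per miRNA.
#' @export
context_target_map <- function(table, ppi) {
  stopifnot(inherits(ppi, "protein_network"))
  dmap <- direct_target_map(table)
  lapply(dmap, function(direct) {
    nb <- as.character(unlist(ppi$adjacency[direct], use.names = FALSE))
    nb <- nb[!is.na(nb)]
    indirect <- setdiff(sort(unique(nb)), direct)
    list(direct = direct, indirect = indirect)
  })
}

#' Build the gene-by-miRNA context-effect design matrix
#'
#' @param context Mapping from [context_target_map()] (or
#'   [direct_target_map()] output wrapped as direct-only sets).
#' @param universe_mode `"ppi_restricted"` keeps only genes that also appear
#'   in the protein network (genes targeted by a miRNA *and* interacting at
#'   the protein level, the default model universe); `"union"` keeps every
#'   gene in any direct or indirect set.
#' @param w_indirect Value placed in indirect-only cells, in (0, 1];
#'   default 1 (indirect targets treated as targets).
#' @param direct_only If `TRUE`, indirect sets are ignored: the direct-target
#'   baseline design matrix.
#' @param ppi The `protein_network`; required for `ppi_restricted` mode.
#' @return A `context_matrix`: sparse `values` and `provenance` matrices
#'   (provenance codes 1 = direct, 2 = indirect), `gene_index`,
#'   `mirna_index` (both sorted), `w_indirect`, `universe_mode`,
#'   `direct_only`. miRNAs with no in-universe target are dropped with a
#'   message.
#' @export
build_design_matrix <- function(context,
                                universe_mode = c("ppi_restricted", "union"),
                                w_indirect = 1,
                                direct_only = FALSE,
                                ppi = NULL) {
  universe_mode <- match.arg(universe_mode)
  stopifnot(length(context) > 0L, w_indirect > 0, w_indirect <= 1)
  # normalize plain direct maps to the two-set shape
  context <- lapply(context, function(x) {
    if (is.list(x) && all(c("direct", "indirect") %in% names(x))) x
    else list(direct = sort(unique(x)), indirect = character(0))
  })
  if (direct_only) {
    context <- lapply(context, function(x) {
      list(direct = x$direct, indirect = character(0))
    })
  }
  universe <- sort(unique(unlist(lapply(context, function(x) {
    c(x$direct, x$indirect)
  }), use.names = FALSE)))
  if (universe_mode == "ppi_restricted") {
    if (is.null(ppi)) {
      stop("universe_mode 'ppi_restricted' requires the ppi network")
    }
    stopifnot(inherits(ppi, "protein_network"))
    universe <- intersect(universe, ppi$nodes)
  }
  if (length(universe) == 0L) stop("empty gene universe")

  gene_pos <- seq_along(universe)
  names(gene_pos) <- universe
  mirnas <- sort(names(context))

  ii <- integer(0); jj <- integer(0); vv <- numeric(0); pp <- integer(0)
  kept <- character(0)
  col <- 0L
  for (m in mirnas) {
    d <- intersect(context[[m]]$direct, universe)
    ind <- intersect(context[[m]]$indirect, universe)
    if (length(d) + length(ind) == 0L) next
    col <- col + 1L
    kept <- c(kept, m)
    ii <- c(ii, gene_pos[d], gene_pos[ind])
    jj <- c(jj, rep.int(col, length(d) + length(ind)))
    vv <- c(vv, rep(1, length(d)), rep(w_indirect, length(ind)))
    pp <- c(pp, rep.int(1L, length(d)), rep.int(2L, length(ind)))
  }
  if (length(kept) < length(mirnas)) {
    message(sprintf("build_design_matrix: dropped %d miRNA(s) with no in-universe target",
                    length(mirnas) - length(kept)))
  }
  if (col == 0L) stop("empty gene universe")
  values <- Matrix::sparseMatrix(i = ii, j = jj, x = vv,
                                 dims = c(length(universe), col),
                                 dimnames = list(universe, kept))
  provenance <- Matrix::sparseMatrix(i = ii, j = jj, x = as.numeric(pp),
                                     dims = c(length(universe), col),
                                     dimnames = list(universe, kept))
  # drop genes that lost every nonzero (possible when a miRNA column went)
  row_nnz <- Matrix::rowSums(values != 0)
  if (any(row_nnz == 0)) {
    values <- values[row_nnz > 0, , drop = FALSE]
    provenance <- provenance[row_nnz > 0, , drop = FALSE]
  }
  structure(list(values = values,
                 provenance = provenance,
                 gene_index = rownames(values),
                 mirna_index = colnames(values),
                 w_indirect = w_indirect,
                 universe_mode = universe_mode,
                 direct_only = direct_only),
            class = "context_matrix")
}

#' @export
print.context_matrix <- function(x, ...) {
  nnz <- length(x$provenance@x)
  nd <- sum(x$provenance@x == 1)
  cat(sprintf(paste0("<context_matrix> %d genes x %d miRNAs (%s%s), ",
                     "%d nonzeros (%d direct, %d indirect, w_indirect=%g)\n"),
              length(x$gene_index), length(x$mirna_index), x$universe_mode,
              if (x$direct_only) ", direct-only" else "",
              nnz, nd, nnz - nd, x$w_indirect))
  invisible(x)
}

#' Align a gene signature to a context matrix
#'
#' Encodes the signature as the regression response: a 0/1 membership vector
#' over the matrix's gene universe. Genes outside the universe are dropped
#' and reported.
#'
#' @param matrix A `context_matrix`.
#' @param sig A `gene_signature`.
#' @return List with `y` (named 0/1 numeric vector over `gene_index`),
#'   `n_in_universe`, `dropped_genes` and `coverage` (fraction of signature
#'   genes inside the universe).
#' @export
align_signature <- function(matrix, sig) {
  stopifnot(inherits(matrix, "context_matrix"), inherits(sig, "gene_signature"))
  inside <- intersect(sig$genes, matrix$gene_index)
  if (length(inside) == 0L) {
    stop("signature has no overlap with model universe")
  }
  y <- as.numeric(matrix$gene_index %in% inside)
  names(y) <- matrix$gene_index
  coverage <- length(inside) / length(sig$genes)
  message(sprintf("align_signature: '%s' covers %d/%d genes (%.1f%%) of the universe overlap",
                  sig$name, length(inside), length(sig$genes), 100 * coverage))
  list(y = y,
       n_in_universe = length(inside),
       dropped_genes = setdiff(sig$genes, inside),
       coverage = coverage)
}

#' Per-miRNA target counts in a context matrix
#'
#' @param matrix A `context_matrix`.
#' @return Data frame with `mirna`, `n_direct`, `n_context` (direct plus
#'   indirect), in column order.
#' @keywords internal
context_target_counts <- function(matrix) {
  prov <- matrix$provenance
  n_direct <- Matrix::colSums(prov == 1)
  n_total <- Matrix::colSums(prov != 0)
  data.frame(mirna = matrix$mirna_index,
             n_direct = as.integer(n_direct),
             n_context = as.integer(n_total),
             stringsAsFactors = FALSE)
}

#' Write a context matrix as a sparse triplet TSV
#'
#' Columns: `gene`, `mirna`, `value`, `provenance` (`direct`/`indirect`),
#' sorted by gene then miRNA. [read_context_matrix()] reproduces the object.
#'
#' @param matrix A `context_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_context_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "context_matrix"))
  trip <- Matrix::summary(matrix$values)
  prov <- Matrix::summary(matrix$provenance)
  df <- data.frame(gene = matrix$gene_index[trip$i],
                   mirna = matrix$mirna_index[trip$j],
                   value = trip$x,
                   provenance = c("direct", "indirect")[prov$x],
                   stringsAsFactors = FALSE)
  df <- df[order(df$gene, df$mirna), ]
  header <- sprintf("# context_matrix universe_mode=%s w_indirect=%.15g direct_only=%s",
                    matrix$universe_mode, matrix$w_indirect,
                    tolower(matrix$direct_only))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a context matrix written by [write_context_matrix()]
#'
#' @param path Path to the triplet TSV.
#' @return A `context_matrix`.
#' @export
read_context_matrix <- function(path) {
  meta_line <- readLines(path, n = 1L)
  meta <- list(universe_mode = "union", w_indirect = NA_real_,
               direct_only = NA)
  if (startsWith(meta_line, "# context_matrix")) {
    kv <- regmatches(meta_line, gregexpr("[a-z_]+=[^ ]+", meta_line))[[1L]]
    for (pair in kv) {
      key <- sub("=.*", "", pair); val <- sub(".*=", "", pair)
      if (key == "universe_mode") meta$universe_mode <- val
      if (key == "w_indirect") meta$w_indirect <- as.numeric(val)
      if (key == "direct_only") meta$direct_only <- identical(val, "true")
    }
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("gene", "mirna", "value", "provenance")
  if (!all(need %in% names(df)) || nrow(df) == 0L) {
    stop("not a context-matrix triplet file: ", path)
  }
  genes <- sort(unique(df$gene))
  mirnas <- sort(unique(df$mirna))
  gi <- match(df$gene, genes)
  mj <- match(df$mirna, mirnas)
  values <- Matrix::sparseMatrix(i = gi, j = mj, x = df$value,
                                 dims = c(length(genes), length(mirnas)),
                                 dimnames = list(genes, mirnas))
  pcode <- ifelse(df$provenance == "direct", 1, 2)
  provenance <- Matrix::sparseMatrix(i = gi, j = mj, x = pcode,
                                     dims = c(length(genes), length(mirnas)),
                                     dimnames = list(genes, mirnas))
  w <- meta$w_indirect
  if (is.na(w)) {
    ind_vals <- unique(df$value[df$provenance == "indirect"])
    w <- if (length(ind_vals) == 1L) ind_vals else 1
  }
  direct_only <- meta$direct_only
  if (is.na(direct_only)) direct_only <- !any(df$provenance == "indirect")
  structure(list(values = values, provenance = provenance,
                 gene_index = genes, mirna_index = mirnas,
                 w_indirect = w,
                 universe_mode = meta$universe_mode,
                 direct_only = direct_only),
            class = "context_matrix")
}
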