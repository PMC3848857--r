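#' @name io_formats
#' @title File formats used by mircontext
#'
#' @description
#' All external inputs are plain text. Edge lists (miRNA-target, protein
#' functional interaction, gold standard signature-miRNA) are two-column
#' tab-separated files; gene signatures are one-symbol-per-line lists or GMT
#' gene-set files. Normalization happens once at the boundary: gene symbols
#' are uppercased, miRNA identifiers are kept verbatim (miRNA nomenclature is
#' case-meaningful), duplicate records are dropped with a logged count, and
#' readers tolerate any line-ending style, trailing whitespace, blank lines
#' and `#` comments. Native TargetScan/miRTarBase exports must be pre-cut to
#' the two-column shape; the parser is deliberately dialect-free.
NULL

# -- internal parsing helpers -------------------------------------------------

# Read a text file into trimmed lines, dropping blank lines and '#' comments.
read_clean_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

split_tsv_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

norm_gene <- function(x) toupper(trimws(x))

looks_like_gene_symbol <- function(x) grepl("^[A-Z0-9][A-Z0-9-]*$", x)

# -- InteractionTable ---------------------------------------------------------

new_interaction_table <- function(edges, source_tag) {
  stopifnot(is.data.frame(edges), all(c("mirna", "gene") %in% names(edges)))
  edges <- edges[order(edges$mirna, edges$gene), c("mirna", "gene")]
  rownames(edges) <- NULL
  structure(list(edges = edges, source_tag = source_tag),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat(sprintf("<interaction_table> %d edges, %d miRNAs, %d genes [%s]\n",
              nrow(x$edges), length(unique(x$edges$mirna)),
              length(unique(x$edges$gene)), x$source_tag))
  invisible(x)
}

#' Read a miRNA-target interaction table
#'
#' Parses a tab-separated edge list with miRNA identifiers in column 1 and
#' gene symbols in column 2. A single header line is auto-detected when the
#' second field of the first line does not look like an uppercase gene symbol
#' (letters, digits, dashes). Gene symbols are uppercased; miRNA identifiers
#' are kept verbatim. Duplicate and malformed lines are dropped and counted
#' in a message.
#'
#' @param path Path to a TSV file with at least two columns.
#' @param source_tag Evidence tag recorded on the table, e.g. `"predicted"`
#'   (TargetScan-style) or `"validated"` (miRTarBase/miRecords-style union).
#' @return An `interaction_table`: a list with `edges` (data frame of
#'   `mirna`, `gene`) and `source_tag`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("miR-1\tHDAC4", "miR-1\thdac4", "miR-16\tBCL2"), tf)
#' read_mirna_targets(tf, "validated")
read_mirna_targets <- function(path, source_tag = "predicted") {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("no interactions parsed from ", path)
  fields <- split_tsv_fields(lines)
  first <- fields[[1L]]
  if (length(first) >= 2L && !looks_like_gene_symbol(trimws(first[2L]))) {
    fields <- fields[-1L]  # header line
  }
  n_raw <- length(fields)
  keep <- vapply(fields, function(f) {
    length(f) >= 2L && nzchar(trimws(f[1L])) && nzchar(trimws(f[2L]))
  }, logical(1))
  fields <- fields[keep]
  mirna <- vapply(fields, function(f) trimws(f[1L]), character(1))
  gene <- norm_gene(vapply(fields, function(f) f[2L], character(1)))
  edges <- unique(data.frame(mirna = mirna, gene = gene,
                             stringsAsFactors = FALSE))
  dropped <- n_raw - nrow(edges)
  if (dropped > 0L) {
    message(sprintf("read_mirna_targets: dropped %d duplicate/malformed line(s)",
                    dropped))
  }
  if (nrow(edges) == 0L) stop("no interactions parsed from ", path)
  new_interaction_table(edges, source_tag)
}

#' Merge two interaction tables
#'
#' Takes the set union of the edge sets, e.g. to pool validated interactions
#' from several databases. The merged `source_tag` is kept when both inputs
#' share one and becomes `"merged"` otherwise.
#'
#' @param a,b `interaction_table` objects.
#' @return An `interaction_table` with the union of the edges.
#' @export
merge_interaction_tables <- function(a, b) {
  stopifnot(inherits(a, "interaction_table"), inherits(b, "interaction_table"))
  edges <- unique(rbind(a$edges, b$edges))
  tag <- if (identical(a$source_tag, b$source_tag)) a$source_tag else "merged"
  new_interaction_table(edges, tag)
}

# -- ProteinNetwork -----------------------------------------------------------

new_protein_network <- function(edges) {
  stopifnot(is.data.frame(edges), all(c("gene_a", "gene_b") %in% names(edges)))
  # canonical unordered representation: gene_a < gene_b
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  edges <- unique(data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE))
  edges <- edges[order(edges$gene_a, edges$gene_b), ]
  rownames(edges) <- NULL
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  # symmetric adjacency list, the only query the context expansion needs
  adj <- split(c(edges$gene_b, edges$gene_a), c(edges$gene_a, edges$gene_b))
  adj <- lapply(adj, function(v) sort(unique(v)))
  structure(list(edges = edges, nodes = nodes, adjacency = adj),
            class = "protein_network")
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf("<protein_network> %d undirected edges over %d proteins\n",
              nrow(x$edges), length(x$nodes)))
  invisible(x)
}

#' Read an undirected protein functional-interaction network
#'
#' Parses a two-column tab-separated edge list of gene symbols (Reactome
#' functional-interaction style). Edges are undirected: `A B` and `B A`
#' collapse to one edge. Self-loops are dropped with a logged count.
#'
#' @param path Path to a TSV file with two gene-symbol columns.
#' @return A `protein_network`: edge data frame, node vector and a symmetric
#'   adjacency list.
#' @export
read_ppi_edges <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("no protein interactions parsed from ", path)
  fields <- split_tsv_fields(lines)
  first <- fields[[1L]]
  if (length(first) >= 2L &&
      !all(looks_like_gene_symbol(trimws(first[1:2])))) {
    fields <- fields[-1L]  # header line
  }
  keep <- vapply(fields, function(f) {
    length(f) >= 2L && nzchar(trimws(f[1L])) && nzchar(trimws(f[2L]))
  }, logical(1))
  fields <- fields[keep]
  ga <- norm_gene(vapply(fields, `[`, character(1), 1L))
  gb <- norm_gene(vapply(fields, `[`, character(1), 2L))
  loops <- ga == gb
  if (any(loops)) {
    message(sprintf("read_ppi_edges: dropped %d self-loop(s)", sum(loops)))
  }
  edges <- data.frame(gene_a = ga[!loops], gene_b = gb[!loops],
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) stop("no protein interactions parsed from ", path)
  new_protein_network(edges)
}

#' Neighbors of a gene in a protein network
#'
#' @param ppi A `protein_network`.
#' @param gene A gene symbol (uppercased internally).
#' @return Character vector of interaction partners (empty if none).
#' @export
ppi_neighbors <- function(ppi, gene) {
  stopifnot(inherits(ppi, "protein_network"))
  nb <- ppi$adjacency[[norm_gene(gene)]]
  if (is.null(nb)) character(0) else nb
}

# -- GeneSignature ------------------------------------------------------------

new_gene_signature <- function(name, genes) {
  genes <- sort(unique(norm_gene(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("gene signature '", name, "' is empty")
  structure(list(name = name, genes = genes), class = "gene_signature")
}

#' Construct a gene signature
#'
#' A named set of gene symbols (e.g. genes downregulated after pre-miRNA
#' transfection, or a disease/pathway gene set). Symbols are uppercased and
#' deduplicated.
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols.
#' @return A `gene_signature`.
#' @export
gene_signature <- function(name, genes) new_gene_signature(name, genes)

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' Read a one-gene-per-line signature file
#'
#' Blank lines and `#` comments are skipped; symbols are uppercased and
#' deduplicated.
#'
#' @param path Path to the gene list.
#' @param name Name to give the signature (default: file base name).
#' @return A `gene_signature`.
#' @export
read_gene_list <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  lines <- read_clean_lines(path)
  genes <- norm_gene(vapply(split_tsv_fields(lines), `[`, character(1), 1L))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop("no genes parsed from ", path)
  new_gene_signature(name, genes)
}

#' Read a GMT gene-set file
#'
#' Standard MSigDB GMT layout: `name TAB description TAB gene TAB gene ...`.
#' The description field is discarded. Lines with fewer than three fields are
#' skipped with a warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of `gene_signature` objects, in file order.
#' @export
read_gmt <- function(path) {
  lines <- read_clean_lines(path)
  fields <- split_tsv_fields(lines)
  ok <- vapply(fields, length, integer(1)) >= 3L
  if (any(!ok)) {
    warning(sprintf("read_gmt: skipped %d line(s) with fewer than 3 fields",
                    sum(!ok)))
  }
  sets <- lapply(fields[ok], function(f) new_gene_signature(f[1L], f[-(1:2)]))
  if (length(sets) == 0L) stop("no gene sets parsed from ", path)
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Drop undersized gene sets
#'
#' Keeps signatures with at least `min_genes` members; pathway collections
#' are conventionally pruned of sets smaller than 10 genes before enrichment.
#'
#' @param sets List of `gene_signature` objects.
#' @param min_genes Minimum set size kept (default 10).
#' @return The filtered list.
#' @export
filter_gmt_by_size <- function(sets, min_genes = 10L) {
  stopifnot(min_genes >= 1L)
  sets[vapply(sets, function(s) length(s$genes) >= min_genes, logical(1))]
}

# -- generic TSV output and round-trip readers --------------------------------

#' Write a data frame as headered TSV
#'
#' All tabular outputs of the package (enrichment tables, association
#' networks, CV diagnostics, evaluation reports) go through this writer:
#' tab-separated, header line, no quoting, deterministic row order supplied
#' by the caller.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gold-standard signature-miRNA edge list
#'
#' Two-column TSV: signature name, miRNA identifier. A header line is
#' auto-detected when the first line equals the canonical header written by
#' [write_table()] callers (`signature`/`mirna` in its first two fields).
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `signature` and `mirna`, deduplicated.
#' @export
read_gold_standard <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("no gold-standard edges parsed from ", path)
  fields <- split_tsv_fields(lines)
  first <- tolower(trimws(fields[[1L]]))
  if (length(first) >= 2L && first[1L] == "signature" && first[2L] == "mirna") {
    fields <- fields[-1L]
  }
  keep <- vapply(fields, function(f) {
    length(f) >= 2L && nzchar(trimws(f[1L])) && nzchar(trimws(f[2L]))
  }, logical(1))
  fields <- fields[keep]
  if (length(fields) == 0L) stop("no gold-standard edges parsed from ", path)
  edges <- unique(data.frame(
    signature = vapply(fields, function(f) trimws(f[1L]), character(1)),
    mirna = vapply(fields, function(f) trimws(f[2L]), character(1)),
    stringsAsFactors = FALSE))
  edges[order(edges$signature, edges$mirna), , drop = FALSE]
}

#' Write an interaction table as two-column TSV
#'
#' @param table An `interaction_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interaction_table <- function(table, path) {
  stopifnot(inherits(table, "interaction_table"))
  write_table(table$edges, path)
}

#' Write a protein network as two-column TSV
#'
#' @param ppi A `protein_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_protein_network <- function(ppi, path) {
  stopifnot(inherits(ppi, "protein_network"))
  write_table(ppi$edges, path)
}

#' Write a gene signature as a one-gene-per-line list
#'
#' @param sig A `gene_signature`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_list <- function(sig, path) {
  stopifnot(inherits(sig, "gene_signature"))
  writeLines(sig$genes, path)
  invisible(path)
}

#' Write gene signatures as a GMT file
#'
#' @param sets List of `gene_signature` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$name, "na", s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
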