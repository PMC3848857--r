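#' @name association_eval
#' @title miRNA-signature association networks and gold-standard evaluation
#'
#' @description
#' Running the enrichment fit over a collection of signatures (diseases,
#' pathways) yields a bipartite signature-miRNA network: one edge per
#' nonzero influence coefficient. Networks can be thresholded to the highly
#' significant associations (coefficient strictly greater than 0.5 by
#' convention) and compared against a curated gold standard by overlap
#' counts (common / missed / novel) and by AUC, computed as the
#' Mann-Whitney statistic over a configurable candidate space of
#' signature-miRNA pairs with absent pairs scored 0 and ties counting 1/2.
NULL

new_association_network <- function(edges, threshold_applied = NULL) {
  edges <- edges[order(edges$signature, edges$mirna), , drop = FALSE]
  rownames(edges) <- NULL
  stopifnot(!anyDuplicated(edges[c("signature", "mirna")]))
  structure(list(edges = edges, threshold_applied = threshold_applied),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("<association_network> %d edges, %d signatures, %d miRNAs%s\n",
              nrow(x$edges), length(unique(x$edges$signature)),
              length(unique(x$edges$mirna)),
              if (!is.null(x$threshold_applied)) {
                sprintf(" (coefficient > %g)", x$threshold_applied)
              } else ""))
  invisible(x)
}

#' Batch enrichment over many signatures
#'
#' Fits [fit_enrichment()] per signature and collects an edge for every
#' miRNA with a nonzero influence coefficient. Signatures with no overlap
#' with the matrix universe are skipped with a warning; all skipped is an
#' error. Deterministic given `config$seed`.
#'
#' @param matrix A `context_matrix`.
#' @param sigs List of `gene_signature` objects.
#' @param config A [regression_config()].
#' @return An `association_network` with columns `signature`, `mirna`,
#'   `coefficient` plus a `fits` attribute naming skipped signatures.
#' @export
batch_enrich <- function(matrix, sigs, config = regression_config()) {
  stopifnot(length(sigs) >= 1L)
  rows <- list()
  skipped <- character(0)
  for (sig in sigs) {
    res <- tryCatch(fit_enrichment(matrix, sig, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("signature '%s' skipped: %s", sig$name,
                      conditionMessage(res)))
      skipped <- c(skipped, sig$name)
      next
    }
    nz <- res$records[res$records$beta != 0, , drop = FALSE]
    if (nrow(nz) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        signature = sig$name, mirna = nz$mirna, coefficient = nz$beta,
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) == length(sigs)) {
    stop("all signatures were skipped: none overlap the model universe")
  }
  edges <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(signature = character(0), mirna = character(0),
               coefficient = numeric(0), stringsAsFactors = FALSE)
  }
  net <- new_association_network(edges)
  attr(net, "skipped") <- skipped
  net
}

#' Keep only highly significant associations
#'
#' Retains edges with coefficient strictly greater than `min_coef`
#' (default 0.5).
#'
#' @param net An `association_network`.
#' @param min_coef Strict lower bound on the coefficient.
#' @return The thresholded `association_network`, with
#'   `threshold_applied` recorded.
#' @export
threshold_network <- function(net, min_coef = 0.5) {
  stopifnot(inherits(net, "association_network"))
  keep <- net$edges$coefficient > min_coef
  new_association_network(net$edges[keep, , drop = FALSE],
                          threshold_applied = min_coef)
}

# Mann-Whitney AUC with ties counting 1/2, via midranks.
auc_mann_whitney <- function(scores, labels) {
  pos <- labels
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)  # midranks handle ties
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Compare a predicted association network to a gold standard
#'
#' Predicted edges are the network's (pre- or post-threshold) edge set.
#' Counts: `common` = predicted AND gold, `missed` = gold only, `novel` =
#' predicted only. AUC scores every candidate signature-miRNA pair by its
#' coefficient (0 when absent) against gold membership, Mann-Whitney style
#' with ties at 1/2. The default candidate space is all pairs of the
#' network's signatures with the supplied miRNA universe (default: miRNAs
#' seen in the network or the gold standard). Gold edges whose signature is
#' outside the candidate space are excluded from the AUC with a warning but
#' still counted as missed.
#'
#' @param net An `association_network`.
#' @param gold Data frame with columns `signature`, `mirna` (e.g. from
#'   [read_gold_standard()]).
#' @param candidate_space Optional data frame of `signature`, `mirna` pairs
#'   over which the AUC is computed.
#' @param mirnas Optional miRNA universe used to span the default candidate
#'   space (pass the context matrix's `mirna_index` to mirror the model).
#' @return An `evaluation_report`: `n_common`, `n_missed`, `n_novel`,
#'   `auc`, and `labeled_pairs` (signature, mirna, score, in_gold).
#' @export
compare_to_gold <- function(net, gold, candidate_space = NULL, mirnas = NULL) {
  stopifnot(inherits(net, "association_network"), is.data.frame(gold),
            all(c("signature", "mirna") %in% names(gold)))
  gold <- unique(gold[c("signature", "mirna")])
  if (nrow(gold) == 0L) stop("gold standard is empty")
  pred <- net$edges
  key <- function(df) paste(df$signature, df$mirna, sep = "\r")
  pred_keys <- key(pred)
  gold_keys <- key(gold)
  n_common <- sum(gold_keys %in% pred_keys)
  n_missed <- nrow(gold) - n_common
  n_novel <- nrow(pred) - n_common

  if (is.null(candidate_space)) {
    if (is.null(mirnas)) mirnas <- sort(unique(c(pred$mirna, gold$mirna)))
    sig_space <- sort(unique(pred$signature))
    candidate_space <- expand.grid(signature = sig_space, mirna = mirnas,
                                   KEEP.OUT.ATTRS = FALSE,
                                   stringsAsFactors = FALSE)
  }
  candidate_space <- unique(candidate_space[c("signature", "mirna")])
  cand_keys <- key(candidate_space)
  outside <- !(gold_keys %in% cand_keys)
  if (any(outside)) {
    warning(sprintf("%d gold edge(s) outside the candidate space: excluded from AUC, counted as missed",
                    sum(outside)))
  }
  score <- numeric(nrow(candidate_space))
  hit <- match(cand_keys, pred_keys)
  score[!is.na(hit)] <- pred$coefficient[hit[!is.na(hit)]]
  in_gold <- cand_keys %in% gold_keys
  labeled <- data.frame(signature = candidate_space$signature,
                        mirna = candidate_space$mirna,
                        score = score, in_gold = in_gold,
                        stringsAsFactors = FALSE)
  labeled <- labeled[order(labeled$signature, labeled$mirna), ]
  rownames(labeled) <- NULL
  structure(list(n_common = n_common, n_missed = n_missed, n_novel = n_novel,
                 auc = auc_mann_whitney(labeled$score, labeled$in_gold),
                 labeled_pairs = labeled),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("common=%d missed=%d novel=%d AUC=%s\n",
              x$n_common, x$n_missed, x$n_novel,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc))))
  invisible(x)
}

#' Write an association network as TSV
#'
#' @param net An `association_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_association_network <- function(net, path) {
  stopifnot(inherits(net, "association_network"))
  write_table(net$edges, path)
}

#' Read an association network TSV (signature, mirna, coefficient)
#'
#' @param path Path written by [write_association_network()].
#' @return An `association_network`.
#' @export
read_association_network <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("signature", "mirna", "coefficient") %in% names(df))) {
    stop("not an association-network file: ", path)
  }
  new_association_network(df[c("signature", "mirna", "coefficient")])
}

#' Write an evaluation report as TSV
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  write_table(report$labeled_pairs, path)
}
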