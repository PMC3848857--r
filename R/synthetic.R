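#' @name synthetic_data
#' @title Seeded synthetic benchmarks with planted ground truth
#'
#' @description
#' Generates miRNA-target tables, protein-interaction graphs, planted gene
#' signatures and noisy gold standards with known ground truth, emulating
#' the real inputs at their published scale (305 miRNAs targeting 3235
#' genes). Signatures mimic pre-miRNA transfection experiments: a list of
#' repressed genes drawn from a planted miRNA's direct targets, its one-hop
#' partners, plus unrelated noise genes. The `hub_bias` knob reproduces the
#' observed tendency of highly connected proteins to be targeted by more
#' miRNAs. All draws are seeded; sub-generators use fixed offsets of the
#' scenario seed so each stage is independently reproducible.
NULL

#' Define a synthetic benchmark scenario
#'
#' Defaults mirror the published scale (305 miRNAs, 3235 genes); the
#' `"small"` preset (100 miRNAs, 1500 genes) is the reduced scale used for
#' testing the recovery properties.
#'
#' @param n_mirnas,n_genes Numbers of miRNAs and genes.
#' @param targets_per_mirna Length-2 integer range; each miRNA draws its
#'   direct-target count uniformly from it.
#' @param ppi_mean_degree Mean protein-interaction degree.
#' @param ppi_model `"erdos_renyi"` or `"preferential_attachment"`.
#' @param hub_bias Propensity (`>= 0`) of high-degree proteins to acquire
#'   miRNA targets; 0 means uniform target sampling.
#' @param planted miRNA id(s) carrying the planted signal.
#' @param sig_n_direct,sig_n_indirect,sig_n_noise Signature composition:
#'   genes drawn from the planted miRNA's direct targets, from its indirect
#'   (partner) targets, and from unrelated genes.
#' @param gold_fp_rate,gold_fn_rate Corruption rates for the synthetic gold
#'   standard, in \[0, 1).
#' @param seed Root seed; all generator randomness derives from it.
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_mirnas = 305L,
                               n_genes = 3235L,
                               targets_per_mirna = c(60L, 120L),
                               ppi_mean_degree = 8,
                               ppi_model = c("erdos_renyi",
                                             "preferential_attachment"),
                               hub_bias = 0,
                               planted = "miR-0001",
                               sig_n_direct = 60L,
                               sig_n_indirect = 20L,
                               sig_n_noise = 20L,
                               gold_fp_rate = 0.3,
                               gold_fn_rate = 0.3,
                               seed = 1L) {
  ppi_model <- match.arg(ppi_model)
  stopifnot(n_mirnas >= 1L, n_genes >= 2L,
            length(targets_per_mirna) == 2L,
            targets_per_mirna[1L] >= 1L,
            targets_per_mirna[2L] >= targets_per_mirna[1L],
            targets_per_mirna[2L] <= n_genes,
            ppi_mean_degree > 0, hub_bias >= 0,
            sig_n_direct >= 0L, sig_n_indirect >= 0L, sig_n_noise >= 0L,
            gold_fp_rate >= 0, gold_fp_rate < 1,
            gold_fn_rate >= 0, gold_fn_rate < 1)
  structure(list(n_mirnas = as.integer(n_mirnas),
                 n_genes = as.integer(n_genes),
                 targets_per_mirna = as.integer(targets_per_mirna),
                 ppi_mean_degree = ppi_mean_degree,
                 ppi_model = ppi_model,
                 hub_bias = hub_bias,
                 planted = planted,
                 sig_n_direct = as.integer(sig_n_direct),
                 sig_n_indirect = as.integer(sig_n_indirect),
                 sig_n_noise = as.integer(sig_n_noise),
                 gold_fp_rate = gold_fp_rate,
                 gold_fn_rate = gold_fn_rate,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Scenario presets
#'
#' `"paper"` is the published scale (305 miRNAs, 3235 genes); `"small"` is
#' the reduced testing scale (100 miRNAs, 1500 genes).
#'
#' @param preset `"paper"` or `"small"`.
#' @param ... Overrides passed to [synthetic_scenario()].
#' @return A `synthetic_scenario`.
#' @export
scenario_preset <- function(preset = c("paper", "small"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "small") {
    base <- list(n_mirnas = 100L, n_genes = 1500L)
    args <- utils::modifyList(base, args)
  }
  do.call(synthetic_scenario, args)
}

synthetic_gene_ids <- function(n) sprintf("G%04d", seq_len(n))
synthetic_mirna_ids <- function(n) sprintf("miR-%04d", seq_len(n))

#' Simulate a protein functional-interaction network
#'
#' Erdos-Renyi (`sample_gnm`) or preferential-attachment (`sample_pa`)
#' graph over all `n_genes` synthetic gene ids, with the configured mean
#' degree. Seeded and reproducible.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A `protein_network`.
#' @export
simulate_ppi <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  n <- scenario$n_genes
  g <- with_seed(scenario$seed + 1L, {
    if (scenario$ppi_model == "erdos_renyi") {
      m <- max(1L, round(scenario$ppi_mean_degree * n / 2))
      igraph::sample_gnm(n, m)
    } else {
      igraph::sample_pa(n, m = max(1L, round(scenario$ppi_mean_degree / 2)),
                        directed = FALSE)
    }
  })
  ids <- synthetic_gene_ids(n)
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(gene_a = ids[el[, 1L]], gene_b = ids[el[, 2L]],
                      stringsAsFactors = FALSE)
  edges <- edges[edges$gene_a != edges$gene_b, , drop = FALSE]
  new_protein_network(edges)
}

#' Simulate miRNA-target interactions
#'
#' Each miRNA draws its target count uniformly from
#' `targets_per_mirna` and samples genes without replacement with
#' probability proportional to `1 + hub_bias * degree(gene)`, where degree
#' is taken from the protein network; `hub_bias = 0` gives uniform
#' sampling.
#'
#' @param scenario A `synthetic_scenario`.
#' @param ppi The `protein_network` from [simulate_ppi()].
#' @return An `interaction_table` tagged `"predicted"`.
#' @export
simulate_interactions <- function(scenario, ppi) {
  stopifnot(inherits(scenario, "synthetic_scenario"),
            inherits(ppi, "protein_network"))
  genes <- synthetic_gene_ids(scenario$n_genes)
  deg <- vapply(genes, function(g) {
    nb <- ppi$adjacency[[g]]
    if (is.null(nb)) 0L else length(nb)
  }, integer(1))
  w <- 1 + scenario$hub_bias * deg
  mirnas <- synthetic_mirna_ids(scenario$n_mirnas)
  lo <- scenario$targets_per_mirna[1L]
  hi <- scenario$targets_per_mirna[2L]
  edges <- with_seed(scenario$seed + 2L, {
    rows <- lapply(mirnas, function(m) {
      k <- if (lo == hi) lo else sample(lo:hi, 1L)
      data.frame(mirna = m, gene = sample(genes, k, prob = w),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  new_interaction_table(edges, "predicted")
}

#' Plant a gene signature with known regulating miRNA(s)
#'
#' Samples `sig_n_direct` genes from the planted miRNAs' direct targets,
#' `sig_n_indirect` from their indirect (partner) targets and `sig_n_noise`
#' from unrelated genes, all without replacement. Emulates a list of genes
#' repressed after pre-miRNA transfection.
#'
#' @param context Mapping from [context_target_map()].
#' @param scenario A `synthetic_scenario`.
#' @return List with `signature` (a `gene_signature`) and `truth`
#'   (`planted` ids and the pools used).
#' @export
plant_signature <- function(context, scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  planted <- scenario$planted
  missing <- setdiff(planted, names(context))
  if (length(missing)) {
    stop("planted miRNA(s) not in context mapping: ",
         paste(missing, collapse = ", "))
  }
  direct_pool <- sort(unique(unlist(lapply(context[planted], `[[`, "direct"))))
  indirect_pool <- setdiff(
    sort(unique(unlist(lapply(context[planted], `[[`, "indirect")))),
    direct_pool)
  all_genes <- synthetic_gene_ids(scenario$n_genes)
  noise_pool <- setdiff(all_genes, c(direct_pool, indirect_pool))
  need <- c(direct = scenario$sig_n_direct,
            indirect = scenario$sig_n_indirect,
            noise = scenario$sig_n_noise)
  have <- c(direct = length(direct_pool), indirect = length(indirect_pool),
            noise = length(noise_pool))
  if (any(need > have)) {
    bad <- names(need)[need > have]
    stop(sprintf("requested signature counts exceed available pools (%s); pools: direct=%d, indirect=%d, noise=%d",
                 paste(bad, collapse = ", "), have["direct"],
                 have["indirect"], have["noise"]))
  }
  genes <- with_seed(scenario$seed + 3L, {
    c(if (need["direct"] > 0) sample(direct_pool, need["direct"]),
      if (need["indirect"] > 0) sample(indirect_pool, need["indirect"]),
      if (need["noise"] > 0) sample(noise_pool, need["noise"]))
  })
  name <- paste0("sig_", paste(planted, collapse = "+"))
  list(signature = new_gene_signature(name, genes),
       truth = list(planted = planted,
                    signature_name = name,
                    n_direct_pool = length(direct_pool),
                    n_indirect_pool = length(indirect_pool)))
}

#' Plant one signature per miRNA for association benchmarks
#'
#' Picks `n_signatures` distinct planted miRNAs (the first ones with large
#' enough pools) and plants one signature for each, giving a true
#' signature-miRNA association edge list.
#'
#' @param context Mapping from [context_target_map()].
#' @param scenario A `synthetic_scenario`; `planted` is ignored, signature
#'   composition fields are reused per signature.
#' @param n_signatures Number of signatures to plant.
#' @return List with `signatures` (list of `gene_signature`) and
#'   `truth_edges` (data frame `signature`, `mirna`).
#' @export
plant_association_truth <- function(context, scenario, n_signatures) {
  stopifnot(n_signatures >= 1L)
  usable <- names(context)[vapply(context, function(x) {
    length(x$direct) >= scenario$sig_n_direct &&
      length(setdiff(x$indirect, x$direct)) >= scenario$sig_n_indirect
  }, logical(1))]
  if (length(usable) < n_signatures) {
    stop(sprintf("only %d miRNA(s) have large enough pools for %d signature(s)",
                 length(usable), n_signatures))
  }
  picked <- usable[seq_len(n_signatures)]
  sigs <- vector("list", n_signatures)
  for (i in seq_along(picked)) {
    sc <- scenario
    sc$planted <- picked[i]
    sc$seed <- scenario$seed + 100L * i
    sigs[[i]] <- plant_signature(context, sc)$signature
  }
  list(signatures = sigs,
       truth_edges = data.frame(
         signature = vapply(sigs, `[[`, character(1), "name"),
         mirna = picked, stringsAsFactors = FALSE))
}

#' Corrupt a true association edge set into a noisy gold standard
#'
#' Removes each true edge with probability `gold_fn_rate`, then adds random
#' false edges (pairs of the truth's signatures with the supplied miRNA
#' pool) until the set reaches `round(|true| * (1 + gold_fp_rate))` edges.
#'
#' @param truth_edges Data frame with columns `signature`, `mirna`.
#' @param scenario A `synthetic_scenario` (rates and seed).
#' @param mirna_pool miRNA ids false edges may use.
#' @return Data frame `signature`, `mirna`: the corrupted gold standard.
#' @export
corrupt_gold <- function(truth_edges, scenario, mirna_pool) {
  stopifnot(is.data.frame(truth_edges), nrow(truth_edges) >= 1L,
            all(c("signature", "mirna") %in% names(truth_edges)))
  n_true <- nrow(truth_edges)
  target_size <- round(n_true * (1 + scenario$gold_fp_rate))
  sig_space <- unique(truth_edges$signature)
  true_key <- paste(truth_edges$signature, truth_edges$mirna, sep = "\r")
  with_seed(scenario$seed + 4L, {
    keep <- stats::runif(n_true) >= scenario$gold_fn_rate
    gold <- truth_edges[keep, , drop = FALSE]
    all_pairs <- expand.grid(signature = sig_space, mirna = mirna_pool,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    all_key <- paste(all_pairs$signature, all_pairs$mirna, sep = "\r")
    candidates <- all_pairs[!(all_key %in% true_key), , drop = FALSE]
    n_add <- min(max(0L, target_size - nrow(gold)), nrow(candidates))
    if (n_add > 0L) {
      add <- candidates[sample.int(nrow(candidates), n_add), , drop = FALSE]
      gold <- rbind(gold, add)
    }
    gold <- gold[order(gold$signature, gold$mirna), , drop = FALSE]
    rownames(gold) <- NULL
    gold
  })
}

#' Run a full synthetic scenario end to end
#'
#' Convenience wrapper: simulates the PPI graph and interaction table,
#' builds the context mapping and design matrix, and plants the signature.
#'
#' @param scenario A `synthetic_scenario`.
#' @param direct_only Build the direct-target baseline matrix instead of
#'   the context matrix.
#' @return List with `ppi`, `interactions`, `context`, `matrix`,
#'   `signature`, `truth`.
#' @export
simulate_scenario <- function(scenario, direct_only = FALSE) {
  ppi <- simulate_ppi(scenario)
  interactions <- simulate_interactions(scenario, ppi)
  context <- context_target_map(interactions, ppi)
  matrix <- build_design_matrix(context, universe_mode = "ppi_restricted",
                                direct_only = direct_only, ppi = ppi)
  planted <- plant_signature(context, scenario)
  list(ppi = ppi, interactions = interactions, context = context,
       matrix = matrix, signature = planted$signature,
       truth = planted$truth)
}

#' Add a decoy miRNA sharing most of a planted miRNA's targets
#'
#' Emulates a miRNA-family sibling: the decoy's direct targets are a random
#' fraction `share` of the planted miRNA's direct targets, so its context
#' footprint is almost entirely contained in the planted one's. Used to
#' probe whether the regression suppresses redundant family members.
#'
#' @param table An `interaction_table`.
#' @param planted The planted miRNA id.
#' @param share Fraction of the planted miRNA's direct targets the decoy
#'   shares (default 0.9).
#' @param decoy_id Identifier for the decoy miRNA.
#' @param seed Integer seed for the target subsample.
#' @return The `interaction_table` with the decoy's edges appended.
#' @export
add_decoy_mirna <- function(table, planted, share = 0.9,
                            decoy_id = "miR-decoy", seed = 1L) {
  stopifnot(inherits(table, "interaction_table"), share > 0, share <= 1)
  targets <- table$edges$gene[table$edges$mirna == planted]
  if (length(targets) == 0L) stop("planted miRNA has no targets: ", planted)
  k <- max(1L, round(share * length(targets)))
  picked <- with_seed(seed, sample(targets, k))
  new_interaction_table(
    rbind(table$edges,
          data.frame(mirna = decoy_id, gene = picked,
                     stringsAsFactors = FALSE)),
    table$source_tag)
}
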