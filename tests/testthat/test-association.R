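make_net <- function(edges) {
  mircontext:::new_association_network(edges)
}

test_that("batch enrichment collects one edge per nonzero coefficient per signature", {
  sc <- scenario_preset("small", seed = 31L)
  sim <- suppressMessages(simulate_scenario(sc))
  assoc <- plant_association_truth(sim$context, sc, 2L)
  cfg <- regression_config(n_lambda = 40)
  net <- suppressMessages(batch_enrich(sim$matrix, assoc$signatures, cfg))
  per_sig <- vapply(assoc$signatures, function(s) {
    res <- suppressMessages(fit_enrichment(sim$matrix, s, cfg))
    sum(res$records$beta != 0)
  }, numeric(1))
  expect_equal(nrow(net$edges), sum(per_sig))
  expect_false(anyDuplicated(net$edges[c("signature", "mirna")]) > 0)
  # deterministic given the config seed
  net2 <- suppressMessages(batch_enrich(sim$matrix, assoc$signatures, cfg))
  expect_identical(net$edges, net2$edges)
  # planted miRNAs show up as edges of their own signatures
  for (i in 1:2) {
    sub <- net$edges[net$edges$signature == assoc$truth_edges$signature[i], ]
    expect_true(assoc$truth_edges$mirna[i] %in% sub$mirna)
  }
})

test_that("signatures with no universe overlap are skipped with a warning", {
  sc <- scenario_preset("small", seed = 31L)
  sim <- suppressMessages(simulate_scenario(sc))
  bad <- gene_signature("alien", c("XX1", "XX2"))
  cfg <- regression_config(n_lambda = 20)
  expect_warning(
    net <- suppressMessages(batch_enrich(sim$matrix,
                                         list(sim$signature, bad), cfg)),
    "skipped")
  expect_true(all(net$edges$signature == sim$signature$name))
  expect_error(
    suppressWarnings(batch_enrich(sim$matrix, list(bad), cfg)),
    "all signatures were skipped")
})

test_that("thresholding keeps strictly greater coefficients only", {
  net <- make_net(data.frame(signature = "d1", mirna = c("m1", "m2", "m3"),
                             coefficient = c(0.6, 0.5, 0.4),
                             stringsAsFactors = FALSE))
  kept <- threshold_network(net, 0.5)
  expect_equal(kept$edges$mirna, "m1")
  expect_equal(kept$threshold_applied, 0.5)
  expect_equal(nrow(threshold_network(net, -Inf)$edges), 3L)
  expect_equal(nrow(threshold_network(net, 1)$edges), 0L)
})

test_that("gold-standard comparison does exact set arithmetic", {
  net <- make_net(data.frame(signature = "d1", mirna = c("m1", "m2"),
                             coefficient = c(0.9, 0.7),
                             stringsAsFactors = FALSE))
  gold <- data.frame(signature = "d1", mirna = c("m1", "m3"),
                     stringsAsFactors = FALSE)
  rep <- compare_to_gold(net, gold, mirnas = c("m1", "m2", "m3", "m4"))
  expect_equal(rep$n_common, 1L)
  expect_equal(rep$n_missed, 1L)
  expect_equal(rep$n_novel, 1L)
  expect_equal(rep$n_common + rep$n_missed, nrow(gold))
  expect_equal(rep$n_common + rep$n_novel, nrow(net$edges))
  expect_error(compare_to_gold(net, gold[0, ]), "empty")
})

test_that("AUC is 1 for perfect separation, 0.5 for all-tied scores, and midrank-correct", {
  net <- make_net(data.frame(signature = "d1", mirna = c("m1", "m2"),
                             coefficient = c(0.9, 0.8),
                             stringsAsFactors = FALSE))
  gold <- data.frame(signature = "d1", mirna = c("m1", "m2"),
                     stringsAsFactors = FALSE)
  rep <- compare_to_gold(net, gold, mirnas = sprintf("m%d", 1:6))
  expect_equal(rep$auc, 1.0)

  auc <- mircontext:::auc_mann_whitney
  expect_equal(auc(rep(3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:20, 1)
    scores <- sample(0:3, n, replace = TRUE) / 3
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(auc(scores, labels), auc_enum(scores, labels))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  auc <- mircontext:::auc_mann_whitney
  set.seed(2)
  scores <- runif(40)
  labels <- runif(40) < 0.3
  expect_equal(auc(scores, labels), auc(exp(3 * scores), labels))
  expect_equal(auc(scores, labels), auc(rank(scores), labels))
})

test_that("count identities hold on random synthetic gold/predicted draws", {
  set.seed(99)
  for (i in 1:100) {
    sigs <- sprintf("d%d", 1:3)
    mirnas <- sprintf("m%02d", 1:12)
    all_pairs <- expand.grid(signature = sigs, mirna = mirnas,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pred_idx <- sample(nrow(all_pairs), sample(1:15, 1))
    gold_idx <- sample(nrow(all_pairs), sample(1:15, 1))
    net <- make_net(cbind(all_pairs[pred_idx, ],
                          coefficient = runif(length(pred_idx))))
    gold <- all_pairs[gold_idx, ]
    rep <- suppressWarnings(compare_to_gold(net, gold, mirnas = mirnas))
    expect_equal(rep$n_common + rep$n_missed, nrow(gold))
    expect_equal(rep$n_common + rep$n_novel, nrow(net$edges))
  }
})

test_that("gold edges outside the candidate space warn, count as missed, skip the AUC", {
  net <- make_net(data.frame(signature = "d1", mirna = "m1",
                             coefficient = 0.9, stringsAsFactors = FALSE))
  gold <- data.frame(signature = c("d1", "dX"), mirna = c("m1", "m2"),
                     stringsAsFactors = FALSE)
  cand <- expand.grid(signature = "d1", mirna = c("m1", "m2"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expect_warning(rep <- compare_to_gold(net, gold, candidate_space = cand),
                 "outside the candidate space")
  expect_equal(rep$n_missed, 1L)
  expect_equal(nrow(rep$labeled_pairs), 2L)
  expect_false(any(rep$labeled_pairs$signature == "dX"))
})

test_that("thresholding never increases the novel count", {
  set.seed(123)
  for (i in 1:20) {
    sigs <- sprintf("d%d", 1:2)
    mirnas <- sprintf("m%02d", 1:10)
    all_pairs <- expand.grid(signature = sigs, mirna = mirnas,
                             KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    pred_idx <- sample(nrow(all_pairs), 8)
    net <- make_net(cbind(all_pairs[pred_idx, ], coefficient = runif(8)))
    gold <- all_pairs[sample(nrow(all_pairs), 6), ]
    before <- suppressWarnings(compare_to_gold(net, gold, mirnas = mirnas))
    thr <- threshold_network(net, 0.5)
    if (nrow(thr$edges) == 0) next
    after <- suppressWarnings(compare_to_gold(thr, gold, mirnas = mirnas))
    expect_lte(after$n_novel, before$n_novel)
  }
})

test_that("evaluation report and association network round-trip through TSV", {
  net <- make_net(data.frame(signature = c("d1", "d2"),
                             mirna = c("m1", "m2"),
                             coefficient = c(0.61, 0.42),
                             stringsAsFactors = FALSE))
  tf <- tempfile()
  write_association_network(net, tf)
  expect_equal(read_association_network(tf)$edges, net$edges)
  gold <- data.frame(signature = "d1", mirna = "m1", stringsAsFactors = FALSE)
  rep <- compare_to_gold(net, gold)
  ef <- tempfile()
  write_evaluation_report(rep, ef)
  back <- utils::read.table(ef, sep = "\t", header = TRUE)
  expect_equal(nrow(back), nrow(rep$labeled_pairs))
})
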