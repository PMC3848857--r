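# Independent oracles used to check the solver and statistics.
# Everything here is deliberately implemented by a different route than the
# package code it verifies.

# Elastic-net objective in the 1/(2n) scaling, evaluated directly.
enet_objective <- function(X, y, intercept, beta, lambda, alpha) {
  n <- nrow(X)
  rss <- sum((y - intercept - drop(X %*% beta))^2)
  pen <- sum(0.5 * (1 - alpha) * beta^2 + alpha * abs(beta))
  rss / (2 * n) + lambda * pen
}

# High-precision proximal-gradient (FISTA) solver of the identical objective.
# The intercept is handled by centering, which is exactly the unpenalized-
# intercept profile of the objective.
fista_enet <- function(X, y, lambda, alpha, max_iter = 200000L, tol = 1e-13) {
  n <- nrow(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm, "-")
  ym <- mean(y)
  yc <- y - ym
  L <- max(eigen(crossprod(Xc) / n, symmetric = TRUE,
                 only.values = TRUE)$values) + lambda * (1 - alpha)
  b <- numeric(ncol(X))
  z <- b
  tk <- 1
  for (it in seq_len(max_iter)) {
    grad <- drop(crossprod(Xc, Xc %*% z - yc)) / n + lambda * (1 - alpha) * z
    u <- z - grad / L
    thr <- lambda * alpha / L
    bn <- sign(u) * pmax(abs(u) - thr, 0)
    tn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- bn + ((tk - 1) / tn) * (bn - b)
    delta <- max(abs(bn - b))
    b <- bn
    tk <- tn
    if (it > 20L && delta < tol) break
  }
  list(beta = b, intercept = ym - sum(xm * b))
}

# Exact hypergeometric upper tail by combinatorial enumeration.
hyper_tail_enum <- function(overlap, target_count, universe, draw) {
  js <- overlap:min(target_count, draw)
  if (overlap > min(target_count, draw)) return(0)
  sum(choose(target_count, js) * choose(universe - target_count, draw - js)) /
    choose(universe, draw)
}

# AUC by exhaustive pairwise comparison, ties counting 1/2.
auc_enum <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Random regression instance for solver checks.
random_instance <- function(seed, n = 30L, p = 8L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p) * rbinom(p, 1, 0.5)
  y <- drop(X %*% beta) + rnorm(n, sd = 0.5)
  list(X = X, y = y)
}

# Tiny deterministic interaction/PPI fixtures used across files.
toy_interactions <- function() {
  edges <- data.frame(
    mirna = c("m1", "m1", "m2"),
    gene = c("A", "B", "A"),
    stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  writeLines(sprintf("%s\t%s", edges$mirna, edges$gene), tf)
  read_mirna_targets(tf, "predicted")
}

toy_ppi <- function(pairs) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(vapply(pairs, function(p) paste(p, collapse = "\t"),
                    character(1)), tf)
  read_ppi_edges(tf)
}
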