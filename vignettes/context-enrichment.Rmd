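---
title: "Context-specific miRNA effect enrichment: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-specific miRNA effect enrichment: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given a list of genes of interest — genes repressed after transfecting a
pre-miRNA, a disease expression signature, a curated pathway — which miRNAs
plausibly regulate it? Classical over-representation analysis (ORA) tests
each miRNA's target set for overlap with the list using a hypergeometric or
Fisher test. Two things are lost in that approach. First, a miRNA's
functional reach extends past the mRNAs it binds: repressing a protein
perturbs its interaction partners, so the relevant footprint is the direct
targets *plus* their protein-interaction neighborhood. Second, ORA scores
each miRNA independently, so members of the same miRNA family — which share
seed sequences and hence target sets — all light up together, burying the
causal miRNA among its redundant siblings.

`mircontext` addresses both. It builds a *context-specific effect* matrix
in which each miRNA's column marks its direct targets and their one-hop
protein-interaction partners, then fits all miRNAs *jointly* by regressing
the signature membership vector on those columns with an elastic-net
penalty. The fitted influence coefficients are the enrichment scores.

## The model

Let the gene universe contain $n$ genes and $p$ miRNAs. The design matrix
$X \in \mathbb{R}^{n \times p}$ has

$$x_{gj} = \begin{cases}
1 & g \text{ is a direct target of miRNA } j\\
w & g \text{ interacts with a direct target of miRNA } j \text{ (indirect)}\\
0 & \text{otherwise,}
\end{cases}$$

with the indirect weight $w \in (0,1]$ defaulting to 1 (indirect targets
treated as targets; a cell that qualifies as both is recorded as direct).
The signature becomes the response $y \in \{0,1\}^n$, $y_g = 1$ iff gene
$g$ belongs to the signature. Membership is the minimal encoding of "a list
of genes of interest" as a vector; no expression magnitudes are assumed.

The influence coefficients solve

$$\hat\beta = \arg\min_\beta \; \frac{1}{2n}\sum_g \Big(y_g - \beta_0 -
  x_g^\top \beta\Big)^2 \;+\;
  \lambda \sum_j \Big[\tfrac{1}{2}(1-\alpha)\beta_j^2 + \alpha|\beta_j|\Big],$$

the elastic net in the $1/(2n)$ (glmnet) scaling, so $\lambda$ values are
comparable across tools in that ecosystem. The intercept is unpenalized.
$\alpha = 1$ is the lasso, $\alpha = 0$ ridge. The $\ell_1$ part produces a
sparse, directly readable ranking; the $\ell_2$ part keeps the solution
stable when columns are strongly correlated — exactly the miRNA-family
situation — while still letting the best-supported family member dominate.
miRNAs are ranked by signed $\beta$ descending: the model regresses
membership on influence, so positive coefficients mean enrichment, and
negative or zero coefficients are ranked below all positive ones (ties
break lexicographically by miRNA id, so ranks are total and reproducible).

## Fitting

The solver is cyclic coordinate descent with covariance updates: the
sufficient statistics $X^\top X$ and $X^\top y$ are formed once, making
each coordinate update $O(p)$ rather than $O(n)$ — the design here is tall
(thousands of genes, hundreds of miRNAs), so this is the right trade. The
coordinate update is the standard soft-threshold step
$\beta_j \leftarrow S(z_j, \lambda\alpha)\,/\,(x_j^\top x_j/n +
\lambda(1-\alpha))$. Predictors are centered and (by default) scaled to
unit population variance before fitting; coefficients are reported back on
the original scale. Constant columns are dropped with a warning and carry a
zero coefficient. Convergence is declared when the largest absolute
coefficient change in a sweep falls below `tol` (default `1e-7`);
non-convergence raises a warning, never a silent pass. The kernel is
implemented in C++ (Rcpp).

Penalty-path mechanics:

* `lambda_max` $= \max_j |\langle x_j, y - \bar y\rangle| / (n\,
  \max(\alpha, 0.001))$ is the smallest penalty that zeroes every
  coefficient; the floor keeps the anchor finite near ridge.
* The path is 100 log-spaced values from `lambda_max` down to
  `lambda_max * 1e-4`, fitted warm-started from sparse to dense.
* $\lambda$ is selected by 10-fold cross-validation at minimum mean
  squared error (`lambda_min`, not the one-standard-error rule — the
  selection criterion here is purely the minimum). Exact ties resolve to
  the larger penalty, i.e. the sparser model.
* Folds are stratified by response class so every training split retains
  signature genes, and are a deterministic function of the seed. A fold
  whose training response is constant is skipped with a warning; more than
  half skipped is an error.
* $\alpha$ defaults to 0.6. With `alpha = "auto"` the package runs the
  cross-validation over a grid of 20 evenly spaced $\alpha$ values and
  picks the smallest grid point from which `lambda_min` stays stable
  (every later consecutive change below 5% in relative terms). The
  rationale: once the selected penalty stops moving, extra $\ell_1$ share
  buys no better-determined model, and the smallest stable $\alpha$ keeps
  the most ridge-style stability against correlated columns. If the
  profile never stabilizes the conventional 0.6 is used, with a warning.
  Routine fits use the fixed default because the grid search multiplies
  the cross-validation cost twenty-fold for a quantity that is stable
  across designs of this shape.

## Gene universe choices

Two universes are supported when building the design matrix.
`ppi_restricted` (default) keeps genes that are targeted by some miRNA
*and* appear in the protein network — the natural universe for the context
model, since a gene invisible to the protein network contributes no
indirect structure. `union` keeps every gene in any direct or indirect
set and is the appropriate baseline universe for `direct_only` matrices.
Both the regression and the ORA baseline always operate on the same
matrix universe, so their comparison is information-fair. miRNAs that lose
every in-universe target are dropped with a message; every retained row
and column has at least one nonzero.

## The ORA baseline

For each miRNA with $K$ in-universe (context or direct-only) targets, of
which $k$ fall in the signature's $m$ in-universe genes, the score is the
hypergeometric upper tail $P(X \ge k)$ with $X \sim
\mathrm{Hyper}(N, K, m)$ over the $N$-gene universe, computed with
`stats::phyper`. Ranking is by ascending $p$, ties by larger overlap, then
id. The baseline is deliberately given the same context-expanded target
sets as the regression, so any performance difference is attributable to
joint fitting, not to the network expansion.

## Association networks and evaluation

`batch_enrich()` fits one model per signature and emits an edge for every
nonzero coefficient. Thresholding to "highly significant" associations
keeps coefficients *strictly* greater than the cut (default 0.5); the
strictness matters at the boundary and is tested. Evaluation against a
gold standard reports `common`, `missed` and `novel` edge counts (which
satisfy `common + missed = |gold|` and `common + novel = |predicted|` by
construction) and an AUC computed as the Mann–Whitney statistic with ties
counting one half, over an explicit candidate space of signature–miRNA
pairs — by default all pairs of the network's signatures with the
supplied miRNA universe, with absent pairs scored 0. The candidate space
is configurable because no negative set is canonical for association
networks; the counts are reported pre-threshold so they describe the
model's raw edge set.

## The synthetic benchmark generator

Real inputs (TargetScan-style predictions, Reactome-style functional
interactions, transfection-derived gene lists, curated disease–miRNA
associations) are large external resources. The generator emulates all of
them with planted ground truth so every stage is testable offline:

* **Scale.** The `paper` preset matches the published scale of the real
  data: 305 miRNAs over 3,235 genes. The `small` preset (100 miRNAs,
  1,500 genes) is the documented testing scale.
* **PPI graph.** Erdős–Rényi by default (mean degree 8, a realistic
  functional-interaction density), or preferential attachment when a
  hubby degree distribution is wanted.
* **Targets.** Each miRNA draws 60–120 direct targets (so planted
  signatures of 60 direct genes always have a pool), sampled uniformly or
  with probability $\propto 1 + \texttt{hub\_bias}\cdot\mathrm{degree}$,
  reproducing the observed tendency of highly connected proteins to be
  targeted by more miRNAs.
* **Signatures.** A planted signature mimics a pre-miRNA transfection
  list: 60 genes from the planted miRNA's direct targets, 20 from its
  indirect partners, 20 unrelated noise genes (all without replacement).
* **Gold standards.** True association edges are corrupted with 30% false
  negatives and false positives added up to 130% of the true size,
  mirroring the roughly comparable sizes and partial overlap of predicted
  and curated association networks in practice.
* **Determinism.** Every stage derives its randomness from the scenario
  seed plus a fixed per-stage offset, so objects are independently
  reproducible and the command-line pipeline is byte-identical across
  runs with the same seed.

What the generator does **not** emulate: measurement noise in expression
space (signatures are exact gene sets), the modular/clustered topology of
real functional-interaction networks, overlapping miRNA families beyond
the explicit decoy construction (`add_decoy_mirna()`), and incomplete
target-prediction coverage. Passing the planted-recovery tests therefore
demonstrates that the machinery is correct and that the context signal is
identifiable under the stated conditions — not that any particular
recovery rate carries over to real transfection data.

## Test and benchmark problem sizes

The recovery properties are verified at the `small` scale: planted-miRNA
recovery and the family-decoy property over 50 seeded replicates each, the
context-versus-direct comparison (signatures drawn purely from indirect
targets) over 50 replicates, and the noise-degradation curve (median rank
non-improving across noise levels 0/20/120) over 12 replicates. Solver
correctness is checked against a high-precision proximal-gradient (FISTA)
solver of the identical objective on 20 random instances, against ridge
and least-squares closed forms, and against `glmnet` for the lasso case
($\alpha = 1$; for $0 < \alpha < 1$ glmnet's internal response
standardization rescales the ridge share of its penalty, so its solutions
answer a slightly different objective and are not used as an oracle
there).

## Numerical and degenerate-input conventions

* Gene symbols are uppercased once at the I/O boundary; miRNA identifiers
  are case-sensitive and kept verbatim (capitalization is meaningful in
  miRNA nomenclature).
* Duplicate edges, self-loops in the protein network and malformed lines
  are dropped with logged counts; empty parse results are hard errors.
* A signature with no universe overlap is a hard error; coverage below
  10% warns.
* One-hop expansion only: indirect means a protein partner of a direct
  target, never a longer path, and no diffusion weighting is applied.
* `soft_threshold`, `compute_lambda_max`, `lambda_path`, `make_folds` and
  `select_stable_alpha` are exported so each mechanism is independently
  testable.

## Known limitations

Symbol-level identity is assumed (no identifier mapping); the regression
family is squared-error on the 0/1 response, not logistic — consistent
with treating the membership vector as a numeric signal and required for
the penalty-path conventions above; and indirect influence is binary (a
partner either counts at weight $w$ or not at all), with no
edge-confidence weighting from source databases.
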