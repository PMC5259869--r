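---
title: "Detecting gene-miRNA co-modules by spectral relaxation of a combined modularity objective"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-miRNA co-modules by spectral relaxation of a combined modularity objective}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

MicroRNAs regulate messenger RNAs post-transcriptionally, and one miRNA can
touch dozens of genes while one gene answers to several miRNAs. Pairwise
target prediction misses this many-to-many structure. `comodule` instead
looks for *co-modules*: groups of genes and miRNAs that are densely
interconnected three ways at once — gene-gene coexpression, miRNA-miRNA
coexpression, and gene-miRNA links (coexpression plus experimentally
supported interactions). Such groups are candidates for coherent regulatory
programs, e.g. in tumour expression cohorts.

## Networks

Given a genes x samples matrix and a miRNAs x samples matrix over the same
samples, all three similarity matrices are Pearson correlations across
samples. Networks are binary, by hard thresholding: an edge exists iff
|r| > tau, with strict inequality (the convention matters — it changes edge
counts — and is tested). Within-type thresholds are guided by scale-free
topology: for each candidate tau we regress log10 f(d) on log10 d, where
f(d) is the raw count of nodes with degree exactly d (no log-binning,
zero-degree nodes excluded since their log is undefined), and accept the
smallest tau whose R^2 reaches `min_r2`. The acceptance level defaults to
0.8, a common scale-free-topology working value, and is an explicit
configuration knob because any single number here is a judgment call. The
gene-miRNA threshold is chosen differently, by rank-AUC (below).

The cross matrix C is the union of the thresholded gene-miRNA coexpression
network and the known-interaction list, with per-edge provenance
(`coexpression`, `known`, `both`). Known pairs whose identifiers are not in
the filtered networks are dropped with a logged count.

## The combined modularity objective and its relaxation

For one network with adjacency A and degree matrix D, the quality of an
assignment of nodes into K modules with indicator columns s_k is

  Psi = sum_k (s_k' (2A - D) s_k) / (s_k' s_k).

Each Rayleigh quotient is (twice the internal edge weight minus the total
degree) per member — a modularity-style score that rewards dense modules and
penalizes edges leaving them. For the integrated network the objective adds
the two within-type terms and a coupling term

  Psi(S_g, S_m) = Psi_g + Psi_m +
      lambda * sum_k s_gk' C s_mk / (||s_gk|| ||s_mk||),

where the normalization by the two column norms balances module sizes
across the two node types, and lambda weighs cross-network connectivity
against within-network modularity (default 1). When a module is empty on
one side the coupling term for it is defined as 0, the limit of the
normalized expression (the raw formula is 0/0 there).

Maximizing Psi over binary assignments is combinatorial. Normalizing each
indicator column to unit length and stacking gives columns of norm sqrt(2),
so the relaxed problem is

  max Tr(S~' L S~)  s.t.  S~' S~ = 2 I_K,
  L = L_w + lambda L_b,  L_w = diag(2A_g - D_g, 2A_m - D_m),
  L_b = [[0, C], [C', 0]].

`build_integrated_matrix()` returns this L (the toy case of two connected
genes, one isolated miRNA and full coupling gives the 3 x 3 matrix
[[-1,2,1],[2,-1,1],[1,1,0]], which the tests pin down). The scalar 2 in the
constraint only rescales the feasible frames, so the embedding uses plain
orthonormal eigenvectors of L; by the Ky Fan principle the relaxed optimum
equals twice the sum of the top-K eigenvalues of L. The test suite verifies
the containment this relies on by brute force: over random small networks,
every discrete assignment in which each module holds at least one gene and
one miRNA (exactly the assignments whose normalized indicators are feasible
for the relaxed problem) scores at most that bound. Assignments with empty
modules are *not* in the relaxed feasible set and the bound genuinely need
not hold for them — a two-gene network with one edge and everything in one
of two clusters is a counterexample — so the enumeration is restricted
accordingly.

Because L is indefinite (2A - D is not a graph Laplacian sign convention),
"top" means largest algebraic eigenvalues. Eigenvector signs are arbitrary;
they are canonicalized so each column's largest-magnitude entry is positive,
which keeps runs byte-reproducible.

## From embedding to modules

The relaxed solution T (nodes x K) is not an assignment. Following the
standard spectral clustering recipe, nodes are clustered by k-means on the
rows of T. Two details are deliberately fixed:

* **Row normalization.** k-means runs on rows scaled to unit norm by
  default (`normalize_rows = TRUE`, a config switch). The objective's
  normalized indicators live on directions, not magnitudes, and
  row-normalization is the standard multiway spectral practice; all-zero
  rows (nodes invisible to the top-K subspace) are left at zero.
* **Seeding.** `stats::kmeans` (Lloyd) is restarted 50 times from
  k-means++ style initializations under a caller-supplied seed, keeping
  the best within-cluster sum of squares. The restart count trades
  determinism-with-quality against time; 50 restarts on a few hundred
  nodes is cheap.

Pairwise co-membership evidence comes from `comodule_scores()`: rows of T
are unit-normalized to T~ and S = T~ T~' computed, so S_ij is the cosine
between the nodes' embedding directions, 1 for nodes certain to share a
module. S is invariant to orthogonal rotations within the eigenspace, which
the tests assert numerically.

Clusters are only reported as co-modules when they contain at least one
gene, at least one miRNA, and at least one edge of each of the three kinds
induced inside the cluster. An optional minimum-internal-density cutoff
exists nowhere: the filter is exactly this membership-and-connectivity
rule. Since the right K is unknown, detection is run over a K grid; modules
recurring across runs are near-duplicates, and any two modules overlapping
strictly more than `merge_overlap` (default 0.9) are replaced by their
union, iterated to a fixed point. The overlap denominator is the smaller
module (min), which makes merging symmetric and absorbs nested duplicates;
Jaccard is available as an alternative. A second merge pass changes
nothing, and an overlap of exactly 90% does not merge — both tested.

## Choosing the gene-miRNA threshold by rank-AUC

For each candidate tau, C is set to the gene-miRNA coexpression network at
that tau (the known interactions are *excluded* from C here: they are the
objects being ranked, and including them would score them by construction),
the embedding computed for each K in the grid, and all gene x miRNA pair
scores from S ranked. The statistic is

  AUC = (sum_i R_i - q(q+1)/2) / (p q),

with R_i the rank of the i-th known pair from the smallest score, q known
pairs and p non-known pairs. Ties receive average ranks, which makes the
formula exactly the Mann-Whitney probability that a known pair outranks a
non-known one with ties counting one half; the tests check this identity
against a literal pair-counting oracle on hundreds of random vectors,
ties included. "Non-known" means every network gene-miRNA pair not on the
known list. The tau with the highest mean AUC over the K grid wins, ties
going to the smaller tau (a sparser C perturbs the coexpression signal
less). `alternate_lambda_threshold()` extends this to a coordinate ascent
over (tau, lambda) grids; each accepted step is a grid argmax, so the mean
AUC trace is non-decreasing, which is asserted rather than assumed.

## Enrichment

Modules are scored against reference sets (genomic miRNA clusters, cancer
miRNA lists, any GMT collection) with the hypergeometric upper tail
P(X >= overlap), computed via `phyper` and verified exactly against the
counting formula for all small parameter combinations. Tests are run in
both directions (modules enriched by clusters, clusters enriched by
modules); only pairs with overlap at least `min_overlap` (default 3) are
tested, and the Bonferroni multiplier is the number of tests actually
performed — both choices logged, since the multiplier convention changes
adjusted p-values. The background universe defaults to the miRNAs present
in the integrated network, the conservative in-analysis choice; it is an
argument, not a constant, because enrichment p-values are meaningless
without an explicit universe. miRNA identifiers are matched after
lower-casing and stripping the species prefix, with arm suffixes
(-5p/-3p) collapsed only when an exact match fails, each fallback logged.

## The planted-data generator

`generate_planted_dataset()` emulates exactly the structure the method
assumes: per module one latent factor per sample; member genes and miRNAs
are `loading * factor + noise`; background features are independent
standard normal; known interactions are Bernoulli, dense within modules
and sparse elsewhere. Within-module correlations then concentrate around
loading^2 / (loading^2 + noise_sd^2) — about 0.74 at the default loading
0.85 and noise 0.5 — while all other correlations are centred at zero with
standard error about 1/sqrt(n_samples). The defaults (6 modules of 30
genes + 5 miRNAs, 50 + 20 background features, 200 samples, within rate
0.3, background rate 0.005, seed 11) keep the within/background separation
far above the 0.6 threshold noise floor, so module recovery is forced when
the implementation is correct — which is what makes recovery a usable
correctness test rather than a benchmark.

What the generator does *not* emulate: heteroscedastic platform noise,
batch effects, copy-number confounding, the heavy-tailed sparsity of real
miRNA counts, or biologically overlapping programs. Passing the planted
tests therefore demonstrates algorithmic correctness under the model's own
assumptions, not performance on tumour cohorts.

Recovery is scored by Adjusted Rand Index against the planted labels over
planted module members (label > 0). Background features are excluded from
the ARI on purpose: they are not part of the planted partition and the
method assigns every node *somewhere* — rejecting background is the
validity filter's job, which is scored separately by counting planted
modules matched by valid detected modules under bidirectional majority
overlap.

## Numerical choices and degenerate inputs

* Variance filtering uses the unbiased (n-1) sample variance; boundary
  ties break by input order, deterministically.
* Probe collapsing averages per sample over non-missing probes before
  gene-level imputation; since the two averaging steps do not commute in
  general, the order is configurable (`impute_before_collapse`).
* Constant expression rows have undefined correlations; they get
  correlation 0 with a logged warning instead of NA poison.
* A degree distribution with fewer than three distinct positive degrees
  has no meaningful scale-free fit and is an error; a flat distribution
  fits slope 0 with R^2 reported as 0 (no variance to explain).
* A disconnected integrated network is refused by
  `build_integrated_matrix()` with advice to split into components —
  silent splitting would make module labels across components arbitrary.
  `detect_comodules()` makes the choice explicit: by default it analyses
  the largest connected component (logged), or errors if asked.
* All randomness flows from user-supplied seeds; the pipeline derives the
  k-means seed for the run at module number K as `seed + K`, so runs are
  reproducible and different K runs are decorrelated.
* Eigen-decomposition uses `eigen(symmetric = TRUE)` (LAPACK); k-means
  Lloyd iterations are capped at 100, far beyond observed convergence at
  these sizes.

## Problem sizes used in the validation suite

The tests and the acceptance script run entirely on generated data chosen
to finish within minutes on one core while staying in the regime the
method targets: the full planted preset (230 genes + 50 miRNAs, 200
samples) for recovery and threshold selection; a 3-module miniature (30
genes + 9 miRNAs, 80 samples) for pipeline, determinism and equivariance
checks; 200 random integrated networks of up to 10 nodes for the
exhaustive relaxation-bound enumeration; graphs of 600-1000 nodes for the
degree-distribution discrimination; and all hypergeometric parameter
combinations up to a background of 25 for the exact enumeration.

## Known limitations

* Hard thresholding discards edge-weight information; the method does not
  implement soft (weighted) networks, mutual information, or partial
  correlations.
* Each node belongs to exactly one module per K run; overlap arises only
  across K runs before merging. Genuinely overlapping regulatory programs
  are out of model.
* K must be supplied (as a grid); there is no automatic model-order
  selection beyond the cross-run merging.
* The rank-AUC threshold selection is in-sample by design; it selects a
  representation, not a predictive model.
* At very large gene counts the all-pairs AUC grows as N_g x N_m; the
  implementation keeps this exact (no subsampling), which is fine to a
  few thousand genes but quadratic beyond.
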