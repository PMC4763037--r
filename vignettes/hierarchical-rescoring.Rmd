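---
title: "Hierarchical random graph rescoring of bootstrap network ensembles"
author: "hrgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical random graph rescoring of bootstrap network ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrgnet)
```

## The problem

Network-inference methods applied to gene-expression time series report
many false-positive regulations. When the same method is run on
bootstrap-resampled data it yields an ensemble of N~g~ networks, and the
fraction of networks containing a regulation — its bootstrap probability
p^B^ — is itself a useful confidence. `hrgnet` sharpens those confidences
with one extra piece of prior knowledge: biochemical networks are
hierarchically organized. A hierarchy consistent with *most* of the
ensemble is extracted, converted into per-pair edge probabilities, and
blended back into the confidence values.

## The hierarchical random graph

A hierarchy over N genes is a rooted, strictly binary dendrogram D with
the genes at its N leaves and N − 1 internal nodes, each carrying a
probability θ~i~. Any unordered pair of genes has a unique lowest common
ancestor (LCA) in D, and the model connects the pair with probability θ at
that node. The model is generative (`sampleNetwork()` draws networks from
it) and direction-blind: the hierarchy speaks about *interaction*, not
about which gene regulates which.

Because inferred regulations are directed and may include
auto-regulations, each ensemble member is first symmetrized: an undirected
edge {n, m} is present when either directed regulation is, and
self-regulations are dropped — the model has no LCA for a gene with
itself (`undirect()`).

Given the ensemble, the log-likelihood of a dendrogram factorizes over
internal nodes. Writing E~ij~ for the number of edges of member j whose
endpoints have node i as LCA, and L~i~, R~i~ for the two subtree leaf
counts,

$$\log L(D, \theta) = \sum_{j=1}^{N_g}\sum_{i=1}^{N-1}
  \big[E_{ij}\log\theta_i + (L_iR_i - E_{ij})\log(1-\theta_i)\big].$$

For fixed D the maximum-likelihood θ is closed-form,
$\hat\theta_i = \sum_j E_{ij} / (N_g L_i R_i)$, so θ is never a free search
variable. The package evaluates the likelihood from the aggregated counts
E~i~ = Σ~j~E~ij~ — algebraically identical to the double sum but O(N²)
instead of O(N²N~g~) — with the standard MLE convention 0·log 0 = 0, so a
perfectly consistent ensemble (every θ~i~ ∈ {0, 1}) has log-likelihood
exactly 0 and every other configuration is negative.

## Searching dendrogram space

The likelihood is maximized over tree shapes by simulated annealing:

* Start from a random dendrogram, built by grafting leaves one at a time
  onto uniformly chosen branches. This yields every one of the (2N−3)!!
  labeled shapes with equal probability; the distribution of the initial
  tree is a free choice, and the annealer is expected to erase it.
* At each proposal an internal node s is drawn uniformly. Its subtree root
  configuration (A, (B, C)) is rearranged by **Exchange** (swap the child
  A with grandchild B or C) or **Rotate** (regroup to ((A,B),C) or
  ((A,C),B)), each operator and variant chosen uniformly. On the local
  three-subtree configuration the two operators reach the same two
  alternative groupings; both are kept because they are the natural
  rooted-tree counterparts of nearest-neighbor interchange, and
  breadth-first closure of the move set provably reaches all 15 shapes at
  N = 4 and all 105 at N = 5 (this is a test). A node with two leaf
  children yields no rearrangement; such proposals are counted against the
  epoch budget and redrawn, keeping the iteration count as specified.
* A proposal with objective Obj~t~ replaces the current tree with
  probability min{1, exp(−(Obj~c~ − Obj~t~)/T)}; the best tree is replaced
  only on strict improvement.
* Temperature cools geometrically, T ← γT, with N~max~ proposals per
  epoch. Defaults: T~start~ = 1000, T~end~ = 0.1, γ = 0.99,
  N~max~ = 1000 N, i.e. about 916 epochs. The printed algorithm restarts
  each epoch from the best tree found so far, which is unusual for
  simulated annealing but implemented faithfully; `AnnealSchedule()` has a
  `restartFromBest` flag (default TRUE) for experimentation.

The annealer (compiled code, driven by R's RNG so a seed fixes the run
exactly) maintains node statistics incrementally: a move at node s changes
the leaf partition only at s and its pivot child, so one cross-block edge
count per proposal suffices. Statistics are recomputed from scratch at
every epoch boundary to prevent floating-point drift, and the suite checks
the incremental objective against an independent full recomputation. For
N ≤ 8, `exhaustiveSearch()` enumerates all (2N−3)!! shapes as an oracle;
with a reduced schedule (T: 10 → 0.1, γ = 0.9, 200 N proposals/epoch) the
annealer attains the enumerated optimum in essentially every run at
N ∈ {5, 6, 7} with N~g~ = 20.

Ties in the objective are real (the worked three-gene example has a 2-way
tie); the annealer keeps the first strict optimum it finds, and the
exhaustive oracle reports the whole tie set.

## Combining confidences

The fitted model gives p^H^(u, v) = θ at the pair's LCA, symmetric by
construction. The final confidence for the directed regulation of gene n
by gene m is the affine blend

$$p_{n,m} = \eta\, p^B_{n,m} + (1-\eta)\, p^H_{n,m},
  \qquad \eta = 1 - 1/N_g \text{ by default}.$$

Since p^B^ lives on the grid {0, 1/N~g~, …, 1}, the default η makes the
hierarchy a pure tie-breaker: η·(2/N~g~) > (1−η)·1 whenever N~g~ > 2, so
two regulations whose bootstrap probabilities differ by at least two grid
steps can never be reordered (property-tested exhaustively for
N~g~ ∈ {10, 100}). Self-regulations keep their p^B^ but are excluded from
ranking and evaluation, mirroring their removal before hierarchy
detection. Ties that remain in the *combined* value are broken
deterministically by p^B^, then regulator label, then target label — a
repository convention, as no canonical rule exists.

Matrices throughout are oriented `[target, regulator]`: entry [n, m] is
the regulation of gene n *by* gene m. Adjacency files follow the same
convention (row = target), which is worth double-checking when importing
external matrices.

## Synthetic data: what it emulates

The simulator reproduces the study protocol used to exercise the method:

* **Dynamics.** An S-system,
  $\mathrm{d}X_n/\mathrm{d}t = \alpha_n \prod_m X_m^{g_{n,m}} -
  \beta_n \prod_m X_m^{h_{n,m}}$, with α = β = 1, pure auto-degradation
  (h = I) and, for every regulation m → n of the target topology, a
  kinetic order g~n,m~ drawn uniformly from [−1, −0.5] ∪ [0.5, 1] (sign
  uniform). Kinetics are redrawn per trial.
* **Observations.** 100 experiment sets per dataset, each integrated from
  initial values uniform in [0, 2] and observed 11 times at 0.4 intervals
  (K = 1100 measurements per gene), then corrupted with 10% Gaussian
  noise.
* **Noise convention.** "10% Gaussian noise" is interpreted as
  multiplicative: noisy = clean·(1 + ε), ε ~ N(0, 0.1²), the common
  convention for relative measurement error in this literature; an
  `absoluteNoise` flag provides the additive alternative. Noisy values are
  floored at 10⁻⁶ so downstream log transforms stay finite.
* **Initial values.** A power law with negative exponent is singular at 0,
  so initial vectors are redrawn while any coordinate is below 10⁻³ — the
  protocol cannot have integrated from exact zeros.
* **Integration.** `deSolve::lsoda` with rtol 10⁻⁸/atol 10⁻¹⁰, chosen for
  robustness to the fast transients that occur when a state approaches 0
  under a negative kinetic order. Trajectories that leave the positive
  orthant or fail to integrate raise an error rather than being silently
  floored. The decoupled system is checked against its closed form
  1 + (X₀−1)e^(−t) to 10⁻⁶.

The generator does **not** emulate intrinsic (process) noise — the
S-system is deterministic between observations, by design — nor biological
replicate structure, unobserved regulators, or measurement-platform
artifacts. Passing tests on these data therefore demonstrate correctness
of the machinery and the directional value of the hierarchy under the
stated assumptions, not performance on real expression data.

For small end-to-end experiments `randomModularTopology()` supplies sparse
topologies with two modules (regulation probability 0.25 within, 0.02
between, ~1.1 regulations per gene at N = 10) — a stand-in for curated
benchmark topologies that preserves the clustered structure a hierarchy
can exploit.

## The inference stage

The bootstrap inference behind the ensemble is pluggable
(`registerInferenceMethod()`); any method that returns N~g~ directed
networks will do, and the published engine this package was designed to
complement is *not* re-implemented here. The bundled baseline resamples
whole experiment sets with replacement (preserving within-set dynamics),
estimates derivatives by central differences (one-sided at the ends), and
regresses each gene's derivative on the log-transformed expression of all
candidate regulators; a regulation enters a replicate's network when the
standardized coefficient magnitude exceeds a threshold (default 0.3,
giving sparse-but-imperfect networks at the scales used here). The log
transform linearizes the production term of the S-system near steady
state; it is a heuristic, not a claim about optimality. Prior-knowledge
masks (forbidden/forced ordered pairs) are enforced centrally, so every
registered method honors them.

## Evaluation conventions

Performance against a gold standard is measured on *directed* regulations
with self-regulations disregarded. The threshold sweeps over the distinct
confidence values, each tie block entering as a whole; recall = TP/(TP+FN)
and precision = TP/(TP+FP), with precision defined as 1 when nothing is
predicted. The area under the recall–precision curve (AURPC) uses
trapezoidal integration over recall, taking at each achieved recall the
best precision, extending the curve horizontally from the smallest
achieved positive recall down to recall 0, and assigning precision 0
beyond the largest achieved recall. The interpolation rule is a package
choice (the convention is not standardized); it is cross-checked against
an independent naive implementation to 10⁻⁶ and any comparison between
scorers uses the same rule, so relative statements are unaffected.

## Problem sizes and defaults used in the verification battery

The shipped tests and `scripts/acceptance.R` run the method at sizes where
the exhaustive oracle and many repetitions are comfortable: annealing vs
enumeration at N ∈ {5, 6, 7} with N~g~ = 20; planted-θ recovery on a
balanced 16-leaf hierarchy with θ ∈ {0.05, 0.9} and N~g~ = 100; and the
end-to-end comparison on 10-gene modular S-system networks with 20
experiment sets, N~g~ = 50 and 8 seeded trials, where the mean AURPC of
the hierarchy-combined confidences is compared against bootstrap-only
confidences. The expected improvement is small — the hierarchy mostly
reorders within bootstrap tie blocks — and that is the point: it adds
information without overruling the data.

## Known limitations

* The hierarchy is undirected; it cannot help decide the direction of a
  regulation, only its plausibility.
* Self-regulations are outside the model entirely.
* When no two regulations share a bootstrap probability, the default η
  leaves the ranking unchanged.
* Networks in which many genes are regulated by a single hub can mislead
  the hierarchy: spuriously co-inferred targets form erroneous clusters.
* The annealer returns a single optimum; posterior averaging over
  dendrograms is deliberately out of scope.
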