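---
title: "KATZSP: walk counting and similarity-space projection for lncRNA-disease inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{KATZSP: walk counting and similarity-space projection for lncRNA-disease inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(katzsp)
```

## The inference problem

The input is a bipartite graph: a Boolean matrix **LD** whose rows are
lncRNAs, whose columns are diseases, and whose ones are experimentally
supported associations. Such matrices are extremely sparse (published
collections run at roughly 1% density), so the modelling premise —
lncRNAs with similar functions tend to be associated with similar
diseases — has to be imported through side information. KATZSP does this
with four similarity layers, one heterogeneous network, one closed-form
walk count, and one refinement step. Every stage is deterministic; the
only stochastic component in this package is the synthetic benchmark
generator.

## Similarity layers

**Disease semantic similarity.** Diseases live in an ontology DAG. The
contribution of ancestor $t$ to disease $d_i$ is defined recursively:
$D_i(d_i) = 1$ and $D_i(t) = \max\{\Delta \cdot D_i(t')\}$ over children
$t'$ of $t$ inside $d_i$'s ancestor closure. The similarity of two
diseases is the mass of their shared ancestors relative to their total
masses. The decay $\Delta$ is dimensionless in $(0,1)$ with default 0.5;
larger values make distant ancestry count more. We compute contributions
by fixpoint relaxation of the child-to-parent edges, which is invariant
to edge order because `max` is associative and $\Delta < 1$ guarantees a
unique fixpoint.

Diseases absent from the ontology get an all-zero semantic row and
column, *including the diagonal*. This is deliberate: the integration
step (below) replaces zeros with GIP values, so a missing disease falls
back to its interaction profile everywhere, and the final diagonal is 1
through the GIP branch. Treating the missing diagonal as 1 instead would
leave a semantic "island" that never falls back.

**LncRNA functional similarity.** With $D(l_i)$ the disease set of
$l_i$, the similarity averages each disease's best semantic match in the
other set, normalized by $|D(l_i)| + |D(l_j)|$. Two conventions handle
degenerate inputs: an empty disease set yields 0 against every other
lncRNA (avoiding 0/0), and the diagonal is forced to 1 regardless. Both
are required by the cold-start protocol, which zeroes entire rows. The
printed definition of the one-sided best match carries an ambiguous
subscript in its source; we read it symmetrically, i.e. the max is taken
over the *other* lncRNA's disease set in both directions.

**GIP kernels.** $\exp(-\gamma \|p_i - p_j\|^2)$ on rows (lncRNAs) and
columns (diseases) of **LD**, with bandwidth $\gamma$ the reciprocal of
the mean squared profile norm. The kernel is undefined on an all-zero
matrix and the package refuses to compute it there.

**Integration.** Elementwise: keep the semantic/functional value where
it is nonzero, otherwise take the GIP value. The comparison is an exact
`!= 0`, not a tolerance: zeros in the base layers are structural (no
shared ancestor, no associations), never rounding artifacts.

## Walk counting

The heterogeneous adjacency is
$A = \begin{pmatrix} LL^{(f)} & LD \\ LD^T & DD^{(f)} \end{pmatrix}$,
symmetric by construction. The KATZ score sums all walks between two
nodes, a walk of length $w$ weighted $\beta^w$:
$S = (I - \beta A)^{-1} - I$, which converges iff
$\beta < 1/\lambda_{\max}(A)$. We parameterize $\beta = K/\lambda_{\max}$
with $K \in (0,1)$, default $K = 0.1$ — the value at which the LOOCV
sweep (`sweepK`, default grid 0.1–0.9 by 0.1) is reported to peak on the
published association collections.

Numerical choices:

* $\lambda_{\max}$ is computed on the symmetrized matrix
  $(A + A^T)/2$ to kill roundoff asymmetry; for this $A$ the eigenvalue
  bound and the spectral-norm bound coincide, and `selectBeta` asserts
  their agreement to 1e-8.
* $S$ is evaluated as the solve $(I - \beta A) S = \beta A$: one
  factorization, no explicit inverse, no subtraction of $I$ after
  inversion; identical to the closed form in exact arithmetic.
* Algebra is dense throughout. The published instances top out near
  1100 nodes, where a dense solve takes well under a second; a sparse
  path would buy nothing.
* The finite walk-length truncation $\sum_{w=1}^{m}\beta^w A^w$ exists
  in the test suite as an independent oracle, not as a user mode.

## Space projection

The primary block $LD^{(p)}$ (rows $1..nl$, columns $nl+1..nl+nd$ of
$S$) is refined by projecting similarity rows onto primary columns/rows,
normalized by the 2-norm of the projected-onto vector, and averaging the
two projections. A zero-norm column or row would divide by zero; the
convention is that all affected entries become 0. This matters in
practice only for the `SP` variant on sparse matrices, where empty
disease columns occur. Projections are exactly invariant to positive
rescaling of the primary scores (numerator and denominator scale
together), which the suite asserts.

Four scoring solutions are exposed. `KATZSP` (default) and `KATZ` are
defined above; `SP` applies the projections directly to the Boolean
**LD** (there is no KATZ stage to produce a primary matrix, so the raw
associations are the only sensible operand); `SPKATZ` is named but not
specified in the source literature, and we define it as the only
composition consistent with "projection first, then KATZ": the SP score
matrix replaces **LD** in the off-diagonal blocks of $A$, then KATZ runs
once and the primary block is returned. No intermediate matrix is ever
re-binarized or thresholded.

## Cross-validation conventions

Three conventions are undefined in the source literature and fixed here:

* **Negative pool.** The candidate set for every fold is the set of
  pairs unknown in the *full* dataset. The held-out positive is ranked
  against these within its own fold. This is the standard convention in
  this model family; it is also the only one that keeps the pool
  constant across folds.
* **Refolding.** GIP and functional similarities depend on **LD**, so
  honest LOOCV recomputes them inside every fold
  (`refoldSimilarities = TRUE`, the default). Semantic similarity is
  LD-independent and cached across folds. A fast mode
  (`refoldSimilarities = FALSE`) computes all layers once from the full
  matrix; it is optimistic and labelled as such.
* **Pooling.** Each fold yields the positive's Mann–Whitney percentile
  among its candidates (ties count half). The pooled AUC is the
  candidate-count-weighted mean of percentiles, and the pooled ROC is
  the weighted pointwise average of per-fold step/ramp curves — a
  construction whose trapezoidal area equals the weighted mean exactly,
  so the stored AUC, the ROC area and the rank-based estimate agree to
  machine precision by design, not by approximation. The per-fold rank
  table is returned so alternative poolings can be recomputed.

Fold computations are optimized: masking $(i,j)$ changes only lncRNA
$i$'s disease set, so only row/column $i$ of the functional matrix is
recomputed (GIP layers are recomputed in full — their bandwidth is
global). The suite proves the optimization exact against a naive
rebuild-everything oracle on a 6×6 toy.

Ranking ties anywhere in the package are broken by identifier in
C-locale (radix) order, so rankings are deterministic across platforms
and locales. Ranks in all user-facing output are 1-based; internal
indexing is R's native 1-based throughout.

## The synthetic benchmark

`generateDag` and `generateAssociations` plant recoverable structure:
lncRNAs and diseases are partitioned into aligned blocks; within-block
pairs carry association probability `withinDensity`, others
`backgroundDensity`; the ontology gives same-block diseases deep shared
ancestors (a branching tree per block under a common root) while
cross-block pairs share only the root. A planted-block design was chosen
over an Erdős–Rényi graph because the method's premise — similar
lncRNAs associate with similar diseases — is then true by construction,
which makes recovery a meaningful test of the machinery rather than of
luck.

The default configuration (40 lncRNAs × 50 diseases, 4 blocks, densities
0.5/0.005, DAG depth 3, branching 3) is the benchmark condition used by
the test suite and the acceptance script; it yields roughly 270
associations, comparable in density regime to the published collections
while small enough that a full refolded LOOCV takes about two seconds.
Equal within/background densities give the signal-free null used for
calibration. All generator stages draw from substreams derived from one
root seed, so outputs are pure functions of the configuration; the
substream structure (not the bitstreams) is documented so ports in other
languages can match the design.

What the generator does **not** emulate: real identifier vocabularies,
literature evidence fields, heavy-tailed degree distributions, ontology
depth heterogeneity, or annotation bias. Passing the planted-recovery
tests therefore demonstrates that the pipeline recovers block-structured
signal at realistic sparsity — not that real-data AUCs will match.

## Known limitations

* **Degree bias.** KATZ scores grow with node degree, so well-annotated
  lncRNAs and diseases are preferentially ranked. Under the signal-free
  null this bias can push pooled AUC visibly above 0.5 for draws with
  high degree variance, because held-out positives necessarily sit in
  rows with at least one association while the global candidate pool
  does not.
* **Cold-start asymmetry.** An isolated disease keeps its
  ontology-derived semantic similarity, which is association-independent,
  so the isolated-disease protocol recovers planted structure well. A
  fully new lncRNA retains *no* association-independent layer — its
  similarity row falls back to the GIP kernel of a zero profile, which
  depends only on the other entities' degrees — so nothing links it to
  any particular disease group and its cross-validated AUC hovers at
  (or, through the degree mechanics above, slightly below) chance on the
  planted benchmark. Bringing in an external lncRNA similarity (sequence
  or miRNA-interaction based) would break this asymmetry but is outside
  this package's scope.
* **MAT-v5 reading** covers dense numeric and logical 2-D arrays,
  uncompressed or zlib-compressed — enough for deposited association
  matrices; cells, structs, sparse and complex arrays are skipped.
* **No k-fold CV or bootstrap intervals**: evaluation follows the
  leave-one-out protocol exclusively, as in the model family this
  method belongs to.

## Session info

```{r}
sessionInfo()
```
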