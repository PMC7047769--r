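---
title: "Multiview consensus graph learning for lncRNA–disease association prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiview consensus graph learning for lncRNA–disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcglda)
```

## The problem and the modeling assumptions

Verified lncRNA–disease associations are sparse: catalogs at the scale
this package targets hold roughly 300–600 links over 100–300 lncRNAs and
150–250 diseases, i.e. about 1% of all pairs. The method implemented here
rests on two assumptions that are standard in this literature:

1. **Guilt by association** — functionally similar lncRNAs tend to be
   involved in semantically similar diseases, so similarity graphs on each
   side of the bipartite network carry predictive signal.
2. **No single similarity is reliable** — ontology-derived, kernel-based
   and cosine similarities each capture different, partially redundant
   structure, so the graph used for propagation should be *learned* from
   several views rather than fixed a priori.

The joint objective couples three groups of unknowns: row-stochastic
consensus graphs `SD` (diseases) and `SL` (lncRNAs), simplex-constrained
view weights, and the prediction matrix `F`. The Laplacian terms
`2α·Tr(F L_SD Fᵀ)` and `2β·Tr(Fᵀ L_SL F)` make predictions vary smoothly
over the learned graphs, while `‖F − Y‖²` anchors them to the known
labels, and the Frobenius misfit terms keep each consensus graph close to
the weighted combination of its input views.

## The similarity views

**Disease semantic similarity.** Each disease is located in a rooted DAG
(a MeSH-like hierarchy supplied as a parent→child edge list). A disease
contributes 1 to itself and each ancestor contributes `0.5^g` along the
best path `g` generations up (formally, the contribution of ancestor `t`
is `0.5 · max` over `t`'s children inside the ancestor closure). The
similarity of two diseases is the total contribution of shared ancestors
normalized by the sum of their semantic values, which lands in `[0, 1]`
and equals 1 on the diagonal. The 0.5 decay is a fixed constant of the
measure, not a tuning knob.

**lncRNA functional similarity** averages best-match semantic similarity
between the two associated disease sets in both directions, dividing by
the total set size. Inside cross-validation folds an lncRNA can lose all
of its associations; its off-diagonal simililarities are then defined as 0
(the `m + n = 0` guard), keeping the view valid without special-casing
downstream.

**GIP kernel.** `exp(−β‖IP(i) − IP(j)‖²)` over interaction profiles (rows
of `Y` for lncRNAs, columns for diseases), with
`β = bandwidth_scale / mean(‖IP‖²)`. `bandwidth_scale` defaults to 1, the
standard choice for interaction-profile kernels; it is exposed because
sparser networks can warrant wider kernels. Two all-zero profiles get
similarity 1 (the kernel is well defined there); only a fully empty
training matrix is an error, since the bandwidth denominator vanishes.

**Cosine similarity** of the same profiles, with zero-norm profiles
assigned 0 off-diagonal and 1 on the diagonal to avoid 0/0.

All views are symmetric, unit-diagonal and entrywise in `[0, 1]`, and all
Y-derived views are rebuilt from whatever matrix is passed in — this is
what makes leak-free cross-validation possible. The semantic view depends
only on the ontology, so evaluation code computes it once and shares it
across folds.

Diseases absent from the ontology are a hard error by default; a
permissive mode (`permissive_terms = TRUE`) instead gives them zero
semantic similarity to everything, which is the honest representation of
"no ontology information".

## The optimizer

`mcgl_fit()` follows an alternating scheme with nested loops:

* **Consensus graphs.** Given weights and `F`, each row of `SD` (and
  `SL`) is the Euclidean projection onto the probability simplex of the
  weighted-average view row minus `(α/2)·h_i`, where `h_i[j]` is the
  squared distance between prediction-matrix slices `i` and `j`. On the
  disease side the slices are *columns* of `F`, on the lncRNA side *rows*
  — the orientation is forced by dimensional analysis of the trace terms.
  The projection uses the exact sorting-based closed form; its output is
  checked in the tests against an exhaustive active-set QP oracle.
* **View weights.** The subproblem is a simplex-constrained least-squares
  fit of the column-stacked consensus graph to the column-stacked views.
  It is solved by projected gradient descent from the uniform weights with
  the exact Lipschitz step `1/σ_max(GᵀG)` (gradient `Gᵀ(Gw − a)` of
  `½‖a − Gw‖²`), iterated to a relative change of `1e-8` (cap 10 000).
  Starting from uniform weights makes duplicated views share weight
  deterministically instead of depending on solver internals.
* **Prediction matrix.** `F` solves the Sylvester equation
  `(2β L_SL + I)F + 2α F L_SD = Y` exactly via symmetric
  eigendecomposition of both operators and elementwise division in the
  joint eigenbasis. Every eigenvalue sum is at least 1, so the system is
  always well conditioned and needs no regularization; the residual is
  asserted below `1e-8` (relative Frobenius) in the tests.

`F` is initialized to `Y` — the only initialization consistent with the
`α = β = 0` limit, in which the model must return `F = Y` exactly — and
weights start uniform. The inner loop (graphs, then `F`) runs until the
relative objective change drops below `inner_tol = 1e-4` (cap 30); the
outer loop refreshes the weights and stops on the same criterion
(`outer_tol = 1e-4`, cap 50). Each block update solves its subproblem
exactly, so the recorded objective trace is non-increasing up to
`1e-8` relative slack — this is asserted on randomized instances. Update
order is fixed: disease graph, lncRNA graph, prediction matrix, then
weights. Nothing in the optimizer is stochastic.

`α` and `β` default to `1e-4`, where five-fold cross-validated accuracy
peaks on association data at this sparsity; `grid_search()` evaluates
alternatives over, e.g., `α ∈ [1e-4, 1]`, `β ∈ [1e-4, 10]`.

## Evaluation protocols

Three schemes are provided, all refitting the model per fold with views
rebuilt from the training matrix only:

* **LOOCV** holds out one association at a time. The pooled AUC compares
  each held-out positive (scored by its own refit) against all
  never-known pairs. The negatives are scored once under a single
  full-data fit: scoring them under every one of the hundreds of refits
  would multiply the cost by the positive count while changing negative
  scores only marginally (each refit differs from the full fit by a
  single matrix entry).
* **k-fold** (default `k = 5`, split seeded, seed recorded in the result)
  zeroes a fold of positives, refits, and scores that fold's positives
  plus all never-known pairs under the fold's model, pooling across folds.
* **Leave-one-disease-out** zeroes a disease's whole column and computes a
  per-disease AUC over that column; diseases with no positives — or no
  negatives — cannot be ranked and are excluded (the latter with a
  warning).

The negative pool is "all pairs never marked positive in the full
matrix"; training positives are never ranked. The AUC is the rank-based
(Mann–Whitney) statistic with midranks for ties. Every scheme accepts a
`fold_hook` called with each training matrix and held-out set, which the
test suite uses to audit that no held-out positive is present in any
matrix from which Y-derived views are built.

## The synthetic generator

`synthetic_config()` defaults emulate the largest catalog scale the
package targets: 285 lncRNAs × 226 diseases in 5 planted blocks, with
`density_in = 0.0442` and `density_out = 0.001` giving ≈621 expected
associations (matched block pairs: `12882·0.0442 + 51528·0.001 ≈ 621`).
Block assignment is round-robin so block sizes are reproducible. The
companion DAG gives each block its own ancestor chain of depth 4 under a
common root, and attaches each disease to one of the 3 deepest chain
levels — within-block diseases share deep ancestors, cross-block diseases
only the root, so the semantic view carries the planted signal. One
master seed drives everything; the ontology uses it directly and the
association draws use `seed + 1`, so either half can be regenerated
independently.

What the generator does **not** emulate: real MeSH identifiers and their
multi-parent tangles, degree heterogeneity (hub lncRNAs such as H19 or
MALAT1 with dozens of links), correlated curation biases, and disease
name irregularities. Passing tests on this generator therefore shows the
machinery is correct and that planted block structure is recoverable —
not that any particular accuracy carries over to a specific catalog
snapshot.

## Numerical choices and degenerate inputs

* Relative-change convergence tests use `max(|previous|, 1e-12)` in the
  denominator so a perfectly fit objective of zero terminates cleanly.
* Symmetry of Laplacian inputs is enforced to `1e-8`; profile-distance
  matrices are clipped at zero before `exp` to absorb round-off.
* Views are symmetrized (`(V + Vᵀ)/2`) and clipped to `[0, 1]` after
  floating-point assembly; diagonals are set to exactly 1.
* An lncRNA or disease losing every association inside a fold is handled
  by the zero-profile rules above rather than erroring, because this
  happens routinely at catalog sparsity.
* Non-finite values emerging from any block update abort the fit with an
  error naming the block.

## Known limitations

* **Leak-free accuracy at catalog sparsity is modest.** With views
  rebuilt per fold — the only evaluation this package considers valid —
  five-fold AUC on the default planted-block data is ≈0.59, far below
  what the same pipeline reports when views are (incorrectly) built from
  the full matrix (≈0.97 on the same fold). With ~2 links per lncRNA,
  removing a fold leaves many entities nearly cold, and one-hop
  propagation through the learned graphs rarely reaches the specific
  held-out disease. Published AUCs in this model family that approach
  0.9 under cross-validation are, in our experience, only reproducible
  when the similarity views retain the held-out links.
* **The weight update favors sparse views.** Because consensus-graph rows
  are simplex-projected (sum 1, few nonzeros), the Frobenius-nearest view
  is systematically the sparsest one (cosine), and dense informative
  views such as the ontology semantic view receive near-zero weight at
  convergence. This is a property of the objective, not of the solver:
  the weight subproblem is solved to global optimality (verified against
  a grid oracle). When two views are replaced by pure noise the weight
  does concentrate on the remaining informative view, so the mechanism
  guards against corrupted views more than it balances complementary
  ones.
* Default test and example problem sizes (20×15 unit tests, one 285×226
  fit plus a five-fold run in the end-to-end suite) are chosen to keep
  the full suite under a minute; all results quoted here are computed by
  that suite or by `scripts/acceptance.R`, not stored.
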