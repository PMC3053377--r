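---
title: "Methods: tethering-potential phenotype prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tethering-potential phenotype prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotether)
```

## The model and its assumptions

`phenotether` implements a one-hop weighted-neighbour vote on a functional
protein association network. The input is (a) an undirected network whose
edges carry integer confidence scores on the 0–999 scale, (b) a set of
*seed proteins* annotated with one or more of K phenotype categories, and
(c) optionally complex/pathway membership tables used only by the
separability analysis.

For a query protein p, the tethering potential to category j is the sum of
edge confidences between p and the seed proteins annotated with j. All K
categories are then ranked by descending potential. The method rests on a
single structural assumption: **phenotype assortativity** — interacting
proteins, being co-complex or co-pathway members, tend to share phenotypes.
The separability analysis makes the assumption inspectable: if complex or
pathway membership could not distinguish the categories (pairwise cosine
similarity of their membership vectors near 1), neighbour votes could not
either.

Deliberately, there is **no propagation beyond direct neighbours** — no
diffusion or random-walk smoothing. The score is a strictly local sum,
which keeps it interpretable (every point of score is one edge to one
annotated neighbour) and exactly reproducible by hand from a neighbour
table, as the shipped worked examples do.

## Parameters that matter

* `min_weight` (default **900**, dimensionless confidence): the edge
  filter is inclusive (score ≥ 900), the "highest-confidence" band of
  STRING-style networks. All headline numbers assume this cutoff; lowering
  it trades noise for coverage. Duplicate/reciprocal edge rows collapse to
  the maximum weight — idempotent for the usual symmetric listings.
* Weights stay on the raw **integer 0–999 scale**; potentials are exact
  integer sums, so rankings are free of floating-point ordering artifacts.
  (The API exposes them as doubles to permit generalized weights.)
* `seed` (tie RNG): runs of tied scores are permuted uniformly at random.
  The RNG is an explicit, seedable argument of every ranking function
  (default 1), so outputs are bit-reproducible; with no ties the ranking
  is RNG-independent.
* K (default 11, the budding-yeast phenotype classification exposed by
  `yeast_phenotype_scheme()`): any scheme with contiguous indices 1..K,
  K ≥ 2, works.
* Similarity `threshold` (default **0.5**): a category pair with cosine
  similarity above it counts as hard to discriminate.

## Degenerate inputs and numerical choices

* A query with **no annotated neighbour** has an all-zero score vector. It
  is flagged (`all_zero`), given a seeded uniformly random permutation,
  and — importantly — **kept in every evaluation denominator**, because
  the order-accuracy definition divides by the full seed-set size. Its
  point-prediction (`top_category()`) is `NA`, a signal distinct from any
  category.
* Self-interactions never count: networks store no self-loops, so a seed
  scoring itself (jackknife) contributes weight 0 automatically.
  Withholding the query's annotation row is therefore exactly equivalent
  to the zero-self-weight rule; the test suite asserts this equivalence.
* In the separability analysis, each category vector is the
  **component-wise sum** of its proteins' binary membership indicators.
  Cosine similarity is invariant to positive rescaling, so summing versus
  averaging is immaterial (tested); categories whose vector is all-zero
  (no membership information, e.g. a pathway analysis where one category
  lacks any annotated protein) are **dropped from the matrix** rather than
  carried as NaN rows.
* Proteins explicitly flagged `no annotation` in a membership table
  contribute zero vectors; protein identifiers are opaque, case-sensitive
  strings.

## The jackknife and its statistics

Each seed protein is scored in turn with its own annotation withheld
(leave-one-out). From one prediction map we derive:

* **A_i**, the i-th order accuracy: per cent of proteins whose rank-i
  category is a true phenotype. "Correct at order i" means membership of
  the rank-i category in the true label set; under this reading every true
  label occupies exactly one rank, so **Σ A_i = 100·M̄ exactly** (M̄ =
  mean phenotypes per protein) — an identity the tests assert on every
  run, tie randomization notwithstanding.
* **L(r)**: per cent of proteins whose whole label set fits in the top r
  ranks; non-decreasing with L(K) = 100 %.
* **Random baseline** 100·M̄/K. At M̄ = 1.7 and K = 11 this is 15.4545…,
  i.e. 15.5 at the 3 significant figures used for reporting (a printed
  15.4 arises from truncating 1.7/11 instead; we report the computed
  value).

Tie randomization makes A_i very weakly stochastic; `evaluate_predictor()`
takes the seed explicitly and a single pass is the default. No K-fold or
held-out splits are provided — with a voter set this small the jackknife
is the least biased protocol, and significance testing of accuracy
differences is out of scope.

## The knockout analysis

"Inactivating" an interactor is implemented as **full node deletion**
(node plus incident edges), the literal reading of removing a protein from
the network, rather than merely dropping its annotation; for a one-hop
score the two coincide for the query's ranking, but deletion also changes
other proteins' neighbourhoods and composes correctly with further
analyses. The query's own annotation is withheld in both the baseline and
knockout conditions, mirroring the jackknife under which baseline
predictions are produced. Removing a non-neighbour provably leaves the
query's scores untouched (tested as a locality property).

## What the synthetic generator emulates — and what it does not

`simulate_phenotype_network()` is a planted-label (stochastic block-ish)
generator: each node gets a primary category in equal blocks and, with
probability `multi_label_rate`, one extra random category (pleiotropy);
each node pair is connected with probability `p_in` when the nodes share a
label and `p_out` otherwise; weights are uniform on `weight_range`
(default 900–999, matching the highest-confidence band); a fraction of
nodes is stripped of labels to serve as prediction targets, their latent
labels still driving edge placement. Multi-label nodes connect under
`p_in` to *both* of their communities — the minimal mechanism that makes
L(r) saturate within roughly 2·M̄ ranks, as a pleiotropy-aware predictor
should.

Defaults are chosen to mirror the yeast study conditions at a size that
runs in seconds: K = 11 categories, 30 nodes per block (330 nodes),
`multi_label_rate` 0.7 so M̄ ≈ 1.7 phenotypes per protein,
`unlabeled_fraction` 0.1, `p_in` = 0.3, `p_out` = 0.01. The membership
generator gives each category a block of 3 synthetic complexes with a
configurable inter-category overlap probability (default 0.1), so
separability shrinks as overlap grows.

The generator does **not** attempt realism beyond label structure: degree
distributions are binomial rather than heavy-tailed, blocks are
equal-sized, edge weights are independent of topology, and annotation
error is absent. Passing tests on synthetic data therefore demonstrate
correctness of the algorithms and the expected response to assortativity,
not performance on a real interactome, where hubs, annotation bias and
incomplete networks all matter.

## Problem sizes and test design

The test suite runs entirely from code-generated data: brute-force oracle
equivalence of the tethering potential on 1,000 random graphs of ≤ 30
nodes; exact-sum and monotonicity identities on jackknife runs of
planted-label networks (typically K = 4–6, 30–60 nodes; the default
330-node condition for the headline statistics); a 20-seed exchangeable
null (p_in = p_out) confirming first-order accuracy matches the random
baseline within sampling error; and a 10,000-draw check that tied
categories reach rank 1 equally often. The full-scale yeast analysis needs
externally obtained tables (see `inst/extdata/realdata/README.txt`); the
corresponding tests check for those files and report their absence as a
failure rather than silently skipping.

## Known limitations

* One-hop scoring cannot reach proteins whose annotated partners are two
  or more steps away; such queries come out `all_zero`.
* Score magnitude scales with degree: hubs accumulate large potentials,
  and the method provides no degree normalization (by design — the score
  is a vote mass, not a probability).
* Activator/repressor sign is invisible to the network: proteins in one
  complex exerting opposite effects on a phenotype vote identically.
* Performance depends on seed-set coverage; sparsely annotated categories
  are hard to predict and rank low by construction.
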