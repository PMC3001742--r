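---
title: "Methods: signed bipartite disease–gene networks in dgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed bipartite disease-gene networks in dgnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnet)
```

## The model

`dgnet` analyses *signed bipartite networks* connecting diseases to genes.
An edge `(disease, gene, sign)` records that the gene is differentially
expressed in that disease, with `sign` ∈ {`up`, `down`}. The object
(`signed_bipartite`) stores the two node sets explicitly, so isolated
(degree-0) nodes are representable, and rejects self-inconsistent input:
an edge whose sign conflicts with an earlier copy, a repeated edge, or an
identifier used as both a disease and a gene.

Three structural regularities drive the analysis:

1. **Skewed gene degrees.** Most genes associate with one disease; a small
   core associates with many.
2. **Predominant down-regulation that increases with degree.** The
   proportion of `down` edges among genes of degree *k* rises with *k*.
3. **Within-gene concordance.** A multi-degree gene tends to carry the
   same sign on all of its edges.

## Synthetic data generator

`generate_network(default_generator_config())` produces a network that
emulates these regularities with 7 diseases and 747 genes. The generator
is *gene-anchored*: for each gene it draws

- a degree *k* from a categorical law on 1–5 with weights
  (.55, .25, .11, .06, .03) — a right-skewed distribution; the weights are
  a qualitative calibration, not a fit to any published histogram;
- *k* distinct diseases, without replacement, with probability
  proportional to attachment weights (3, 3, 3, 3, 1.5, 1.5, 1), so four
  diseases share many genes and one is small;
- a primary sign, `down` with probability `plogis(a + b*k)`, defaults
  `a = -2`, `b = 1.2` (so P(down | k=1) ≈ 0.31 and P(down | k=4) ≈ 0.85);
- per-edge signs: with probability `concordance` (default 1) every edge of
  the gene takes the primary sign; otherwise each edge resamples
  independently from the same logistic law.

What the generator does **not** emulate: gene identities, pathway
structure, disease–disease similarity beyond shared attachment weights,
or expression magnitudes — only the sign/topology regularities above.
The default seed is 20101111.

## Null models

Three randomization schemes, each preserving progressively more structure:

- `uniform_rewire()` — resamples the edge *set* uniformly from all
  `choose(D*G, E)` possibilities (via `sample.int(D*G, E)`) and permutes
  the sign multiset over it. Preserves node sets, |E|, and sign counts.
- `degree_preserving_rewire()` — checkerboard (2×2 swap) Markov chain on
  the biadjacency matrix, `swap_multiplier * |E|` attempted swaps
  (default multiplier 100, mixing checked by a two-sample
  Kolmogorov–Smirnov test at Q vs 2Q in the test suite). Preserves every
  node degree.
- `label_shuffle()` — permutes the sign labels over the fixed topology.

`null_ensemble()` derives an independent child seed per replicate
(`child_seed()`, a Lehmer mix exact in doubles), so ensembles are
reproducible and insensitive to statistic-internal RNG use.

## Statistics and tests

- `down_regulation_curve()` — proportion of `down` edges by gene degree;
  degrees with fewer than `min_genes_per_degree = 3` genes are excluded
  (a proportion over one or two genes is noise).
- `concordance()` — over genes of degree ≥ 2, the mean of
  `max(#up, #down) / k`.
- `degree_distribution_test()` — sample skewness (the moment estimator
  `g1`) of gene degrees vs. uniform rewiring, one-sided.
- `disease_down_test()` — number of diseases with a strict majority of
  `down` edges vs. degree-preserving rewiring; diseases with no edges are
  excluded with a message.
- `concordance_test()` — concordance vs. label shuffling.

All Monte-Carlo p-values use the add-one estimator
`p = (1 + #{null ≥ obs}) / (B + 1)`, which is never 0 and is exact for a
discrete exchangeable null. Its minimum is `1/(B+1)`.

## The curve envelope

`curve_envelope()` compares the observed curve against `B` (default 1000)
label-shuffled replicates, reporting per-degree equal-tail quantile bands
at `level` (default 0.999), strict outside flags, and two-sided add-one
p-values. Quantiles are inverse-ECDF (type 1): for B below `2/(1-level)`
the equal-tail quantiles degenerate to the null min/max, and the function
signals a classed warning (`dgnet_envelope_B`) so callers can either
raise `B` or acknowledge the wider band. At `level = 0.999` that
threshold is B = 2000, so the historically common B = 1000 warns.

Two numerical points about validity:

- The label-shuffle null conditions on topology and the sign multiset; it
  is exact (exchangeable) when edge signs are independent given topology.
  Under full within-gene concordance the observed per-degree proportions
  have roughly *k*-fold inflated variance relative to shuffles, so the
  envelope is anticonservative for such data — by design it asks "could
  this curve arise from random sign placement?", and concordant data are
  far from that null at every degree. The package's type-I validation
  therefore uses independent signs (`concordance = 0`, flat sign law).
- The label-shuffle path is computed by permuting the sign vector and
  tabulating by precomputed per-edge gene degree (`rowsum`), consuming
  the RNG stream identically to the generic ensemble route; the two
  routes agree exactly and are tested against each other.

`discordant_high_degree_genes()` lists genes of degree ≥ 4 whose edges
are majority-`up` — the against-the-trend cases worth inspecting.

## Layouts

`fr_layout()` is a Fruchterman–Reingold layout in 2 or 3 dimensions
(compiled, all-pairs repulsion): optimal distance
`kappa = C * (1/n)^(1/dims)` with `C = 0.9`, linear cooling
`t = t0 * (1 - it/iterations)` with `t0 = 0.1`, coordinates initialized
from R's RNG stream so `seed` governs determinism, and a final rescale to
the unit box (disable with `rescale = FALSE`; a connected pair then
settles at distance ≈ kappa, which the tests verify). Node radii scale
affinely with degree between `r_min` and `r_max`; edges colour yellow
(`up`) / blue (`down`). `centre_periphery_score()` is the Spearman
correlation between gene degree and distance from the disease centroid —
reliably negative on generated networks (high-degree genes are pulled to
the core), and more so in 3D, where the extra dimension separates the
hub region.

## File formats

`write_pajek()` / `read_pajek()` implement the Pajek `.net` format with
diseases listed first, 1-based indices, quoted labels, optional
coordinates at 6 decimal places, edge values 1 = `up` / 2 = `down`, and
the two-class partition either as a `.clu` sidecar or an inline
`*Partition` block. Write → read → write is byte-identical, and reader
errors cite original file line numbers. `write_edge_list()` /
`read_edge_list()` handle delimited files (comma or tab, auto-detected).

## Problem sizes and budgets

On the default 754-node / ~1300-edge network: a B = 1000 envelope runs in
well under a second (fast path), a 500-iteration 3D layout in ~1.3 s, and
the degree-preserving test (B = 1000 chains of 100·|E| swap attempts) in
a few seconds. The full pipeline (`run_pipeline()`) writes its outputs
byte-identically across reruns with the same configuration.
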