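---
title: "Summary trees from posterior samples: models, choices and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary trees from posterior samples: models, choices and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treesum)
```

## The data model

`treesum` represents a rooted ultrametric tree as a set of clades with
ages rather than as a node-and-edge structure. A `timeTree` over taxa
`L` holds a clade set that must (i) contain every singleton, (ii)
contain the root `L`, (iii) form a strict hierarchy — any two clades
nested or disjoint — and (iv) respect ages, a clade never being older
than a clade containing it. Tips are contemporaneous at age 0; trees
with dated tips are rejected at load, because every definition in the
package (branch intervals "as measured from the time of the tips",
coalescent densities, the taxa-partition construction) assumes
contemporaneous sampling.

The clade set view has two payoffs. First, clade matching across
thousands of posterior trees reduces to key equality (clades are keyed
by their sorted taxon indices, fixed when a `treeSample` is built), so
per-clade statistics can be pooled in one pass. Second, polytomies need
no special casing: a multifurcation is simply a clade set that omits
some internal clades, and a zero-length branch — which several summary
methods produce deliberately — encodes "present but not really
resolved". The error measures treat a zero-length clade as *not* called,
which is what makes the clades-missed count agree with half the
Robinson–Foulds distance on fully resolved trees.

```{r}
ta <- timeTree(c("a", "b", "c"), list(c("a", "b"), c("a", "b", "c")), c(1, 2))
ta
treeDistance(ta,
             timeTree(c("a", "b", "c"), list(c("a", "b"), c("a", "b", "c")),
                      c(0.5, 3)),
             "rbs")
```

## Two ambiguities we had to resolve

**Divergence times.** The divergence-time error sums, over the clades of
the scored tree, the difference between the clade's age and its mean
pair-split time. As literally written, the set of pairs splitting at a
clade is empty when that clade does not occur in the other tree, which
would make the definition vacuous off-topology. We adopt the only
reading consistent with its stated behaviour — the splitting pairs come
from the tree being scored and their split ages from the reference —
under which the heights and divergence errors coincide exactly for trees
of equal topology (a property the test suite checks on random
same-topology pairs) and diverge as topologies drift apart.

**The heights-only objective (HSO).** The "heights only" family is
named but not defined where it originates. We implement it as the
matched-clades term of the heights score alone — the sum of |h1 − h2|
over shared clades with *no* penalty for private clades — because that
is the only objective that is neither the full heights score nor the
per-clade median (MED): it still optimizes all ages jointly, but is
indifferent to clades absent from a posterior tree. This is a documented
interpretation, flagged here so users comparing against other
implementations know where results may differ.

## Topology selectors and their tie-breaks

All selectors return a *sampled* topology; nothing is searched outside
the sample. MCC maximizes the product of clade posterior frequencies,
CCD the product of split probabilities conditional on clade occurrence,
TCB the support mass of the tree's clades, HPF simply the topology
frequency. Two choices were open:

* **TCB combination.** "Total clade branch" reads additively, so a
  tree's TCB score is the *sum* of its clades' matched-branch totals; a
  product variant is available behind `combine = "product"` but off by
  default.
* **HPF tie-break.** Frequency ties are broken by the tree whose root
  height is closest to the posterior mean root height; we restrict the
  candidates to trees of the *tied topologies* (the alternative — all
  trees — is not distinguishable from the available description).

Every remaining tie in the package breaks to the lowest index, for
reproducibility.

## Height assignment

The per-clade mean/median rules (AVG/MED) estimate each clade age from
the posterior trees containing that clade. Because every clade uses a
different subset of trees, a child can be assigned an older age than its
parent. We return these assignments *flagged*, never silently repaired:
the negative branches are a real, known phenomenon of this estimator and
a user should see them. The drivers convert flagged assignments to trees
by clamping child ages to their parent (creating zero-length branches)
and warn.

CAT instead averages the MRCA age of each clade over **all** posterior
trees. Nesting of clades implies nesting of MRCAs in every tree, so any
monotone statistic of the MRCA ages (mean or median) yields a valid tree
by construction — this validity guarantee is exercised in the test suite
over a thousand randomized posteriors.

The majority-rule consensus keeps clades with frequency strictly above
0.5 (mutually compatible by the majority property). Its height rule is
not pinned down by its origin; we use CAT-style MRCA statistics over all
trees, again for guaranteed validity, with the matched-ages variant
behind a flag.

## Minimum-distance trees

For a fixed topology the candidate tree is encoded as
`z = (h_r, α_2, …, α_m)`: the root height plus, per non-root internal
clade in pre-order, the ratio of its age to its parent's age. Every
coordinate has a simple bound (`h_r ≥ 0`, `α ∈ [0, 1]`) and **every**
point within bounds decodes to a valid tree — the bounds are the
validity constraints — which makes the mean distance to the sample a
clean target for L-BFGS-B.

The mean distance is evaluated against a preprocessed `cladeIndex`: per
observed clade, sorted matched branch lengths, ages and interval
endpoints with prefix sums, plus sample-wide totals. Each evaluation
costs O(|C| log k) via binary search instead of O(|C|·k); the test suite
pins the indexed evaluation to a naive pairwise loop at 1e-9 on hundreds
of random tree/sample pairs.

Numerical choices:

* **Gradients.** Analytic throughout; at the kinks of the L1-type
  objectives (RBS/HS/RAS) we use the one-sided derivative from below.
  L-BFGS-B tolerates this in practice; a short Nelder–Mead polish after
  each descent cleans up what the quasi-Newton step cannot.
* **Initialization.** Each branch first gets its isolated optimum — the
  median (RBS/HS/RAS) or mean (SRBS) of its matched posterior branch
  lengths padded with zeros for trees lacking the clade — and ages are
  then assembled in post-order by averaging child age + child optimum,
  clamped from below by the oldest child so the start is always within
  bounds. Even-count medians resolve to the midpoint.
* **Restarts.** The L1 objectives have many local minima. Descents start
  from the initialization, from up to four sampled trees of the
  topology, and from seeded random points (3 by default).
* **Safety net.** The sampled trees themselves are always evaluated as
  candidates, so a minimum-distance tree is never worse than the best
  sampled tree — and on a concentrated (zero-noise) posterior the method
  returns the true tree *exactly*, because the comparison treats
  differences within floating-point noise as ties and prefers the
  earlier (sampled) candidate.
* **Degenerate input.** A sample in which every tree has height 0
  returns the zero-height tree directly.

The all-topology search (`mrbs` etc.) optimizes each distinct sampled
topology, most frequent first, capped at 1024 topologies (configurable,
with a warning on truncation).

## The taxa-partition tree

The TP construction orders the taxa, collects ages per inter-taxon
boundary, and only then rebuilds a topology. Three design points:

* **Ordering.** Agglomerative clustering on the mean MRCA-clade-size
  matrix; group distance is the mean of cross-pair distances; joins
  concatenate the two ordered groups in whichever of the four
  orientations minimizes the boundary-pair distance, ties resolving to
  the lexicographically smallest label sequence. The linkage and
  orientation rules are our choices — the source of the heuristic leaves
  them open — and are deterministic.
* **Compatibility rule.** A clade contributes its age to boundary `k`
  iff it occupies a contiguous block of order positions, its two
  children occupy contiguous sub-blocks, and `k` is *exactly* the
  boundary between them. The formal definition as printed elsewhere
  ("any k within the clade's span") over-generates; the boundary rule is
  forced by all three worked examples accompanying it, and our tests
  encode those examples verbatim.
* **Totality.** A boundary no clade contributes to falls back to the
  MRCA age of the two adjacent taxa over all trees (always defined), and
  is flagged. Because boundary estimates are independent, a
  sub-interval's maximum can exceed its parent's chosen age during
  reconstruction; children are clamped to the parent age and the clamp
  count reported in the `"clamped"` attribute. Ties at the maximal age
  go to the leftmost boundary.

## What the simulators emulate — and what they do not

`rCoalescentTree` draws genealogies from the Kingman coalescent with
constant population size: with `k` lineages the waiting time is
exponential with rate `k(k−1)/(2Ne)` and a uniform pair merges. Ages are
in population-size time units; multiplying by a mutation rate (default
0.005 substitutions/site/unit) expresses heights on the substitution
scale, giving mean root heights around 0.01–0.08 substitutions for the
default grid (n ∈ {8,…,128}, Ne ∈ {1,…,8}) — small, realistic
single-gene heights. `simulateJC` evolves an 800 bp alignment (default)
under Jukes–Cantor along the tree.

`pseudoPosterior` stands in for an actual MCMC run: each replicate
applies a Poisson number of age-preserving NNI moves and multiplicative
height noise in the ratio parametrization (lognormal on the root, logit
normal on the ratios), so every replicate is a valid tree and the
zero-noise limit reproduces the truth exactly. This emulates the
*spread* of a posterior, not its *shape*: real posteriors concentrate
mass by likelihood, correlate topology with ages, and mix burn-in
artifacts — none of which the generator reproduces. Passing tests
therefore demonstrate correctness of the summary machinery on controlled
spread, not end-to-end statistical performance on real MCMC output.

The ranking protocol (dense ranks per case, per-case normalization to
mean 0 / population variance 1, 4000 bootstrap resamples, dominance at
90% of resamples, scores chained as 1 + the best dominator) is
implemented exactly but exercised at reduced scale in the tests: the
simulation-comparison experiments in this package run with tens of test
cases, 8–128-tip trees only at the calibration step, and posterior sizes
of 10–200 trees. These sizes are the package's test design — large
enough to exercise every code path and pin the distributional
calibrations to closed forms at three standard errors, small enough to
run routinely.

## Known limitations

* Serially-sampled (dated-tip) trees are rejected; all definitions here
  assume contemporaneous tips.
* No search over unsampled topologies: every selector and
  minimum-distance method commits to topologies present in the sample.
* The optimizer offers no global-optimality guarantee for the L1-type
  objectives; the multi-start design and sampled-tree safety net bound
  the result by the best sampled tree but local minima can persist.
* The coalescent likelihood is evaluated at a supplied (true) population
  size; integrating over a population-size posterior is out of scope.
* NEXUS support covers trees blocks with translate tables (BEAST
  dialect, annotations ignored on read); data/characters blocks are not
  parsed.
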