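---
title: "Block models for correlation-based omics networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block models for correlation-based omics networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbmnet)
```

## The problem

Co-expression analysis turns an entity-by-sample abundance matrix (mRNAs,
proteins or metabolites measured over tumour or tissue samples) into a
network: every pair of entities is connected by an edge weighted with the
Spearman correlation of their measurements. Such networks are fully
connected and must be reduced before structural analysis. `sbmnet`
implements a complete reduction-and-modelling pipeline around the
microcanonical stochastic block model (SBM): blocks of entities with a
common connectivity pattern are inferred by minimizing a description
length, competing model variants are compared by posterior odds, and the
fitted model is reused to score every present or absent edge by how much
its removal or addition would change the description length.

## Correlation network and reduction

Spearman's rank correlation is used because it is invariant under monotone
transformations (e.g. the log transforms typical for sequencing and
mass-spectrometry data) and robust to outliers. Correlations and their
two-sided p-values (t approximation, `n - 2` degrees of freedom, midranks
for ties) are computed over pairwise-complete observations; pairs with
fewer than three shared samples, or a constant entity within the shared
window, are flagged undefined and never become edge candidates. Two
missing-value policies mirror common practice: log-of-zero sentinels are
replaced by a fixed low value (default -10), and entities with more than
`na_fraction_max` (default 20%) missing values are dropped; with 36
samples that tolerates 7 missing values and removes entities with 8.

Two hard-thresholding reductions are provided:

* **Significance of correlation.** Keep a pair iff its corrected p-value
  (Bonferroni or Benjamini-Hochberg, over all defined pairs) is below 0.01
  or 0.05. Among the four candidate settings, the one chosen maximizes the
  percentage of nodes in the largest connected component subject to an
  edge budget (default $10^7$), with ties broken toward the stricter
  setting.
* **Scale-free criterion.** Keep pairs with $|\rho| \ge t$ for the
  smallest $t$ on an ascending grid whose reduced network has a scale-free
  fit index above 0.85. The index is the $R^2$ of a $\log_{10}$ frequency
  versus $\log_{10}$ mean-degree regression over 10 equal-width bins of
  the positive degrees, set to 0 when the fitted slope is positive; each
  of these choices (bin count, base, empty-bin handling, slope-sign rule)
  is a function argument.

Both routes binarize: edge weights are discarded after reduction, and all
entities stay in the graph as nodes even at degree zero.

## The microcanonical SBM family

All probabilities are exact and assembled in bits (base-2 logs). With
$e = \{e_{rs}\}$ the block edge-count matrix ($e_{rr}$ twice the
within-block count — a convention enforced at the data-structure level so
that `rowSums(e)` is always the block degree sum), $n_r$ the block sizes,
$k$ the degree sequence, and $(2m)!! = 2^m m!$:

$$P(G\mid e,b) = \frac{\prod_{r<s} e_{rs}!\, \prod_r e_{rr}!!}
{\prod_r n_r^{e_r}\, \prod_{i<j} A_{ij}!\, \prod_i A_{ii}!!},\qquad
P(G\mid k,e,b) = \frac{\prod_{r<s} e_{rs}!\, \prod_r e_{rr}!!\, \prod_i k_i!}
{\prod_r e_r!\, \prod_{i<j} A_{ij}!\, \prod_i A_{ii}!!}.$$

The adjacency products are 1 on the simple graphs the pipeline produces,
but the package keeps the multigraph form so that the test suite can sum
each likelihood over exhaustive tiny ensembles and confirm it normalizes
to one; that normalization check is also what fixes the denominator of
the degree-corrected likelihood to $\prod_r e_r!$ (the double-factorial
variant does not normalize). The priors are
$P(e) = n_e^E / (n_e+1)^{E + B(B+1)/2}$ with $n_e = 2E/(B(B+1))$,
the three-stage partition prior
$P(b) = \frac{\prod_r n_r!}{N!}\binom{N-1}{B-1}^{-1}\frac1N$, and the
degree prior $P(k\mid e,b) = \prod_r \frac{\prod_k \eta_k^r!}{n_r!}
\prod_r q(e_r, n_r)^{-1}$ with $q(n,m)$ the number of partitions of $n$
into at most $m$ parts, computed by the standard recurrence in log space
and cached.

The nested (hierarchical) variants model $e$ with a further SBM per level.
The chain of conditional edge priors uses multiset coefficients,
$P(e_l \mid e_{l+1}, b_{l+1}) = \prod_{r<s}\binom{\!\!\binom{n_r n_s}{e^{l+1}_{rs}}\!\!}{}^{-1}
\prod_r \binom{\!\!\binom{n_r(n_r+1)/2}{e^{l+1}_{rr}/2}\!\!}{}^{-1}$, and
terminates at a single top block ($B_L = 1$, $P(b_L) = 1$) whose 1×1
matrix carries the flat edge prior at $B = 1$. This boundary choice makes
a one-level hierarchy with a single block coincide with the flat model's
edge prior exactly. Empty-graph conventions: $0^0 = 1$ in the edge prior
and $q(0, m) = 1$, the limits consistent with empty products.

The description length is $\mathrm{DL} = -\log_2 P(G\mid\lambda,b) -
\log_2 P(\lambda,b)$; under the microcanonical hard constraints the
parameters $\lambda = (e_l, k)$ are determined by $(G, b)$, so minimizing
DL maximizes the partition posterior. Variants are compared at their
minimum-DL partitions with the posterior odds
$\Lambda = 2^{-(\mathrm{DL}_1 - \mathrm{DL}_2)}$ under equal model priors.

## Search

Each restart draws its initial partition from the partition prior itself
($B$ uniform on $1..N$, sizes uniform among compositions, assignment
uniform given sizes) and then alternates two move types until a full pass
stops improving: single-unit moves, with candidate blocks taken from the
unit's neighbors plus one random block and a fresh block, and
agglomerative block merges, evaluated for all block pairs and applied
greedily. Acceptance is greedy by default (only DL-decreasing moves); a
Metropolis mode accepting with probability $\min(1, 2^{-\Delta DL})$ is
available. Move deltas are computed incrementally from the affected
blocks' terms; an optional audit recomputes the full description length
on a sampled subset of accepted moves and reports the largest deviation
(the suite requires $< 10^{-6}$ bits). Hierarchical variants seed the
level stack with the flat fit and sweep levels bottom-up under the full
nested DL, deepening while that lowers it (depth cap 10); upper-level
sweeps are cheap because they act on block counts, not nodes.

The number of restarts is the only parameter with a real compute cost.
The desk default is 10 (the production setting for networks of $10^4$
nodes is 500); the examples and checks in this package use 3-10 restarts
on graphs of 60-500 nodes, where the greedy search is already highly
reproducible.

## Edge confidence scores

At the fixed best partition $b^\ast$, the score of a single-edge
perturbation $\delta G$ is $\mathrm{DL}_{G,b^\ast} -
\mathrm{DL}_{G+\delta G,b^\ast}$ in bits: positive means the perturbation
improves the fit. Every existing edge is scored as putatively spurious;
absent pairs between degree-positive nodes are scored as putatively
missing up to a budget, ranked by $|\rho|$ when scoring everything is
infeasible. Degree-zero nodes are indistinguishable to the SBM within a
block, so one representative per (zero-class, target) pair is scored and
reported separately. For degree-corrected states the perturbed
description uses the updated degree sequence and degree prior. Scores are
relative confidence values — they are not normalized into probabilities,
and the natural threshold 0 is reported but deliberately not applied,
because removing edges tends to shrink the description of the model
itself and both score distributions shift accordingly. Validation
correlates scores with $|\rho|$, which the SBM never saw.

## Block characterization

Term overrepresentation per block uses the upper-tail hypergeometric test
with the network's entities as the universe, term-size filters (10-500
for gene-style annotations, minimum 2 for metabolite-style ones),
Benjamini-Hochberg adjustment across the tested terms of each block (the
scope is an argument), a q-value column carried as the BH-adjusted p (the
practical proxy; the cutoffs are raw p < 0.05 and q < 0.2), and a shuffle
null that permutes entity labels while keeping every level's block
structure fixed. Two tree distances on the annotation hierarchy — path
steps, and the level of the lowest common ancestor with leaves at level 1
and `level(t) = 1 + longest downward path` — feed within- versus
between-block comparisons by medians over term pairs (zero self-distances
omitted, single-term blocks skipped) with Welch's t-test; identical
degenerate lists give p = 1 by the t = 0 convention. An artificial root
joins all top-level terms so both measures are defined everywhere; for
terms with several parents the path measure uses the true shortest path
and the parent-term summary picks the lexicographically first top-level
ancestor, a deterministic tie-break. The parent-term summary counts a
term once per block it is overrepresented in, normalizes to the level's
total, and divides by the parent's share of all sub-terms in the
hierarchy, so a score above 1 flags a category appearing more often than
its size suggests.

## What the generators emulate

The expression generator plants co-expression modules with one shared
latent Gaussian factor per module: entity $i$ observes
$a f_j + \sqrt{1-a^2}\,\varepsilon_{ij}$, so same-module pairs have
Pearson correlation $a^2$, and the loading is calibrated through
$\rho_S = \tfrac{6}{\pi}\arcsin(\rho_P/2)$ so the *Spearman* correlation
hits the requested target (verified empirically in the tests). A fraction
of loadings is sign-flipped to plant anticorrelation without changing
$|\rho|$; missing values are injected completely at random or by
censoring the low end of the scale (the log-of-zero pattern). The graph
generator is microcanonical: without a degree sequence it places exactly
$e_{rs}$ edges uniformly among the distinct pairs of each block pair;
with one it stub-matches per block pair and repairs multi-/self-edges by
degree-preserving swaps within the same class, declaring the request
infeasible after a bounded number of repair sweeps ($10^4$). The
annotation generator builds a rooted tree of stated depth whose leaf
terms interpolate between the planted modules (alignment 1) and uniform
random sets (alignment 0), with same-module terms placed as siblings.

These generators reproduce the block-correlation structure, degree
heterogeneity, missingness and annotation alignment that the analysis
consumes — not count distributions, ratio chemistry or intensity
distributions of real platforms. Passing tests therefore demonstrate the
correctness and the qualitative behavior of the method, not performance
on any particular real data set.

## Study conditions used by the checks

The recovery experiments use 3 planted blocks of 20 nodes with
within-block density 0.6 and between-block density 0.12 (a 5× contrast),
20 seeds, 10 restarts; the level is set high enough that the planted
partition is, with high probability, the description-length optimum of
the sampled graph — the premise of an exact-recovery benchmark; at
weaker levels (e.g. 0.5 / 0.1) a sizable fraction of realizations have a
strictly shorter description under a partition that reassigns one node,
which the search correctly finds. Random-graph controls are G(60, 0.1),
10 seeds.
The degree-correction selection experiment plants half the nodes at
degree 2 and half at degree 12 per block with $e_{rr} = 80$, $e_{rs} =
30$ — strongly heterogeneous degrees while leaving the stub-matching
problem enough slack to mix. The end-to-end runs use 4 modules of 15
entities with heterogeneous Spearman targets (0.40, 0.55, 0.70, 0.85),
40 samples, 20% anticorrelated loadings, 5% missing cells, and 8 leaf
terms at full alignment. The heterogeneous module strengths matter: when
every module is equally and strongly co-expressed, the reduced network
degenerates into interchangeable near-cliques with virtually constant
edge $|\rho|$, and the score-versus-correlation pattern — which lives on
the spread of edge correlations and block densities — is drowned in
noise. Modules of varying strength, the realistic case, keep that spread
in the reduced network. These sizes keep a full run in seconds while
leaving all the qualitative contrasts (planted versus shuffled
annotation, within- versus between-block distances, sign of the
score-correlation pattern) far from their decision boundaries.

## Numerical choices and limitations

All model arithmetic is in log2 space via `lgamma`; no factorials are
formed, so description lengths remain finite up to at least $10^7$ edges.
The $q(n,m)$ table is filled by the exact recurrence with log-sum-exp and
cached across calls. Greedy moves accept only improvements beyond
$10^{-10}$ bits, which makes fits deterministic given the master seed
(every restart, shuffle and generator draw receives a seed derived from
it). Known limitations: the search is a point estimate — no averaging
over the partition posterior, as scoring all edges under sampled
partitions is deliberately out of scope; the correlation stage
materializes dense matrices only below a configurable entity cap (20,000)
and otherwise streams pairs to disk; and the hierarchical search explores
level stacks greedily, so very flat DL landscapes can return different
(equally short) hierarchies across seeds even when level 1 is stable.
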