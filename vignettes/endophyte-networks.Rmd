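---
title: "Analysing host-endophyte metabarcoding communities as bipartite networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing host-endophyte metabarcoding communities as bipartite networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endonet)
```

## The model

An ITS metabarcoding survey of foliar endophytes produces, after read
merging, filtering, chimera removal and 97% clustering, two things per
MOTU: a best reference hit (lineage, % identity, % coverage, score) and a
read count per host sample. `endonet` models the community downstream of
that point as an undirected, weighted bipartite network: host individuals
are the lower level (LL, matrix rows), fungal taxa the higher level (HL,
columns), and the cell `a_ij` is the read count of taxon *j* in host *i*.
Read counts are kept as raw integers: no rarefaction or compositional
transform is applied by default, because the index battery below is
either binary (computed on presence/absence) or built from interaction
*proportions*, which are invariant to uniform rescaling. Binarization and
per-cell z-scoring are available as explicit, user-invoked views.

## Taxonomic resolution from percent identity

The resolution of a MOTU's assignment is capped by the identity of its
best hit. The bundled default intervals are

| identity | rank |
|---|---|
| [97, 100] | genus |
| [95, 97) | family |
| [90, 95) | order |
| [85, 90) | class |
| (80, 85) | phylum |
| [0, 80] | kingdom |

Two conventions needed fixing where interval prose is inherently
ambiguous. First, every interval is closed at its lower bound *except*
phylum: an identity of exactly 80 falls to kingdom, honouring the
explicit "less than or equal to 80" reading, while 85.0 is class and
84.999 phylum. Second, no coverage threshold is part of the rule set
itself, but surveys in practice never trust hits covering much less than
the query; every assignment in the reference survey this package is
benchmarked against has coverage >= 90, so the default minimum-coverage
gate is 90% (configurable, and echoed in every report). A best hit below
the gate leaves the MOTU `"unassigned"` with an all-`"Undefined"`
lineage.

Best-hit selection is deterministic: maximal score, then higher
identity, then higher coverage, then the lexicographically smallest
lineage string, so classification is invariant to row order.

Benchmarking note: of the 44 published assignments in the reference
survey, 38 are internally consistent with these intervals and are
reproduced exactly by the rule engine. Six are not (identities 95.25,
96.90, 95.67, 96.95, 96.98 printed at phylum/genus/order/genus/genus
resolution, and 85.68 printed at family), presumably reflecting the
"extensive manual curation" such surveys apply after the automatic step.
The package implements the rules as stated and does not replicate those
six rows.

## The index battery

All entropies are natural-log Shannon entropies `H` of a normalized
non-negative vector, with `0·log 0 = 0`. Effective numbers `exp(H)` are
invariant to the logarithm base, which is why no base option is exposed:
every reported index is either entropy-free or built from effective
numbers and entropy *ratios*, where the base cancels.

**Binary structure.** Connectance `L/(I·J)`; web asymmetry
`(J−I)/(J+I)`; links per taxon `L/(I+J)`. NODF scores, for every ordered
same-level pair with strictly decreasing fill `f_u > f_v`, the paired
overlap `100·|shared partners|/f_v` (equal fills score 0), averaged over
all `I(I−1)/2 + J(J−1)/2` pairs. The weighted NODF analogue replaces
fills with marginal totals and overlap with the count of partners where
the poorer node's weight is positive but strictly below the richer
node's.

**Quantitative structure.** Bersier's linkage density
`LD = ½[Σ_j (c_j/m)·n_j + Σ_i (r_i/m)·n_i]` weights each node's
effective partner number `n_x = exp(H_x)` by its share of the total;
weighted connectance is `LD/(I+J)`, an identity the test suite asserts
on every matrix it touches. H2' standardizes the two-dimensional
interaction entropy `H2 = −Σ p_ij log p_ij` between its
marginal-constrained extremes: `H2max` is the entropy of the
independence surface `r_i c_j/m²`, and `H2min` the entropy of a
maximally packed allocation found by a deterministic greedy rule —
repeatedly place `min(remaining r_i, remaining c_j)` into the cell with
the largest remaining marginal product, first index winning ties. Exact
integer minimization is combinatorial; the greedy packing is verified
against exhaustive enumeration on small marginals in the tests, and the
resulting `H2' = (H2max − H2)/(H2max − H2min)` is clipped to [0, 1].
Degenerate inputs (1×1 matrices, or marginals for which the extremes
coincide, e.g. a single row) return 0 with a warning rather than 0/0.

**Same-level pairwise indices.** The C-score averages the checkerboard
unit `(r_u − S)(r_v − S)/(r_u·r_v)` over unordered same-level pairs;
the per-pair denominator bounds each unit in [0, 1], a normalization
convention chosen here and stated because several variants circulate.
Horn's information-theoretic overlap is used for niche overlap (not the
Morisita–Horn index that some packages substitute): proportional weight
vectors score 1, disjoint supports 0. Mean shared partners is the plain
average of pairwise partner overlap; note that its level means are fully
determined by the *opposite* level's degree sequence
(`Σ choose(d, 2)` over opposite-level nodes, divided by the pair count),
which is why the reference fixture reproduces the survey's published
values for it exactly.

**Node-level indices.** Species strength sums each partner's
proportional dependence on the focal node and therefore conserves
exactly: strengths over a level sum to the opposite level's size, a
property the tests assert in exact arithmetic. Proportional generality
divides a node's effective partners by the effective number of
*available* partners — `exp(H)` of the opposite level's weighted
marginal distribution. The weighted-marginal (rather than
partner-count) denominator is adopted because it makes all degree-1
nodes of a level share one value, the pattern the reference survey's
node table displays. Weighted betweenness is computed on the bipartite
graph itself (not a one-mode projection) with edge length `1/a_ij`, by
exact Brandes accumulation with fractional credit over equal-length
shortest paths and endpoints excluded (via igraph); within each level,
scores are divided by the level total. Both choices — bipartite graph
and share-of-level normalization — are adopted because they reproduce
the sum-to-one pattern of the nonzero published values per level. A
level with no intermediary nodes reports all zeros, so per-level sums
are exactly 0 or 1.

## Barber modularity and the annealing schedule

`Q = (1/m) Σ_ij [B_ij − k_i d_j/m] δ(g_i, g_j)` is computed on the
binary matrix by default — the convention of the classic annealing-based
modularity programs — with a flag for weighted cells. The optimizer is
simulated annealing from the all-singletons partition with three move
kinds: single-node reassignment (80%, including moves into an empty
module), module merge (10%) and module split (10%). Moves are accepted
when they improve `Q` and otherwise with probability `exp(ΔQ/T)`;
temperature cools geometrically, `T ← c·T`. Since no schedule is
canonical, the defaults are `T0 = 1`, `c = 0.95`, `100·(I+J)` proposals
per temperature, stopping below `10⁻⁴`; every parameter is configurable
and echoed, with the seed, in the report. `ΔQ` is computed
incrementally from per-module partial sums, so a proposal costs O(level
size), and the best-seen partition is returned (non-convergence is not
an error). Determinism is part of the contract: one seed, one
partition. On planted three-module 15×15 communities (within-module
link probability 0.9, between 0.05) the annealer recovers the truth at
NMI ≥ 0.9 in at least 9 of 10 seeds; the recovery test uses a shortened
schedule (`c = 0.9`, `20·(I+J)` proposals per temperature, floor 10⁻³),
which already saturates recovery on problems of that size.

## Guild annotation

Trophic modes and guilds come from a local TSV snapshot in the FunGuild
key–rank–modes–guild layout; no external service is queried, and
manually literature-curated taxa are simply extra rows in the same
file. Matching is rank-descending — genus, family, order, class, phylum
— and the first match wins, the most-specific-entry convention of
guild databases. Mode strings tolerate en/em dashes and the spelling
variants that circulate in published tables ("Pathothroph",
"Saprothroph"), normalizing with a message; unknown tokens reject the
row with a warning rather than silently mis-binning. The bundled
snapshot covers the 44 taxa of the reference myrtle survey and is also
the fixture for the partition tests: 16/44 taxa (36%) carry
pathotrophy, and exactly one is exclusively symbiotrophic.

## What the synthetic generator does and does not emulate

`gen_matrix()` plants one of three link structures — modular blocks
(`p_in`/`p_out`), exponentially decaying nested fill, or uniform random
— and weights realized links with `ceiling(rlnorm(meanlog = 3,
sdlog = 1.5))`, a right-skewed integer read-count distribution of the
kind metabarcoding abundance tables show (median ≈ 20 reads per link,
occasional links in the thousands); rounding *up* guarantees every
sampled link keeps at least one read, so the planted link count
survives weighting. `gen_hits()` produces per-(sample, taxon) best-hit
rows with normally distributed identities clipped to [0, 100], which
lets the rank rules be exercised at and across every interval boundary.

`gen_study_fixture()` deserves a caveat in bold: it realizes the
**degree sequences** of the reference survey (11 hosts, 45 taxa, 94
links) through a deterministic greedy Havel–Hakimi-style construction,
then weights links log-normally. Degree-determined quantities —
connectance, web asymmetry, links per taxon, normalized degrees, the
shared-partner means — therefore match the survey exactly, and that is
all the fixture claims: the underlying count matrix is unpublished, so
weighted indices computed on the fixture (H2', linkage density, NODF,
niche overlap, modularity Q) describe the synthetic realization only.
Passing tests on this fixture demonstrate correctness of the formulas
and of the degree-forced structure, not reproduction of the survey's
weighted values. Likewise none of the generators emulate read-level
artefacts — PCR bias, chimeras, tag switching — because the package's
scope starts after clustering.

## Numerical choices and degenerate inputs

* Ties everywhere are broken by first index (greedy packing, best-hit
  lineage ordering, degree realization), making every code path
  reproducible without hidden ordering dependence.
* NODF/WNODF pairs with an empty poorer node contribute 0 (no overlap
  is possible); single-node levels make the pair denominator 0 and
  return `NA` with a warning.
* `zscore_cells()` uses the population standard deviation over positive
  cells only and returns `NA` for non-links; an all-equal-weights
  matrix z-scores to 0 with a warning.
* C-score and species strength refuse zero-degree nodes: prune first
  (`prune_empty()` logs what it drops and never changes totals or link
  counts).
* All randomness is locally seeded and the caller's RNG stream is
  restored afterwards.

## Problem sizes in the test suite

The oracle-equivalence sweep checks NODF, weighted NODF, C-score,
shared partners and Barber Q against literal nested-loop oracles on
*every* binary matrix of every shape up to 4×4 (~70k matrices) plus 100
random count matrices; exhaustive `H2min` enumeration runs on 3×3
marginals with totals ≤ 7; the exhaustive modularity check enumerates
all 203 partitions of a 3×3 toy and all ≤4-module partitions of a 5+5
toy; annealing recovery uses ten 15×15 seeds. These sizes keep the
whole suite to a few minutes while leaving no behaviour of the small-n
combinatorics untested.

## Known limitations

* H2min uses the greedy packing heuristic; on adversarial marginals the
  true integer minimum can be lower, which would shrink (never inflate)
  the denominator and slightly inflate H2'. The tests bound this on
  small cases only.
* The annealer guarantees the best partition *seen*, not the global
  optimum; for networks much larger than a few hundred nodes the
  default schedule should be lengthened.
* Nestedness temperature, interaction strength asymmetry, weighted
  cluster coefficients and null-model significance testing are out of
  scope, as are rarefaction and compositional normalization.
* Guild assignment is only as good as the local snapshot; per-entry
  confidence levels ("probable"/"possible") are not modelled.
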