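---
title: "Grouping health-care facilities by community utilization patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grouping health-care facilities by community utilization patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgclust)
```

## The problem

Community-based capacity planning — most prominently state Certificate-of-Need
programs that regulate inpatient bed supply — needs allocation units larger
than a single hospital: groups of facilities serving a common set of
communities. Historically such groupings were produced by watershed-style
rules on service-area overlap plus expert-panel adjustment, which is hard to
reproduce and easy to gerrymander. `hgclust` implements an alternative that
is deterministic end to end and uses only two inputs a state routinely
holds: an origin–destination table of patient days (facility × areal unit)
and an inter-facility travel-distance matrix.

## The model

**Similarity.** A facility's community footprint is its Commitment Index
profile: $CI_{ij} = Pd_{ij}/Pd_i$, the fraction of facility $i$'s total
patient days drawn from areal unit $j$. Rows sum to one, so the profile is
insensitive to facility size — two hospitals of very different bed counts
drawing the same *proportions* from the same communities have nearly
identical profiles. The complementary Relevance Index
$RI_{ij} = Pd_{ij}/Pd_j$ (the unit's dependence on the facility) is provided
for diagnostics but deliberately not used for clustering: it is dominated by
facility size and describes the community's behavior rather than the
facility's. Units with zero recorded patient days get an all-zero RI column
rather than NaN.

**Location.** Geography enters as each facility's row of the distance
matrix, rescaled to $[0,1]$ by the maximum pairwise distance. The
$n$-dimensional representation is used instead of x,y coordinates because
travel distance (road network, shorelines) need not be Euclidean in the
plane; the pipeline consumes any valid symmetric matrix. The two blocks are
joined into an $n \times (z+n)$ feature matrix. Both blocks already live on
$[0,1]$; no further standardization is applied, so the implicit weighting
between blocks is their column counts. A scalar `distance_weight` on the
distance block is exposed for sensitivity analysis (default 1).

**Clustering.** For every $K$ from 2 to $n-1$ the feature matrix is
partitioned by a 2-step algorithm: Ward's minimum-variance agglomeration
(`hclust`, `ward.D2` linkage — the canonical minimum-variance form; the
older convention of running `ward.D` on squared distances produces the same
merge order) is cut at $K$, and its group means seed a K-means refinement
of the SSE objective $J(C)=\sum_k\sum_{x_i \in c_k}\lVert x_i-\mu_k\rVert^2$.
Seeding removes the randomness of conventional K-means initialization — for
50 groups of 158 observations there are roughly $K^N/K! \approx 9\times10^{203}$
possible assignments, and random starts essentially never repeat a
solution — so the whole pipeline is a deterministic function of its inputs.
The refinement is a Lloyd descent rather than a wrapper around an existing
K-means routine because its contract matters downstream: ties in nearest-center
assignment break to the lowest group index, a cluster emptied during
reassignment is re-seeded with the point farthest from its current center
(preserving $K$, recorded in the solution metadata), convergence is declared
at a relative SSE change below $10^{-10}$ (capped at 1000 iterations, an
error afterwards), and the refined RSS never exceeds the seed partition's.
The test suite cross-checks the descent against `stats::kmeans` (Lloyd) and
against exhaustive minimum-SSE search on small fixtures.

**Choosing K.** No statistic answers "how many clusters?" definitively, so
the package uses a two-part heuristic. The incremental F statistic
$$\mathrm{incF}_K=\frac{R^2_K-R^2_{K-1}}{(1-R^2_K)/(n-(K-1))},\qquad R^2=1-\mathrm{RSS/TSS},$$
computed on the consecutive grid (with the analytically forced $K=1$
reference, $R^2=0$), measures the fit gained by one more group against the
residual variance per remaining degree of freedom. Candidate solutions are
the *strict* local maxima ($\mathrm{incF}_K$ greater than both neighbors;
plateaus and grid endpoints are ineligible, which is why $K=2$ can never be
a candidate even though incF is defined there). Grid points with $R^2=1$
have undefined incF and are excluded rather than clamped. Decision rules
then encode planning constraints: (1) drop candidates whose largest group
exceeds `max_group_size` (default 20) *underlying* facilities, (2) keep
candidates with the fewest single-facility groups, (3) take the largest
surviving $K$. Group sizes and single-facility counts are computed through
`member_count`, so an observation formed by merging tandem-reporting
facilities counts all its members toward size and is never a
"single-facility" group. The rules are plain data (`selection_rules()`) and
should be adapted to the application; if nothing survives the size rule the
fit stops with an explicit error rather than silently relaxing it. On the
bundled statewide candidate table (`michigan_candidates()`, 52 candidates)
the defaults remove everything below 29 groups, keep the SH = 1 candidates
{29, 31, 33} and select K = 33.

**New facilities.** A proposed facility has no utilization history, so it
is placed by geography alone: its distance vector, rescaled by the
*original* $d_{\max}$ (entries may exceed 1 and are flagged, not clipped),
is compared with the distance-block columns of each group center and the
nearest center (Euclidean $d$) wins; ties break to the lowest group index.
Permuting the utilization block of the centers provably cannot change the
answer. No re-clustering is performed — assignment is a lookup against the
existing solution.

**Comparison statistics.** `fit_stats()` scores any external partition of
the same facilities (RSS/TSS/$R^2$), and `pseudo_f()` implements the
Calinski–Harabasz form $F=(R^2/(K-1))/((1-R^2)/(n-K))$, which penalizes
group count and so compares partitions with different $K$ more fairly than
$R^2$ (a single-facility group buys perfect fit for free). With the rounded
statewide $R^2=0.971$, $K=33$, $n=158$ this form reproduces the published
$F=131.75$ to within 1%; the exact degrees-of-freedom convention behind the
printed value cannot be pinned down without the unrounded $R^2$.
`solution_agreement()` compares two solutions (e.g. fitted on disjoint time
periods) restricted to their common facilities; groups are paired by
maximum-weight bipartite matching on shared-member counts — the least
assumptive reading of "agreement" between two partitions, since greedy
pairing understates it — and the report gives the matched-agreement
percentage and the number of exactly matching groups.

## The synthetic-data generator

Real statewide discharge databases are confidential, so the package ships a
generator of regions with planted service communities
(`generate_region()`). Community centers sit on a ring with adjacent
centers `community_spacing` apart; facilities and areal units scatter
around their center (`scatter_sd`); facility attractiveness (bed count) is
log-normal; each unit's total patient days is Poisson and allocated across
facilities by a multinomial with gravity probabilities
$p(i\mid j)\propto S_i^{\alpha} e^{-\beta d_{ij}} \gamma^{[\text{same community}]}$.

Defaults — 5 communities 60 km apart, 3 facilities and 6 units per
community with 8 km scatter, median 150-bed facilities
(`meanlog = log(150)`, `sdlog = 0.7`), $\alpha=1$, $\beta=0.15$/km,
$\gamma=3$, 2000 patient days per unit — describe a region with pronounced
community structure: at 60 km the decay factor is $e^{-9}\approx10^{-4}$,
so cross-community flows are rare but present, the regime regional planning
units are meant to capture. Exponential decay was chosen for the flow
kernel for its single interpretable rate parameter; the pipeline itself is
agnostic to the flow model. Distances are Euclidean on the generated plane
— the road-network argument for the real data is a data-collection concern,
not an algorithmic one.

What passing tests on this generator do show: the full pipeline (features →
sweep → selection) recovers planted community structure (adjusted Rand
index ≥ 0.9 in ≥ 90% of 20 replicates at the default configuration, and in
practice exactly 1.0), the Ward seed dominates random initialization, and
every invariant (row-stochastic CI, descent, determinism) holds on sampled
data. What they do not show: performance on real utilization data, whose
communities overlap far more, whose OD matrices are sparser and larger, and
whose travel distances are non-Euclidean. The null configuration used in
the tests removes *both* flow structure ($\alpha=\beta=0$, $\gamma=1$) and
geographic structure (scatter ≫ spacing); with geographic structure left
in, selecting the community count from the distance block alone is correct
behavior, not bias.

## Numerical and design choices

- **Orderings.** Facilities and units are ordered lexicographically at
  ingest; all downstream output is byte-reproducible.
- **Distance input.** Relative asymmetry above $10^{-6}$ is an error;
  below, the matrix is symmetrized by averaging (road-network matrices are
  near- but rarely exactly symmetric). Nonzero diagonals are reset with a
  warning. Merged observations force self-distance 0 even though member
  means need not be.
- **Zero-usage units** are retained as constant zero CI columns: they
  preserve the declared $z$ dimension and are SSE-neutral.
- **Inactive facilities** (zero patient days) are removed with a warning
  before CI computation; an all-inactive table is an error.
- **Degenerate cases.** $K=1$ gives $R^2=0$ by construction; $K=n$ gives
  $R^2=1$; both bound the sweep. `fit_stats` accepts arbitrary labels so
  legacy configurations can be scored unchanged.
- **Problem sizes in the tests** (a handful of communities, $n\le20$
  facilities, exhaustive oracles up to $3^8$ assignments) were chosen so
  that every oracle is computed exactly and the whole suite runs in
  seconds; the pipeline itself is $O(n^2)$ in memory and comfortably
  handles statewide scales (hundreds of facilities, ~1000 units).

## Known limitations

- The selection heuristic is semi-objective by design: the size and
  single-facility rules are planning constraints, not statistics, and
  different applications should change them.
- The bipartite-matching definition of cross-solution agreement is one
  reasonable convention; published agreement figures computed under an
  unspecified rule may differ slightly.
- K-means refinement guarantees descent, not global optimality; the
  exhaustive-search equivalence shown on small fixtures cannot be verified
  at real scale.
- The generator emulates the statistical shape of community-structured
  flows, not any specific geography, payer mix or temporal trend.
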