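---
title: "Multi-persistent clustering of microstate Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-persistent clustering of microstate Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpcluster)
```

## The model and its assumptions

The package analyses *discrete trajectories*: sequences of microstate
indices sampled at a fixed time step, typically produced by a structural
clustering of molecular-dynamics conformations. Everything downstream
assumes that (i) the microstate process is approximately Markovian at the
chosen lag, and (ii) the trajectories visit a single communicating set of
microstates often enough that transition probabilities, stationary
probabilities and mean hitting times are estimable. Neither assumption is
verified for the user; microstates outside the largest strongly connected
component of the transition-count graph are removed (and reported),
because hitting times to or from them are infinite.

From counts at lag $\tau$, $T_{ij} = C_{ij} / \sum_k C_{ik}$, with no
pseudocounts and no reversibility constraint by default: the commute time
is well defined for any irreducible chain, so enforcing detailed balance
is an option (`symmetrize`), not a requirement. The stationary
distribution solves $\pi T = \pi$ by a dense linear solve with the
normalization row substituted, and is verified as a left fixed point to
$10^{-8}$. The free-energy proxy is $E_i = -\ln \pi_i$ — dimensionless,
defined up to an additive constant, meaningful only for ranking and
thresholding.

Commute times are computed in one pass from the fundamental matrix
$Z = (I - T + \mathbf{1}\pi^\top)^{-1}$ as
$h(i \to j) = (Z_{jj} - Z_{ij})/\pi_j$, $D = h + h^\top$. The per-target
solves of the $(n-1)\times(n-1)$ first-step systems are kept in the
package as the independent oracle route; the test suite requires the two
routes to agree to a relative $10^{-8}$ on random chains. If the
fundamental matrix is numerically ill-conditioned (reciprocal condition
below $10^{-12}$) the implementation falls back to per-target solves with
a warning. Commute time is a squared-distance-like quantity: symmetric
and positive, but with no triangle inequality; nothing in the package
assumes one.

## The two-parameter sweep

The clustering at cell $(j, l)$ is the set of connected components of the
graph on the super level set $L_j = \{i : E_i \le \theta_j\}$ with edges
wherever $D \le \varepsilon_l$. This equals a single-linkage dendrogram
cut at $\varepsilon_l$ — the suite checks that equivalence against
`stats::hclust` on random instances — but is computed incrementally: per
density row, edges are sorted once and merged into a union–find structure
as $\varepsilon$ grows, which also guarantees that partitions coarsen
along the scale axis. Components are labeled by their minimum-$E$ member,
ties broken by the lowest index (deterministic; the underlying labels are
continuous free energies, so real ties essentially never occur).

A label's persistence region is provably 4-connected: within a row the
region is a prefix of scale columns (a component only ever gains members
as $\varepsilon$ or $\theta$ grows, so once a lower-$E$ state has been
absorbed it stays absorbed), and those prefixes shrink with the density
level. The implementation still verifies connectivity by flood fill and
raises a hard error on violation, treating it as an implementation bug,
not a data problem. Merge events are recorded symmetrically: each
"merged by" event on one label has a matching "absorbs" event on the
other; figures that show gaps in diagrams are a rendering of these
records, not extra state.

## Grid spacing

Both axes are bounded: density thresholds span $[\min E, \max E]$, and
scales are kept inside $[d_{\min}, D^{*}]$, where $d_{\min}$ is the
smallest pairwise commute time (below it all clusters are singletons) and
$D^{*}$ is the largest minimum-spanning-tree edge (at or above it the
graph is one component).

Spacing defaults were a genuinely open design point and were settled by
experiments on the synthetic benchmarks:

* **Scale axis: geometric (log) spacing.** Commute times grow like
  $e^{\Delta E}$ with barrier heights, so they span orders of magnitude.
  Rank quantiles — the obvious alternative — are dominated by the
  enormous distances of rarely visited microstates: on the 2-D benchmark
  every inter-basin core distance fell below the third percentile of the
  pairwise distance distribution, which compresses all real structure
  into one or two scale indices. Geometric spacing allocates resolution
  evenly in barrier height. Quantile and linear spacing remain
  selectable.
* **Density axis: linear in free energy.** Birth levels then read
  directly as basin depths, and hierarchy join heights as barrier
  levels. Quantile spacing is available for heavily skewed $E$
  distributions.

Duplicate grid values (possible under quantile spacing with ties) are
dropped with a warning, so a requested $m \times q$ grid may be realized
smaller.

## Selecting clusters

Selection implements three principles: persistence in scale (the cluster
is kinetically detached), persistence in density *after birth* (the
density requirement is capped at $m - \mathrm{birth} + 1$, since a
late-born cluster cannot persist over levels that predate it), and a
minimum number of conformations. Defaults: `min_scale = ceiling(q/3)`,
`min_density = ceiling(m/3)`, `min_size` = 1% of all frames.

Clusters passing the persistence rules but failing the size rule are
*rare-state candidates* — possibly genuine rare metastable states,
possibly under-sampling. Because a sparsely visited microstate has few
observed transitions, its commute times to everything are inflated and
its scale persistence is misleadingly long; the package therefore guards
the rare-state flag twice. First, an outlier floor
`min_rare_size = min_size/10`: below it a label is left unflagged (it
stays visible in the summary table, so nothing is silently dropped).
Second, `min_rare_scale = ceiling(0.6 q)`: on the geometric scale grid a
state near the size floor dies at roughly $\kappa/\pi$ (a return-time
effect), which lands around the middle of the scale range; across the
synthetic benchmarks such artifacts never survived past $q/2$ scale
indices, while planted rare states persisted past $0.6q$ with margin.
Both guards are calibrated on the package's own benchmarks and are
plain arguments — a user who prefers the raw three-principle behaviour
can set `min_rare_size = 0, min_rare_scale = min_scale`.

## Versions, partition, hierarchy

Candidates are materialized shallow-first (descending label free
energy): each takes the largest cell of its region whose member set
contains no other candidate's label and no already-claimed microstate.
"Largest" is by conformation count, ties to the earlier cell in (density,
scale) order. If every cell conflicts, the candidate falls back to its
smallest cell minus conflicting members, with a warning — disjointness is
treated as non-negotiable because the cores feed the partition. The full
partition assigns each remaining microstate to the candidate minimizing
the single-linkage distance $\min_{a \in \mathrm{version}} D(i, a)$, ties
to the lower-energy label; `mode = "core"` skips the assignment.

The hierarchy scans density levels at one reference scale column and
joins candidates when their labels first share a component; leaves sit at
birth levels, so branch lengths are level differences and join heights
approximate barrier levels. The reference column defaults to the
*smallest* scale at which any candidate pair co-occurs in the most
permissive level set. The median column — the natural-looking default —
sits below every merge scale on a geometric grid and degenerates the tree
to a star; the first informative column is where the merge ladder
becomes visible. Candidates that never merge within the grid are joined
at a virtual root one level above the top, with a warning. Trees are
serialized as Newick and returned as `ape` `phylo` objects.

## What the synthetic worlds do and do not establish

The generator samples a Metropolis walker (Gaussian proposals, uniform
starts, lockstep vectorized over walkers, fully seeded) on sums of
inverted Gaussian wells, then bins positions on a uniform grid. Two
landscapes are fixed:

* **Three-basin 1-D** (50 bins, 100 × 2 000 steps): deep wells A and B,
  a shallow C nearer to A, and an A–C barrier below every barrier to B.
  The pipeline should select exactly three clusters, show a scale window
  at full density where C has merged into A while B is separate, and
  join C to A before B in the hierarchy.
* **Torsion-like 2-D** (periodic, 20 × 20 bins, 200 × 5 000 steps): four
  prominent wells `a–d` of graded depth, a low `a–b` saddle, and two
  small, deeper-than-they-look wells `e`, `f` far from the main basins.
  The pipeline should select `a–d` and flag `e`, `f` as rare-state
  candidates (late birth, long scale persistence).

Well constants were chosen once so that this qualitative structure is
robust in the sampled world: wells deep enough (≈ 4–10 kT) to be
metastable, within-well mixing fast relative to barrier crossing, and
the small wells genuinely kinetically distinct. Two physical lessons from
that calibration are worth recording. A *shallow* well is not kinetically
distinct — without an escape barrier its label never gathers
conformations before being absorbed — so realistic rare states are
narrow-but-deep, and the low `a–b` saddle is constrained to lie below
the core of the last-appearing well only. And the smallest well's
detection is sampling-limited: across seeds its labeled component
fluctuates around the outlier floor, exactly the regime in which the
method is designed to say "simulate more here" rather than to decide.

The worlds exercise the full pipeline against planted truth, but they
are not molecular physics: flat backgrounds, isotropic kinetics, no
projection artifacts, no discretization error from structural
clustering. A green suite establishes the machinery and its
interpretability on landscapes with known structure — not performance on
any particular biomolecule.

## Numerical choices and degenerate inputs

* Row-stochasticity enforced to $10^{-10}$; stationary fixed point and
  commute-oracle agreement to $10^{-8}$; two-state closed form
  $1/p + 1/q$ to $10^{-10}$.
* Hitting-time systems on reducible chains raise errors rather than
  returning infinities; trimming first is mandatory and reported.
* All-equal free energies degenerate to a single density level with a
  warning; empty super level sets warn and carry through.
* Out-of-domain walker proposals are rejected (bounded domains) or
  wrapped (periodic); out-of-domain positions passed to the discretizer
  are clamped with a warning.
* Every stochastic step flows from one integer seed via `withr`;
  identical configuration and seed reproduce byte-identical artifacts.

## Limitations

Commute-time estimates degrade for microstates with few observed
transitions, and the rare-state guards are calibrated heuristics, not
inference; borderline candidates deserve more simulation, as the
persistence framework itself suggests. The grid sweep is quadratic in
microstates per row ($O(m\,n^2 \log n)$ overall), comfortable to a few
thousand microstates on one CPU but not beyond. Selection thresholds are
judgment calls exposed as arguments; the summary table and overview plot
always expose every label so that no decision is hidden.
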