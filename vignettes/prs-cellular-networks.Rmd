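---
title: "Perturbation-response scanning of cellular networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perturbation-response scanning of cellular networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsnet)
```

## The model

`prsnet` treats a cellular network — typically a genetic interaction
profile similarity network (GI PSN), where genes are linked when their
genome-wide genetic interaction profiles correlate above a threshold — as a
Gaussian network model (GNM): a bead-and-spring system whose connectivity
is encoded in the Kirchhoff (Laplacian) matrix $\Gamma$, with node degrees
on the diagonal and $-1$ for every edge. At equilibrium the covariance of
node fluctuations is the scaled pseudo-inverse over the nonzero modes,

$$C = \frac{1}{\gamma}\,\Gamma^{+} =
  \frac{1}{\gamma}\sum_{\lambda_k > 0}\frac{1}{\lambda_k}\,u_k u_k^\top,$$

where $\gamma$ is a uniform spring constant and $(\lambda_k, u_k)$ the
eigenpairs of $\Gamma$. The diagonal $\sigma_i = C_{ii}$ is the square
fluctuation of node $i$ — its intrinsic, topology-determined adaptability.

Perturbation-response scanning (PRS) perturbs each node in turn and records
every other node's response, normalising each row by the perturbed node's
own fluctuation so the self-response is 1. The default convention squares
the covariance,

$$P_{ij} = \frac{C_{ij}^2}{C_{ii}^2},$$

so that every entry is a nonnegative response magnitude; a `linear`
convention ($P_{ij} = C_{ij}/C_{ii}$) is retained for comparison, but its
off-diagonal entries can be negative and it is not the default. The row
average of $P$ is a node's **effectiveness** (how strongly its perturbation
reaches the rest of the network) and the column average its
**sensitivity** (how strongly it responds to perturbations anywhere). Both
profiles share the same grand mean, a useful internal consistency check
that the test suite asserts to machine precision.

Because $\gamma$ cancels in the normalisation, the PRS matrix and
everything downstream of it are independent of $\gamma$; the covariance is
reported in arbitrary units with $\gamma = 1$ by default.

### Assumptions and scope

The GNM is isotropic and harmonic: only the connectivity matters, edges are
unweighted and undirected, and the network must be a single connected
component (the package insists the caller extract the giant component
first, rather than silently analysing a disconnected Laplacian). The dense
symmetric eigendecomposition is the contract up to 10,000 nodes; larger
inputs are rejected explicitly rather than approximated.

## From profiles to sensors, effectors and antennae

* `selectTop()` defines **sensors** as the top fraction (default 1%) of
  sensitivity and **effectors** as the top fraction of effectiveness. The
  selection size is $\mathrm{round}(f\,n)$ with halves rounded away from
  zero — the only rounding rule consistent with selections of 52 genes out
  of 5,183 (1%), 32 out of 3,238 (1%), and 57 out of 1,145 (5%). Ties at
  the boundary break by descending value then ascending label, so
  selections are reproducible.
* `findClusters()` takes the connected components of the members-only
  induced subgraph; components with at least 3 members (the published
  definition) become clusters, labelled by descending size.
* `detectAntenna()` flags a cluster as an **antenna motif** when exactly
  one non-member node connects it to the rest of the network. These
  bottlenecks let perturbation effects accumulate inside the cluster,
  which is what makes their members unusually sensitive.
* `edgeEnrichment()` asks whether class members connect to each other more
  than degree-matched chance: each null sample draws, per member, a
  distinct random node of identical degree (nearest degree as a logged
  fallback), and the within-class edge percentage is compared over
  `nSamples` draws. Class members themselves stay eligible as candidates —
  the less biased choice, since excluding them would force the null away
  from the observed configuration. The within-percentage counts each
  incident edge once (internal edges are not double-counted).
* `neighborDegreeStats()` compares average neighbour degree between a
  class and the rest with an unpaired rank-sum test. A signed-rank test
  would require a pairing of class members to non-members that has no
  natural definition here, so the unpaired form is used.

## Null models and inference

`rewireNetwork()` randomises a network by double-edge swaps while
preserving every node's degree and overall connectivity. Swaps that would
create self-loops or duplicate edges are rejected outright; connectivity is
verified every 10 accepted swaps and the window rolled back if it breaks,
which keeps the cost of connectivity checking linear while guaranteeing a
connected result. Swapping runs until 10 accepted swaps per edge (the
`swapMultiplier`) have been committed — counting accepted swaps, not
attempts, so sparse networks are mixed as thoroughly as dense ones — with
an attempt cap of 100 times the target to detect degenerate inputs (a
triangle, which admits no valid swap, is returned unchanged with a
warning).

All empirical p-values use the permutation form
$p = (r+1)/(n+1)$, where $r$ counts null values at least as extreme as the
observation. Ties count as extreme, which is conservative, and the p-value
is bounded below by $1/(n+1)$ — it can never be zero. `permutationTest()`
shuffles node labels (default 10,000 times) for group-mean comparisons;
`ensembleStats()` runs the whole pipeline per rewired replicate and
collects mean profiles, degree–profile correlations and sensor-cluster
counts, with per-replicate seeds spawned deterministically from one master
seed so ensembles are bit-reproducible.

## PRS paths

For a path starting at gene $i$, the $i$-th row of $P$ provides node
weights: the response of every gene to perturbing $i$. `prsPath()`
considers all unweighted shortest paths between source and target and
returns the one with the maximal summed weight, computed exactly by
dynamic programming over the BFS shortest-path DAG (never by enumeration,
whose cost is exponential in the worst case; the test suite proves the DP
equal to exhaustive enumeration on hundreds of random graphs). Endpoints
are included in the sum — the source's unit self-response is constant
across candidates and cannot change the argmax, but the target's weight
matters when comparing different targets. Exact ties break toward the
lexicographically smallest node sequence, so outputs are deterministic.

`clusterPairPath()` scans all member pairs of two disjoint clusters and
keeps the single highest-total-weight path, with ties broken by shorter
path then lexicographic order. Because responses are nonnegative, raw
totals favour paths that sweep up additional weighted nodes; this matches
the "highest total perturbation effect" selection, and a
`normalize = "mean"` option scores candidates by per-node mean weight for
users who prefer length-invariant scoring.

## GO enrichment with resampling-based FDR

`loadAnnotations()` combines a minimal OBO 1.2 parser (term id, name,
namespace, obsolescence, `is_a`/`part_of` parents) with a GAF 2.x reader.
Annotations with evidence codes ND, IGI and HGI are excluded by default so
that genetic-interaction-derived annotations cannot leak back into the
evaluation of a genetic network; `NOT`-qualified rows and obsolete terms
are dropped, and annotations are restricted to the background population
(all network nodes). Annotations are *not* propagated to ancestor terms by
default — propagation is available via `propagate = TRUE` but changes the
implicit null and is therefore opt-in.

`enrichGO()` computes, per term, the one-sided hypergeometric tail
(equivalently Fisher's exact test for over-representation), then estimates
a resampling-based FDR: the same per-term p-values are recomputed for 500
random gene sets of the study's size, and each term's FDR is
$(r+1)/(n+1)$ with $r$ the number of resamples at least as significant.
The same resampled sets are reused across terms, which is both cheaper and
the natural reading of a shared null. FDR < 0.1 flags significance. Note
the orientation: strong enrichments must yield *small* FDR, so $r$ counts
null p-values at or below the observed one.

## The synthetic generator

`makeCorePeriphery()` builds the topology the sensor machinery is designed
to detect: a connected Erdős–Rényi core (default 40 nodes at edge
probability 0.3, giving a dense, hub-rich centre) plus 3 antenna cliques
of 4 nodes, each tied to the core by a single edge. Connectors are core
nodes of median degree, so that an antenna's sensitivity signal is
attributable to its bottleneck attachment, not to a privileged connector.
The defaults keep the dense eigendecomposition trivial (52 nodes) while
leaving the planted classes large enough that a top-25% sensitivity
selection is dominated by the 12 antenna nodes.

What the generator does *not* emulate: the heavy-tailed degree
distributions, thousands of nodes, and correlated similarity structure of
real genetic networks. Passing the planted-recovery tests therefore shows
that the machinery identifies bottleneck-attached peripheral clusters when
they exist — it does not certify performance on any particular organism's
network, whose sensors must be validated against their own nulls.

`makeAnnotations()` plants one enriched term per antenna cluster (plus two
random "leakage" genes per term, so recovery is not an artefact of perfect
labels) over a background of 20 terms annotating genes at rate 0.1; a
`signal = FALSE` configuration provides a pure null for FDR calibration.

## Numerical choices

* Zero-mode tolerance: $10^{-8}\times\lambda_{\max}$, a relative threshold
  robust to network size; more than one eigenvalue below it means the
  input was disconnected and is an error, not a warning.
* Similarity matrices must be symmetric within $10^{-8}$; larger asymmetry
  is an error rather than silent symmetrisation.
* Edge threshold: strict (`>` cutoff) by default, with an `strict = FALSE`
  option, because the two conventions genuinely differ at the cutoff value
  and the strict reading reproduces the reference node/edge counts.
* PRS-matrix clustering winsorises at the 95% quantile of all $n^2$
  entries (ties at the quantile left unchanged), uses standardised
  Euclidean distances over rows or columns (zero-variance coordinates
  dropped with a notice), Ward linkage, and a two-way cut at the top
  merge; the smaller side is the "distinct" cluster, with a warning if it
  is a singleton.
* Weight ties in path selection are resolved with a relative tolerance of
  $10^{-12}$ before the lexicographic tie-break.

## Problem sizes used in validation

The shipped tests and the acceptance script validate on: 100 random
connected graphs of up to 50 nodes against an independent pseudo-inverse
oracle (agreement below $10^{-8}$); 100 random 30-node graphs for the
path dynamic program against exhaustive enumeration; 20 generator seeds
for planted-antenna recovery; 15 rewired replicates for cluster-loss
statistics; 200 repeats of 199-shuffle permutation tests for calibration;
and 500-resample FDR estimates on planted and pure-null annotation sets.
These sizes were chosen so the entire validation runs in minutes on a
single CPU while every stochastic check retains a comfortable margin.

## Known limitations

* Dense eigendecomposition only; no sparse or iterative path for networks
  beyond $10^4$ nodes.
* Unweighted, undirected networks; similarity weights are used solely for
  thresholding.
* The rewiring null preserves the degree sequence and connectivity but not
  higher-order structure (clustering coefficient, modularity); conclusions
  drawn from it are conditional on degrees alone.
* The "tip effect" of elastic models — free-end nodes with very large
  fluctuations dominating profiles — is inherent to the method; inspecting
  the degree–sensitivity relationship (as `ensembleStats()` reports) is
  the recommended diagnostic.
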