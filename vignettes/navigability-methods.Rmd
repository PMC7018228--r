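---
title: "Navigability and hyperbolic maps of spatially embedded networks: methods"
author: "navmaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Navigability and hyperbolic maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

A connectome is a spatially embedded network: its nodes (neurons or brain
regions) occupy positions in 3D space, and wiring cost shapes which
connections exist. How much of the network's topology is *encoded* in a
geometric layout? `navmaps` quantifies this with greedy routing and asks the
question twice — once in the anatomical Euclidean embedding, and once in an
*effective* hyperbolic geometry inferred from the topology alone.

# Greedy routing

A source node forwards a signal to its neighbor closest to the target under
the chosen metric; each node en route repeats this until the target is
reached (success) or the signal revisits a node (failure). Because the
forwarding rule is deterministic, revisiting **any** node guarantees an
infinite loop, so the first revisit is the earliest sound failure detection;
a hop cap of $N$ is kept only as a backstop. Ties in neighbor distance are
broken by the lexicographically smallest node id (C collation), making runs
bit-reproducible. The current node being closer to the target than all its
neighbors does *not* halt forwarding — the protocol always forwards and the
loop rule catches the failure.

Statistics over all ordered source/target pairs within connected components
(pairs spanning components are excluded from numerator *and* denominator,
since they can never succeed; source = target pairs are excluded too):

* **Success rate (SR)** — fraction of successful ordered pairs.
* **Topological stretch** — greedy hops divided by BFS shortest-path hops;
  always $\ge 1$.
* **Geometric stretch** — greedy geometric length divided by the geometric
  length of the hop-minimal path. Among the generally many hop-minimal
  paths we take the one of minimal geometric length, computed by layered
  relaxation over the BFS level DAG; this makes the denominator
  deterministic and conservative. Geometric stretch *can* fall below 1: a
  greedy path with more hops can be geometrically shorter than the
  hop-minimal path. The test suite contains a constructed instance with
  stretch $\approx 0.53$.
* **Locally outgoing / incoming SR** — per-node success fractions over
  pairs with that node as source or target.

# The S1/H2 hidden-metric-space model

In the hyperbolic disk (H2 model) each node has polar coordinates
$(r, \theta)$: radius encodes popularity (degree), angle encodes similarity.
Nodes at hyperbolic distance $x$ connect with probability

$$p(x) = \frac{1}{1 + e^{\beta (x - R)/2}},$$

where $R$ is the disk radius (sets density) and $\beta > 1$ the inverse
temperature (sets clustering). Distances use the exact hyperbolic law of
cosines, with the $\operatorname{arccosh}$ argument clamped to $[1,\infty)$
against round-off near coincident points.

The isomorphic S1 formulation replaces radius by a hidden degree $\kappa$
on a circle:

$$p_{ij} = \frac{1}{1 + \left(\frac{\Delta\theta_{ij}}{\mu\,\kappa_i \kappa_j}\right)^{\beta}}.$$

$\Delta\theta$ is the minimal angular separation used directly (all scale
constants are absorbed into $\mu$). The two formulations coincide exactly
under $r = R - 2\ln(\kappa/\kappa_0)$ — the convention that places the
minimum hidden degree $\kappa_0$ on the disk boundary — together with
$R = 2\ln\!\big(2/(\mu\kappa_0^2)\big)$ and the large-radius distance
approximation $x \approx r_i + r_j + 2\ln(\Delta\theta/2)$. The package
verifies this identity to $10^{-9}$ relative error. Note the approximation
drops a $\sin(\Delta\theta/2)/(\Delta\theta/2)$ factor, so it is accurate
only for separations well below $\pi$ (and above the $e^{-r}$ floor);
routing and likelihoods therefore always use the exact law of cosines —
the approximation exists only for the model equivalence and diagnostics.

## Calibrating $\mu$

Given hidden degrees, $\beta$ and a target mean degree, $\mu$ is found by
bisection (in $\log\mu$, from the analytic seed
$\mu_0 = \beta\sin(\pi/\beta)/(2\pi\langle\kappa\rangle)$, bracket expanded
geometrically) until the ensemble's expected mean degree is within 2% of
target. The expected degree is the exact angular average of $p_{ij}$ over a
uniform pair separation; per pair it reduces to the 1D integral
$\tfrac{a}{\pi}\int_0^{\pi/a} \frac{du}{1+u^\beta}$ with
$a = \mu\kappa_i\kappa_j$, evaluated deterministically (dense trapezoid
grid on $[0,10]$, three-term tail expansion around
$\int_0^\infty du/(1+u^\beta) = (\pi/\beta)/\sin(\pi/\beta)$ beyond). A
Monte-Carlo average was considered and rejected: at realistic densities
($\langle k\rangle/N \sim 0.005$) its sampling noise exceeds the 2%
convergence band unless $\sim 10^7$ draws per bisection step are used,
whereas the quadrature is noise-free and fast.

# Synthetic connectomes

The generators define the study conditions; all randomness flows from one
integer seed per call (no global state is left disturbed).

* **S1 generator** — hidden degrees are Pareto draws
  ($\propto \kappa^{-\gamma}$, $\kappa \ge \kappa_0$, $\gamma > 2$ so the
  mean is finite), matching the broad-but-not-power-law degree
  distributions of real connectomes; angles uniform, or placed in planted
  arcs for cartography tests; $\mu$ calibrated; pairs linked independently.
  Defaults $N$ in the hundreds to thousands, $\gamma = 2.7$,
  $\kappa_0 = 2$, $\beta = 2.5$, $\langle k\rangle = 10$ — the sparse,
  clustered, heterogeneous regime of coarse-grained connectomes.
* **Euclidean generator** — $N$ points uniform in a 3D box; pairs linked
  with $p = 1/(1 + (d/\lambda)^{\beta_e})$ (an exponential decay is
  selectable), mirroring the S1 law in Euclidean distance for
  comparability. An optional hard cutoff removes links longer than a given
  length, emulating partial-volume, neuron-level datasets that miss
  long-range connections. Note the large-$\lambda$ limit of this law is
  $p \to 1$ (a flat curve near 1), which is what the tests assert.

What the generators deliberately do **not** emulate: correlations between
the anatomical positions and the similarity space, directed or weighted
edges, hemispheric symmetry, or any specific species' statistics. Passing
tests therefore demonstrate correctness of the machinery under the model's
own assumptions, not fidelity to any particular real connectome.

# Maximum-likelihood embedding

Coordinates are inferred by maximizing the Bernoulli likelihood
$\sum_{i<j} a_{ij}\ln p_{ij} + (1-a_{ij})\ln(1-p_{ij})$ with $p_{ij}$ from
the H2 law at exact distances (probabilities clamped to
$[10^{-15}, 1-10^{-15}]$ before logs).

Design choices, isolated in `embedding_config()`:

* **Radii are fixed, not sampled.** Hidden degrees are set to
  $\max(k_i, 1)$ (observed degrees), $\mu$ is calibrated to the observed
  mean degree, and radii follow from the popularity–similarity convention.
  This reduces the search to the angles, which are the dominant unknowns.
* **$\beta$** is either supplied or estimated by `infer_beta()`: bisection
  on $(1.01, 10]$ until S1 surrogates (observed degrees, uniform angles,
  calibrated $\mu$; 5 surrogates per evaluation) match the observed mean
  local clustering within $\pm 0.01$. Clustering rises monotonically with
  $\beta$, which makes the bisection well posed; graphs with no clustering
  (trees) return the lower boundary with a warning.
* **Sampler.** One Metropolis proposal per node per sweep: a wrapped
  Gaussian step (default final width $2\pi/\sqrt{N}$) or, with probability
  0.1, a uniform redraw. During the first 60% of the sweep budget the
  proposal width anneals from $\pi$ down to its final value and the
  acceptance temperature from 8 down to 1; afterwards sampling is plain
  Metropolis ($\min(1, e^{\Delta\log L})$). Each sweep also makes four
  *block* proposals — a random arc is reflected about its bisector or
  translated to a new location, changing only arc-to-rest pair terms.
  Without block moves, cold-started chains stall in flipped-segment local
  optima far above the likelihood attainable from the true angles; with
  them they reach or pass it.
* **Stopping and restarts.** Plateau stopping (default: 100 sweeps without
  a gain above $10^{-4} N$) arms only after the annealing phase; the best
  of 3 restarts wins. Runs are deterministic given the seed.

Disconnected graphs are rejected — the pipeline layer embeds the largest
component explicitly rather than silently.

## Measuring angular recovery

The likelihood is invariant under global rotation and reflection, so any
quality measure must be too. The package reports the **alignment-corrected
angular agreement**: the maximum over the two reflections and all rotations
of the mean cosine of the angular residuals (the optimal rotation is the
circular mean of the residuals, so the search is closed-form). It equals 1
for a perfect map up to isometry and is $O(1/\sqrt{N})$ for unrelated
angles. The moment-based Fisher–Lee circular correlation coefficient is
also provided but is *not* used as a recovery criterion: with multimodal
angle marginals its normalization can collapse, and it returned 0.01 on a
map whose pairwise-separation correlation with the truth was 0.94 and whose
routing success rate was 1.0.

# Null models

1. **Position swap** — the node-to-coordinate assignment is permuted
   uniformly; topology and the coordinate multiset are preserved exactly.
2. **Degree-preserving rewiring** — double-edge swaps
   $(a\!-\!b, c\!-\!d) \to (a\!-\!c, b\!-\!d)$ on four distinct nodes,
   rejecting self-loops and duplicates, until $100L$ successful swaps.
   Graphs with no valid swap (e.g. a triangle) exhaust the attempt budget
   ($100\times$ the swap target) and return unchanged with a warning, so
   pipelines over many graphs keep running.
3. **Cost-preserving rewiring** — as above, but a swap is accepted only if
   $|(d_{AB}+d_{CD}) - (d_{AC}+d_{BD})| < \varepsilon D$, with
   $\varepsilon = 1/60$ and $D$ the total wiring cost of the *input* graph
   (each undirected edge counted once; $D$ is computed once and never
   updated). The tolerance binds each swap, not the cumulative drift, so
   the total cost can drift by up to (accepted swaps)$\times\varepsilon D$
   in the worst case; the per-swap audit is the binding contract and is
   what the tests verify. When the tolerance is loose relative to typical
   per-swap deltas (e.g. hyperbolic metrics, where $D$ is large), this
   null approaches the unconstrained rewiring, which is informative in
   itself.

# Cartography

* **Critical gap communities.** Nodes sorted by angle; every consecutive
  gap (wraparound included) greater than the critical gap splits
  communities. The default threshold is $(2\pi/N)\ln N$, the asymptotic
  expected maximal gap of $N$ uniform angles — gaps larger than uniform
  placement would produce mark community boundaries. The threshold is a
  parameter so other conventions can be substituted. Output is rotation
  invariant; labels start after the largest splitting gap.
* **NMI** between partitions uses the joint contingency table with natural
  logs, normalized by the arithmetic mean of the entropies (max- and
  sqrt-normalizations selectable). Two single-cluster partitions are
  identical (NMI 1); if exactly one entropy is zero the information is
  zero (NMI 0).
* **Angular localization.** Observed statistic: mean pairwise angular
  separation within the cluster. Null: the same statistic for equally
  sized subsets drawn uniformly without replacement from *all* map nodes
  (cluster members included), default 10000 samples. The p-value is the
  plain fraction of null samples at or below the observed value — no
  $(k+1)/(n+1)$ smoothing — so 0 is a possible report meaning "below all
  null samples".
* **Region angular span** — the smallest arc containing the cluster
  ($2\pi$ minus the largest gap), as a fraction of the circle; normalized
  angular separation is $\Delta\theta/\pi \in [0,1]$.
* **Empirical connection probability** — unordered pairs binned by metric
  distance (equal-width over the observed range); per-bin connected
  fraction with pair counts, empty bins reported as such.

# Numerical conventions

Node ids are opaque strings; all internal integer indexing is invisible in
outputs. Orderings use C collation so results do not depend on the locale.
All stochastic functions take explicit integer seeds; the C++ samplers use
a Mersenne-Twister generator seeded from them, and R-side draws run in an
isolated RNG scope that restores the caller's state. Degenerate inputs have
defined behavior: self-loops are dropped with a warning (published
connectome tables occasionally contain them), duplicate edges collapse,
empty bins report NaN fractions, a single node forms one community, and a
cluster equal to the whole node set has localization ratio and p-value
exactly 1.

# Problem sizes

The test suite and the reproduction script use $N = 300$ networks with
$\langle k \rangle = 10$ for embedding and routing (89,102 ordered pairs),
$N = 2000$ for generator calibration, $N = 1000$ for $\beta$ recovery, and
10,000 permutation samples for localization — sizes at which every
statistic of interest is stable yet a full run completes on a single CPU in
a few minutes. The embedding recovery threshold (agreement $\ge 0.7$,
routing SR $\ge 0.9$ on the inferred map) is a scaled-down analogue of the
near-perfect hyperbolic navigability regime.

# Known limitations

* The MH schedule (annealing, block moves, plateau rule) is validated by
  parameter recovery on S1 networks only; real connectomes with strong
  core-periphery or bipartite structure may need longer budgets.
* Fixing radii from observed degrees biases $\kappa$ for low-degree nodes
  ($\max(k,1)$) and ignores degree noise; joint $(r,\theta)$ samplers are
  out of scope.
* $\beta \le 1$ (vanishing clustering) and weighted or directed generation
  are unsupported; directed routing is available but all other analyses
  are undirected.
* The cost-preserving null's cumulative drift is unbounded by design (see
  above); interpret "cost-preserving" as per-swap, not global.
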