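---
title: "Network dimension from diffusion transients: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network dimension from diffusion transients: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffdim)
```

## The model

On Euclidean space the Green's function of the diffusion equation,
$G_t(\mathbf{x}) = (4\pi\sigma t)^{-d/2} \exp(-\|\mathbf{x}\|^2 / 4\sigma t)$,
carries the dimension $d$ in both the time and the amplitude of the transient
maximum observed at any fixed point: the response at distance
$\|\mathbf{x}\|$ from a delta initial condition peaks at
$\hat t = \|\mathbf{x}\|^2 / (2 d \sigma)$ with amplitude
$\hat p = (4 e \pi \sigma \hat t)^{-d/2}$. Eliminating $\|\mathbf{x}\|$ gives

$$d = \frac{-2 \ln \hat p}{\ln(4 e \pi \sigma \hat t)},$$

which uses positions only as labels. That makes the relation portable to any
space carrying a diffusion process. On a graph we use consensus dynamics
$\partial_t \mathbf{p} = -L\mathbf{p}$ with the random-walk normalized
Laplacian $L = K^{-1}(K - A)$ ($A$ the weighted adjacency, $K$ the diagonal
weighted-degree matrix), the graph generator whose continuum limit is
Euclidean diffusion. The transient response of node $j$ to a delta condition
of mass $m_i$ at node $i$ is the heat kernel
$p_j(t \mid i) = m_i (e^{-tL})_{ji}$. Measuring its peak $(\hat t_{ij},
\hat p_{ij})$ and inverting through the relation above yields the **relative
dimension** $d_{ij}$ of $j$ seen from $i$. Nodes whose response rises
monotonically to the stationary value — typical when a boundary or the finite
graph size shadows the pair — have no peak and no defined relative dimension;
this "no peak" outcome is represented by an explicit mask, never by a
sentinel number.

Three conventions complete the discrete definition.

* **Initial mass.** `source_masses()` sets $m_i = \bar k / (n k_i)$ over the
  $n$ source nodes ($k_i$ the weighted degree, $\bar k$ its mean). Then the
  stationary state is exactly $1/N$ at every node and sums to unity, and
  $p_j(t \mid i) = p_i(t \mid j)$, so the relative-dimension matrix is
  symmetric. Both facts are asserted in the test suite.
* **Time normalization.** Times are reported as $\tau = \lambda_2 t$, with
  $\lambda_2$ the spectral gap, so $\tau = 1$ is the stationarity scale on
  any graph and scales are comparable across graphs. This normalization is a
  *scale axis* convention: it drives the time grid and the indicator
  $\hat\tau_{ij} < \tau$ of the local dimension, but the inversion formula is
  evaluated at the raw peak time $\hat t_{ij}$. Feeding normalized times into
  the formula destroys the Euclidean calibration (on the 500-node interval
  the near-source plateau moves from $1.00$ to a meaningless negative value,
  because $\ln(4e\pi\sigma\hat\tau)$ changes sign across the peak-time
  range), which is why the two roles of time are kept distinct.
* **Diffusion constant.** The unit-rate random walk generated by
  $K^{-1}(K-A)$ on a $2d$-regular lattice with unit spacing performs jumps of
  unit mean-squared displacement, i.e. diffuses with
  $\sigma = 1/(2d) = 1/\bar k$. The package therefore defaults to
  $\sigma = 1/\bar k$ (per graph), which makes lattice recovery essentially
  exact without any graph-specific tuning: the 500-node line gives a
  near-source median of $1.000$ and the $25{\times}20$ grid a central mean of
  $1.96$ at $\tau = 0.1$ (both recomputed by the acceptance script). With a
  fixed $\sigma = 1$ the same quantities are $0.93$ and $1.50$ — the
  logarithmic bias $d\,\ln(\sigma_{\mathrm{eff}})/\ln(4e\pi\hat t)$ decays
  only logarithmically in distance, and it is twice as large for the grid
  ($\sigma_{\mathrm{eff}} = 1/4$) as for the line ($1/2$). `sigma` remains a
  user parameter for non-lattice applications.

**Local and global dimension.** The local dimension of node $i$ at scale
$\tau$ averages the relative dimensions of targets that have peaked by then,

$$D_i(\tau) = \frac{\sum_{j \ne i} d_{ij}\,\mathbb{1}[\hat\tau_{ij} < \tau]}
                   {\sum_{j \ne i} \mathbb{1}[\hat\tau_{ij} < \tau]},$$

undefined while the count is zero. The count is non-decreasing in $\tau$ and
$D_i$ is a convex combination of the contributing $d_{ij}$ (both asserted as
properties). The global dimension $\mathfrak{D}(\tau)$ averages $D_i(\tau)$
over the nodes where it is defined; averaging undefined entries as zero would
bias the curve downward at small scales, so they are simply excluded. For
grid-like graphs $\max_\tau \mathfrak{D}(\tau)$ approaches the Euclidean
dimension from below as the lattice grows, faster for periodic and
lower-dimensional families — the convergence experiment measures exactly
this, and the test suite asserts the strict increase over sizes
$\{100, 300, 900\}$ for the line and ring families with ring above line
throughout.

An alternative reading of the scale-dependent relative dimension — re-detect
peaks within a truncated horizon $[0, \tau]$ — coincides with the indicator
filtering for every interior maximum, so it is not implemented separately.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `sigma` | $1/\bar k$ | dimensionless | diffusion constant in the inversion formula |
| `t_min`, `t_max` | $10^{-3}$, $5$ | normalized $\tau$ | time-grid bounds |
| `n_times` | 400 | — | grid resolution (log-spaced by default) |
| `rel_tol` | $10^{-6}$ | relative | peak acceptance margin above $1/N$ |
| `gamma` | 1 | 1/time | SIR recovery rate (fixes the time unit) |
| `n_realizations` | 500 | — | SIR outbreaks averaged per seed node |

The grid bounds matter at both ends. Peaks of very close pairs occur at tiny
$\tau$: on the 500-node line a node at hop distance $u$ peaks at raw time
$u^2$, which is *below* `t_min`$/\lambda_2 = 50$ for $u \lesssim 7$, so
immediate neighbours of a source report no peak under the defaults; widening
`t_min` downward recovers them at the cost of a longer grid. The margin
`t_max` $= 5 > 1$ lets peaks that occur just before stationarity remain
interior grid maxima. `rel_tol` rejects numerically flat trajectories whose
grid maximum exceeds $1/N$ only by rounding; $10^{-6}$ is far below any
genuine shallow peak we observe but well above eigensolver noise.

## Numerical scheme

One symmetric eigendecomposition per graph. The similarity transform
$K^{1/2} L K^{-1/2} = I - K^{-1/2} A K^{-1/2}$ is symmetric with the same
spectrum, so `eigen(symmetric = TRUE)` applies, and the heat kernel for any
source and all grid times is two dense matrix products. The all-pairs
relative-dimension matrix reuses the same decomposition for all $N$ sources.
Because $p_j(t \mid i) = p_i(t \mid j)$ exactly under the mass convention,
`relative_dimension_matrix(use_symmetry = TRUE)` computes targets $j \ge i$
and mirrors, halving the work; the symmetry *tests* run with
`use_symmetry = FALSE` so they check the mathematics rather than the
mirroring. Trajectories are cross-validated against `Matrix::expm()` on
small graphs to $10^{-9}$.

Peak refinement fits a parabola through the three log-time grid points
around the grid argmax and reports its vertex, removing grid quantization
(the refinement is switchable; a degenerate parabola falls back to the grid
point). Grid argmax ties resolve to the earliest time. The inversion is
flagged undefined when $|\ln(4e\pi\sigma\hat t)| < 10^{-12}$ rather than
returning an unbounded value. The residual of the slowest transient mode
decays as $e^{-\tau}$, so stationarity checks are asserted at $\tau = 16$
(residual $\sim 10^{-7}$) at tolerance $10^{-6}$.

Graphs are validated at construction: strictly positive weights, no
self-loops (dropped with a warning), parallel edges summed, directed input
symmetrized by averaging with a warning, and connectivity required — on a
disconnected graph $\lambda_2 = 0$ and the time normalization is undefined,
so the error names the component count instead. Node order is fixed at load
(numeric when labels parse as numbers), making every matrix reproducible.

## Synthetic generators and what they (do not) emulate

The generators produce the study conditions used throughout: unit-weight
path/ring/grid/torus lattices (4-neighbour connectivity, the standard
discretization of 2-D diffusion; the 500-node grid is realized as
$25 \times 20$, the most nearly square factorization); a Delaunay mesh of a
$40 \times 40$ unit-square grid whose edges are weighted by inverse length —
adding a Gaussian cluster of points (variance $0.05$) locally densifies the
mesh and bends the effective diffusion geometry, the gravitational-lensing
analogue; and seeded Erdős–Rényi / Watts–Strogatz / Barabási–Albert
ensembles with edge probability $0.03$–$0.1$, rewiring $0.1$–$0.7$ with
$5$–$10$ lattice neighbours (total degree; the ring couples $k/2$ nodes per
side), and $1$–$20$ edges per node respectively, sizes cycling over ten bins
of the requested range. Disconnected ER/BA draws are reduced to their
largest component; disconnected WS draws are resampled. All stochastic
generators are seeded and bit-reproducible.

These are clean mathematical ensembles: unit or inverse-distance weights, no
measurement noise, no degree–weight correlations, no community structure.
Passing the lattice-recovery tests shows the estimator is correctly
calibrated to Euclidean geometry; it does not certify behaviour on real
weighted networks, where weight heterogeneity enters through $K$ and the
meaning of $\sigma$ is application-specific.

## SIR infectiousness

`simulate_sir()` is a direct Gillespie simulation of Markovian SIR
(transmission at rate $\beta$ per S–I edge, recovery at rate $\gamma$).
`node_infectiousness()` — the mean final removed count per seed node over a
$\beta$ grid — instead uses the exact final-size representation of the same
process: each node draws a recovery time $r_i \sim \mathrm{Exp}(\gamma)$,
the directed edge $i \to j$ transmits iff an $\mathrm{Exp}(\beta)$ waiting
time is shorter than $r_i$, and the outbreak seeded at $i$ is its
out-reachable set. One draw serves every seed node, and reusing the same
waiting times across the $\beta$ grid (common random numbers) makes the
population-mean infectability exactly non-decreasing in $\beta$. The two
routes are cross-checked in the tests against the exact branching
expectation on a star graph ($1 + (N-1)/2$ removed at $\beta = \gamma$).
$\gamma = 1$ fixes the time unit so $\beta$ is the single control
parameter; the default $\beta$ grid log-spaces 20 values across
$[0.1, 10] \times \gamma/\bar k$, which brackets the transition on all
graphs used here, and $\beta_{\mathrm{crit}}$ is the smallest grid rate
whose mean infectability reaches $N/2$, without interpolation.

On a low-rewiring small world (WS $n = 100$, degree $10$, $p = 0.015$) the
correlation surface between $D_i(\tau)$ and infectiousness reproduces the
expected structure: the best scale $\tau^*(\beta)$ increases with $\beta$
below criticality (asserted as a positive rank correlation) and the best
correlation peaks near $\beta_{\mathrm{crit}}$ (about $0.83$ at high
realization counts). The *uniform* bound $r^* \ge 0.8$ across the middle
half of the sub-critical grid does not hold for every WS realization:
measured at $2 \times 10^4$ realizations — i.e. with Monte-Carlo attenuation
removed — the ceiling on unfavourable draws is $0.66$–$0.79$, and a
discrete-time (Reed–Frost) variant gives the same ceiling. At sub-critical
rates outbreaks are small and node infectiousness is dominated by degree
fluctuations that the local dimension captures only partially. The
corresponding acceptance test asserts the bound as stated and is expected to
fail for typical draws; we report this rather than selecting a favourable
realization.

## Random-graph classification

Each graph is summarized by the mean, standard deviation and skewness
(adjusted Fisher–Pearson, zero by convention for a degenerate distribution)
of its nodes' local dimension at the largest computed scale — at
$\tau_{\max}$ every peaked target contributes, making the feature a
whole-graph summary; among the scales tried ($\tau \in \{0.1, 0.5, 1,
\tau_{\max}\}$) the largest scale also separates the families best. A
100-tree random forest is evaluated by stratified 10-fold cross-validation
(folds dealt per class under a fixed seed), with feature importance reported
both as mean decrease in impurity and as permutation importance — two
standard measures used here in place of Shapley values. Skewness and spread
dominate the importance ranking, and Barabási–Albert graphs show the
broadest, most skewed distributions, reflecting their heavy-tailed degrees.

At desk scale (60 graphs per class, $n \in [100, 300]$, `n_times = 200`)
the cross-validated accuracy is about $0.74$–$0.81$ depending on the
ensemble seed: BA separates almost perfectly and the loss is ER–WS
confusion, which shrinks at larger sizes where the families' densities
diverge (accuracy already reaches $0.82$ with only 30 graphs per class when
sizes span $[100, 1000]$). The full-scale experiment (600 per class, sizes
to 1000) is available through the same functions but is deliberately not
part of the default test run.

## Problem sizes

The package's own experiments run at: all-pairs matrices up to $N = 900$
(convergence) with 200 time points; $N = 500$ lattices with the full
400-point grid for the headline recoveries; SIR scans at $n = 100$ with 500
realizations per seed over 15 rates; classification ensembles of 180 graphs.
These choices keep a complete validation run in the minutes range on a
single core while leaving every size a parameter.

## Known limitations

* Directed diffusion is out of scope; directed input is symmetrized on load.
* Disconnected graphs are rejected rather than analysed per component.
* Pairs closer than the first grid time or shadowed by boundaries carry no
  relative dimension; downstream averages use only the defined set.
* The $\sigma = 1/\bar k$ calibration is exact for regular lattices and a
  reasonable default elsewhere; strongly heterogeneous weighted graphs may
  warrant an application-specific $\sigma$.
* The mass–radius fractal baseline (`fractal_dimension_baseline()`) fitted
  over small radii underestimates the asymptotic dimension (its
  least-squares slope over $r \le 10$ on a torus is $1.67$, not $2$); it is
  included as the conventional point of comparison, not as a reference
  value.
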