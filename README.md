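# diffdim

Dimension of a network from the transient response of diffusion.

Many questions about a network — how influence spreads from a protein's
allosteric site, which node seeds the largest epidemic, whether a graph
"looks like" a lattice or a scale-free tangle — come down to the effective
dimension of the space the network discretizes, locally and at a given
scale. `diffdim` estimates that dimension directly from dynamics, without
any embedding or fit: it runs diffusion on the graph, watches when and how
high the response peaks at each node, and inverts the Euclidean
Green's-function relation to read off a dimension.

## The estimator

On $\mathbb{R}^d$, diffusion from a point source produces at any other
location a transient maximum at time $\hat t$ with amplitude
$\hat p = (4 e \pi \sigma \hat t)^{-d/2}$, so

$$d = \frac{-2\,\ln \hat p}{\ln\!\left(4 e \pi \sigma\, \hat t\right)}.$$

On a graph, `diffdim` applies the same inversion to the heat kernel
$p_j(t \mid i) = m_i\,(e^{-tL})_{ji}$ of the random-walk normalized
Laplacian $L = K^{-1}(K - A)$ (the graph generator whose continuum limit is
Euclidean diffusion), giving:

* the **relative dimension** $d_{ij}$ of node $j$ seen from source $i$
  (`relative_dimension_matrix()`), a symmetric matrix under the package's
  inverse-degree mass convention, with an explicit mask for pairs whose
  response never peaks;
* the **local dimension** $D_i(\tau)$ of each node at scale $\tau$
  (`local_dimension()`), averaging $d_{ij}$ over targets that peaked before
  $\tau$ (times are normalized by the spectral gap, so $\tau = 1$ is the
  stationarity scale);
* the **global dimension** curve $\mathfrak{D}(\tau)$
  (`global_dimension()`), whose maximum over $\tau$ recovers the Euclidean
  dimension of grid-like graphs.

Around this core the package provides lattice / Delaunay-mesh /
random-graph generators reproducing the validation experiments, an SIR
module relating local dimension to node infectiousness across transmission
rates, a random-graph classification experiment on local-dimension
distribution features, and a mass–radius fractal-dimension baseline.

## Worked example

Estimate the dimension of a 15×10 lattice — a discretization of a 2-D
rectangle, so boundary-distant nodes should look 2-dimensional at short
scales while boundaries depress the estimate at large ones:

```r
library(diffdim)

g <- grid_graph(15, 10)
g
#> dd_graph: 150 nodes, 275 edges, mean weighted degree 3.667

rdm <- relative_dimension_matrix(g)   # all-pairs, one eigendecomposition
rdm
#> dd_relative_dimension: 150 nodes, 54.0% of pairs defined, sigma = 0.2727

gd <- global_dimension(local_dimension(rdm))
gd
#> dd_global_dimension: max 1.727 at tau = 0.0164 (400 scales)

local_dimension_features(g)           # distribution moments, used for
#>     mean      std skewness          # random-graph classification
#>    1.605    0.086    0.130
```

Reading the output: 46% of pairs never peak (the boundary shadows them —
on a two-node graph *no* pair peaks), `sigma = 0.2727` is the automatic
lattice calibration $1/\bar k$, and the global-dimension maximum 1.73 sits
below the Euclidean 2 because a 150-node lattice is small; the ratio rises
toward 1 as the lattice grows (`convergence_experiment()` measures the
trend, and on 500-node grids the short-scale central estimate is within 0.04
of 2).

A command-line interface wraps the same functions for shell use, e.g.

```sh
exec/diffdim generate --family ws --n 100 --nei 5 --p 0.015 --out ws.txt
exec/diffdim global-dim --graph ws.txt --out curve.csv
```

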