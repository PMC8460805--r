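# transcell

Detecting transition cells and quantifying cell-fate dynamics from
single-cell expression snapshots.

## The problem

Snapshot single-cell transcriptomics shows heterogeneous cell states but not
their dynamics. Clustering forces every cell into a discrete type;
pseudotime forces every cell onto a continuum. Cells caught mid-switch —
transient, with mixed identity — fit neither description, yet they carry the
information about how fates convert. `transcell` models a snapshot as
samples from an overdamped stochastic dynamical system in a multi-well
potential: stable types are attractor basins, transition cells cross the
saddles in between, and the package infers that structure directly from the
expression matrix.

## The method

Starting from a cells-by-genes matrix, the package learns a reversible
cellular random walk and reduces it across three resolutions that are fitted
to agree with one another:

* **cell–cell**: a symmetric Gaussian-type kernel on the kNN graph gives the
  row-stochastic walk `p(x,y) = w(x,y)/d(x)` with stationary distribution
  `mu(x) = d(x)/sum(d)` satisfying detailed balance
  `mu(x) p(x,y) = mu(y) p(y,x)`;
* **cluster–cluster**: a hard partition into K attractor basins with a K×K
  transition matrix `Phat`, minimizing the mu-weighted Hilbert–Schmidt
  distance `J = ||phat_induced − p||²_mu`; the optimal `Phat` is the
  stationary block flux `Phat_ij = Σ_{x∈S_i, y∈S_j} mu(x) p(x,y) / muhat_i`;
* **cell–cluster**: per-cell simplex memberships `rho(x)` over basins,
  minimizing `E = ||ptilde(rho) − p||²_mu` with `Phat` held fixed; the
  transition entropy `H(x) = −Σ_k rho_k log rho_k` flags hybrid cells.

On the coarse chain, transition path theory (committors `q±`, effective
currents `f⁺`, bottleneck capacities) assigns a likelihood to every route
between chosen start and target basins; spanning- and shortest-path trees
summarize the global lineage; a Gaussian-mixture landscape
`phi(z) = −log Σ_k muhat_k N(z; Y_k, Λ_k)` renders the dynamics as an
energy surface; and per-transition scores
`tau_ij(x) = rho_i(x)/(rho_i(x)+rho_j(x))` order the cells of one
conversion and classify genes as transition drivers (track `tau`),
meta-stable (exclusive to one stable side) or intermediate-hybrid (shared by
transition cells and one side). A micro-state aggregation pre-pass
(`declareMicroStates`) scales the pipeline to large datasets with the same
lumping algebra.

## Worked example

Three metastable basins from an overdamped Langevin simulation on a
triple-well potential, recovered from 2,001 snapshot points alone:

```r
library(transcell)

ds <- simulateTripleWell(nCells = 2001, seed = 5)   # 2-D pseudo-cells + truth
model <- fitDynamics(ds@coords,
                     runConfig(kNeighbors = 30, nAttractors = "auto",
                               seed = 1))
model
#> CellFateModel on 2001 cells
#> CoarseGrainedModel with 3 attractors
#>   sizes: 576, 746, 679
#>   objective J: 61.5795
#>   mean transition entropy: 0.0611

model@spectrum@bestK
#> [1] 3

round(transitionMatrix(model@coarse), 4)
#>        [,1]   [,2]   [,3]
#> [1,] 0.9869 0.0076 0.0054
#> [2,] 0.0059 0.9864 0.0077
#> [3,] 0.0046 0.0085 0.9869

tp <- transitionPaths(model, 1, 3)
tp@paths$likelihood
#> [1] 0.5561419 0.4438581
```

The eigen-peak index selects K = 3; the coarse transition matrix is
diagonally dominant (cells mostly stay in their basin, with conversion
probabilities of order 10⁻²); and of the two routes from basin 1 to basin
3, the direct conversion carries 56% of the transition-path likelihood
versus 44% for the route through basin 2. Cells near the saddles get high
transition entropy, and `dynamicalManifold(model)` places them on the
barriers of the reconstructed landscape.

The attractor labels match the ground-truth basins of the noiseless flow
with an adjusted Rand index above 0.99 on this fixture (checked in the test
suite along with the entropy and path-dominance claims above).

## Command line

A thin CLI over the same functions lives at `inst/cli/transcell.R`:

```sh
Rscript inst/cli/transcell.R run --input expr.csv --k-neighbors 30 \
    --n-attractors auto --seed 1 --out results/
Rscript inst/cli/transcell.R simulate --model triple-well --n 2001 --out sim/
```

`run` writes attractors.csv, membership.csv, entropy.csv, phat.csv,
manifold.csv and the configuration as YAML; `spectrum`, `paths` and
`simulate` cover the remaining steps.
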