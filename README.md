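# netsevd

Differential gene-network analysis by sparse spectral graph
decomposition.

Two phenotypes — for example drug-sensitive and drug-resistant cancer
cell lines — can wire the same genes into different regulatory
networks even when single-gene expression changes little.  `netsevd`
detects such differentially regulated sub-networks.  It represents
each phenotype's network by its normalized graph Laplacian
`L = D^{-1/2}(D - A)D^{-1/2}`, estimates the Laplacian's eigenvalues
with **sparse** loadings under an L1 plus network-constrained
(quadratic Laplacian, `β'Lβ`) penalty, measures the dissimilarity of
the two phenotypes by the spectral distance

```
d(G^Y, G^N) = Σ_r { λ(L^Y)_r − λ(L^N)_r }² ,
```

and attaches significance with a label-permutation test in which both
networks are re-estimated from scratch on every permutation
(`p = #{d_obs ≤ d_perm} / T`).  The quadratic Laplacian penalty — the
graph Dirichlet energy — encourages genes linked in the network to
carry similar loadings and, through its degree rescaling, shrinks hub
genes less, so components are built from hubs and their neighborhoods
rather than arbitrary gene mixtures.

The package contains:

* `weighted_graph()`, `normalized_laplacian()`,
  `correlation_network()` — graph construction and Laplacians;
* `net_sevd()`, `penalized_loading_solve()`,
  `sign_adjusted_laplacian()`, `select_regularization()` — the sparse
  eigen-solver (network, ridge, L1-only, sign-adjusted and dense
  penalty variants) and its tuning;
* `spectral_distance()`, `permutation_test()`,
  `identify_differential_subnetworks()` — the two-group test;
* `generate_precision_matrix()`, `generate_scenario()`,
  `run_experiment()` — a Gaussian graphical-model simulator (random /
  cluster / scale-free / hub structures) and the identification
  experiment with accuracy, F-measure, TNR, recall and precision;
* `fit_regulatory_network()`, `split_by_quartiles()`,
  `filter_top_variance()`, `extract_top_edge_subnetworks()`,
  `run_differential_pipeline()`, `simulate_drug_response_dataset()` —
  a lasso-based drug-response pipeline from log-IC50 quartile split to
  marker table;
* a command-line wrapper (`inst/cli/netsevd`) with `simulate`, `fit`,
  `test` and `pipeline` subcommands.

## Worked example

A three-gene path `a - b - c` and its sparse spectral decomposition:

```r
library(netsevd)
W <- matrix(0, 3, 3); W[1,2] <- W[2,1] <- 1; W[2,3] <- W[3,2] <- 1
L <- normalized_laplacian(weighted_graph(W, labels = c("a","b","c")))
L$matrix
#>            a          b          c
#> a  1.0000000 -0.7071068  0.0000000
#> b -0.7071068  1.0000000 -0.7071068
#> c  0.0000000 -0.7071068  1.0000000

net_sevd(L, penalty = penalty_config(0.1, 0.1, "network"))
#> Sparse eigendecomposition (network penalty, gamma1 = 0.1, gamma2 = 0.1)
#>   components: 3  iterations: 2
#>   eigenvalues: 1 1 0
#>   nonzero loadings per component: 1 2 0
```

The dense spectrum of this path is `{2, 1, 0}`; with `gamma1 = 0.1`
the leading component keeps a single gene and its eigenvalue estimate
shrinks accordingly — sparsity trades exactness of the spectrum for
interpretability of the loadings.  With
`penalty_config(kind = "dense")` the solver reproduces `{2, 1, 0}` to
machine precision.

A two-group test on simulated data — one module with a shared
precision matrix in both groups, one module co-regulated only in group
A (group B is unit-variance noise):

```r
cfg  <- scenario_config("random", sigma2 = 1, T = 200, n_reps = 2)
dat  <- generate_scenario(cfg, seed = 1)
identify_differential_subnetworks(dat$subnetworks[c(1, 6)],
  dat$expr_A, dat$expr_B, penalty = penalty_config(0.1, 0.1, "network"),
  T = 200, alpha = 0.05, seed = 1)
#> Differential sub-network tests (alpha = 0.05 ): 1 of 2 flagged
#>  subnetwork_id n_genes   distance p_value flagged
#>       common_1      10 0.02778502     0.3   FALSE
#>     specific_1      10 1.01865539     0.0    TRUE
```

The A-specific module's spectral distance (1.019) exceeds all 200
permutation distances (`p = 0`, i.e. `p < 1/200`), while the common
module's small distance (0.028) is typical of the permutation null
(`p = 0.3`): the wiring difference, not the noise level, drives the
flag.

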