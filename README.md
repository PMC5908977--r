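# diffmod

Differential modularity analysis of paired bipartite regulatory networks.

## The problem

Condition-specific gene regulatory networks — for example transcription
factor (TF) → target-gene networks inferred separately for two disease
subtypes, treatments or tissues — often look globally similar even when the
biology differs. Standard community detection on either network alone
recovers the shared large-scale structure; subtracting the two networks
edge by edge discards decreased interactions and amplifies edge-level
noise. `diffmod` targets the question practitioners actually ask: *which
groups of regulators and genes reorganize between the two conditions?*

## The method

Given a **baseline** network (weights `w_ab`, total `m`) and a
**perturbed** network (weights `A^P_ij`, total `m_P`), both bipartite
(regulator × target) and restricted to positive weights:

1. Communities `{C}` of the baseline network are found by weighted
   bipartite modularity maximization,
   `Q = (1/2m) Σ_ij (A_ij − d_i d_j / 2m) δ(C_i, C_j)`,
   on the symmetrized adjacency.
2. The baseline weights are rescaled by `m_P / m` (so totals match), and
   each node pair gets a community-conditioned null expectation

   ```
   N_ij = ( Σ_{b∈C_j} w̃_ib ) ( Σ_{a∈C_i} w̃_aj ) / Σ_{a∈C_i, b∈C_j} w̃_ab
   ```

   with `N_ij = 0` when no baseline weight connects the two communities.
3. The **differential modularity**
   `D = (1/m_P) Σ_ij (A^P_ij − N_ij) δ(M_i, M_j)`
   is maximized over module assignments `{M}` with a deterministic
   generalized Louvain procedure that accepts the negative entries of
   `D_ij` as-is (areas of decreased edge density count against a module).
4. Every node is scored by its contribution
   `S_i = (1/m_P) Σ_j D_ij δ(M_i, M_j)`; the top-scoring target genes of
   each module are its **core genes**, the natural input for downstream
   enrichment tools.

Because the null is conditioned on baseline communities rather than on a
global random graph, small modules that form *within* conserved global
structure become detectable, and the resolution limit of plain modularity
maximization shrinks.

The two classical comparison strategies are included as benchmarks:
**edge subtraction** (cluster the positive part of `w^P − w^B`) and
**community comparison** (detect communities separately, map them with the
SVD-pseudoinverse solution of `B = A R`, and score nodes by
`S_i^(R) = Σ_k (A R)_ik B_ik`).

## Worked example

The canonical hard case for network comparison is a *decrease* in edge
weights: two dense groups A and B (10 TFs + 40 genes each, fully connected
bipartite, within-group weight 1.0) whose coupling drops from 0.8 to 0.2.
Edge subtraction in the forward direction retains nothing; community
comparison sees the same two communities in both conditions. The
differential modularity recovers the transition exactly:

```r
library(diffmod)
toy <- twoGroupToy()
res <- differentialModules(toy$baseline, toy$perturbed)
res
#> Differential module analysis
#>   baseline communities: 2; differential modules: 2
#>   module sizes: 50, 50
#>   differential modularity: 0.277778
table(membership(modules(res)), nodeClasses(modules(res)))
#>    
#>     regulator target
#>   1        10     40
#>   2        10     40
partitionAgreement(modules(res), toy$truth)$index
#> [1] 1
```

Each differential module is exactly one of the groups (10 regulators, 40
genes), and the agreement with the planted grouping is perfect (adjusted
Rand index 1). The per-gene null expectations behind this are
`N = 2/3` within a group and `8/15` across groups, so within-group pairs
contribute `D = 1 − 2/3 = +1/3` and cross-group pairs
`D = 0.2 − 8/15 = −1/3`.

Simulation-based method comparison (planted modules, optional
block-preserving resampling noise, one-sided Wilcoxon rank tests):

```r
sweep <- benchmarkSweep(sizes = c(18, 30, 54, 90), nReps = 20, resample = TRUE)
summarizeBenchmark(sweep)
```

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "diffmod.R", package = "diffmod"))')" \
  simulate two_group --out-prefix toy
Rscript .../diffmod.R run --baseline toy.baseline.tsv \
  --perturbed toy.perturbed.tsv --out-prefix res
```

writes `res.modules.tsv`, `res.scores.tsv`, `res.core_genes.tsv`,
`res.summary.json` and a manifest with input digests. Subcommands:
`run`, `compare`, `simulate`, `benchmark`; every source of randomness is
routed through `--seed` and reruns are byte-identical.

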