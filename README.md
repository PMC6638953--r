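# psychonectome

Psychological constructs measured by questionnaire batteries do not change
in isolation: mindfulness, compassion, well-being, distress and
cognitive-control subscales form a network of mutually dependent elements
— a *psychonectome* — whose architecture can reorganize under an
intervention even when mean scores tell a flat story. This package
implements the full network-analysis pipeline for pre/post questionnaire
cohorts: regularized partial-correlation network estimation from ordinal
subscale scores, topological characterization, community detection,
predictability, resampling-based stability, and pre/post comparison. It is
aimed at researchers analyzing intervention studies (the design it
emulates is an 8-week mindfulness program, N = 182, 25 subscales on
5-point scales, ~11% missing values) and at methodologists who need a
synthetic-cohort generator with *known* planted structure to benchmark any
part of that pipeline.

## The model

Each occasion's network is a Gaussian graphical model over the k = 25
subscales: an edge is the partial correlation between two constructs given
all others, so absent edges mean conditional independence. Ordinal scores
are bridged to the Gaussian model through rank-based normal scores
(Blom-offset inverse-normal transform, whose Pearson correlation matches
the Spearman correlation of the raw data). Estimation is nodewise
adaptive LASSO: for each node *j*,

1. a plain lasso of *j* on all other nodes, penalty chosen by 10-fold
   cross-validated MSE over a 50-point log-spaced grid;
2. an adaptive lasso restricted to stage-1 survivors with penalty factors
   1/|β̂₁ᵢ|, penalty again chosen by CV;
3. symmetrization by the AND rule with geometric-mean magnitude,
   w(i,j) = sign · √(β̂(j←i) β̂(i←j)), which is the partial correlation
   under the identity β(j←i) = −K(ij)/K(jj) for precision matrix K.

On top of the estimated weighted signed network the package computes
expected influence (signed one-step sum), strength, degree and hubs,
Onnela weighted clustering, global/nodal efficiency (lengths 1/|w|),
maximal-simple-path extraction, and Fruchterman–Reingold layouts.
Communities come from a signed spinglass: simulated annealing of the
Reichardt–Bornholdt Potts Hamiltonian

H(σ) = −Σ(i<j) [w⁺ − γp⁺] δ(σi,σj) + Σ(i<j) [w⁻ − γp⁻] δ(σi,σj),

with per-sign-layer configuration nulls p± and the annealing settings
γ = 1, T: 1 → 0.01, cooling 0.99, spins = 25. Robustness is assessed by
node predictability (R² from all other nodes), subject-resampling
bootstrap intervals for every edge, and case-dropping stability curves
with CS-coefficients. Missing entries are handled by multivariate-normal
EM imputation on normal scores, rounded back onto the ordinal grid.

## Worked example

```r
library(psychonectome)

res <- run_pipeline(
  pipeline_config(robustness = list(edge_boot_B = 0, case_drop_B = 0)),
  output_dir = "demo-run"
)
glance(res$networks$pre)
#> # A tibble: 1 × 7
#>   layer nodes edges potential percent positive negative
#>   <chr> <int> <int>     <dbl>   <dbl>    <int>    <int>
#> 1 pre      25   120       300    40         75       45
glance(res$networks$post)$percent
#> [1] 34.67
compare_partitions(res$partitions$post, res$truth$post$communities)
#> # A tibble: 1 × 2
#>     ari   nmi
#>   <dbl> <dbl>
#> 1     1     1
find_paths(new_psy_network(res$truth$pre$pcor))$path[[1]]
#> [1] "FFMQ-O" "MAIA"   "EQ"     "NAS"    "SCS-M"  "SCS-K"  "SCS-H"
```

The demo scenario plants two dominant chains (a transversal
mindfulness–self-compassion path with weights 0.33…0.22 and a
distress–rumination path 0.45…0.21) inside six weak construct
communities before the intervention, and five denser reorganized blocks
after it. The run simulates 182 subjects on 5-point scales with 10.8%
MCAR missingness, imputes, estimates both network layers (the 40% / 34.67%
densities above are the estimated edge fractions of the 300 possible
edges), detects communities, and writes every artifact (edge lists,
GraphML, centrality and predictability tables, partitions, paired t-tests,
a manifest with the config hash) under `demo-run/`. The post-intervention
partition recovers the five planted blocks exactly (ARI = 1); the printed
truth-layer path is the planted mindfulness chain.

`autoplot()` methods produce ggplot2 figures for networks (signed
force-directed drawing), centrality profiles (z-scored per index),
bootstrap edge intervals and stability curves; `tidy()`/`glance()` give
long-form tibbles for every result type.

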