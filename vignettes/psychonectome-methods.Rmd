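---
title: "Estimating and comparing psychometric networks with psychonectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing psychometric networks with psychonectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(psychonectome)
```

## The scientific problem

A questionnaire battery administered before and after an intervention
yields, per occasion, a subjects × subscales table of ordinal scores. The
usual analysis compares means subscale by subscale; the network view asks
instead how the *dependence structure* among constructs is organized and
how it reorganizes. This package treats each occasion as one layer of a
Gaussian graphical model (GGM) over the 25 subscales, where edges are
partial correlations — the association between two constructs after
conditioning on all others — so that the network separates direct from
merely transitive relationships.

## The estimator and its assumptions

**Ordinal–Gaussian bridge.** The GGM is a model for multivariate Gaussian
data; 5-point Likert subscale scores are not Gaussian. We assume a
Gaussian copula: an underlying continuous latent trait per subscale,
observed after monotone discretization. Rank-based normal scores
(`normal_scores()`, Blom offset `qnorm((rank - 3/8)/(n + 1/4))`,
mid-ranks for ties) recover the latent scale up to monotone
transformation; their Pearson correlation tracks the Spearman correlation
of the raw codes to within ~0.01 at n = 1000. Subject-level scores (not
just a correlation matrix) are needed because penalty selection uses
cross-validation over subjects.

**Nodewise adaptive LASSO.** Each node is regressed on all others
(`estimate_network()`): a plain lasso stage with the penalty chosen by
10-fold cross-validated MSE on a 50-point log-spaced grid spanning
`[1e-4 λmax, λmax]`, then an adaptive stage restricted to stage-1
survivors with penalty factors `1/|β̂₁|`. Two cross-validation rules are
exposed because they sit at opposite ends of a well-known trade-off:

* `screening = "1se"` (the default for `estimate_network()`): stage 1
  screens at the one-standard-error penalty; penalty factors come from
  the CV-minimum coefficients; stage 2 refits at its CV minimum. This
  combination keeps false edges rare while leaving recovered weights
  essentially unbiased. On a planted 25-node network with 45 edges of
  magnitude 0.2–0.31 (n = 1000, 5-point scales) it attains edge
  sensitivity ≈ 0.99 with false-discovery proportion ≈ 0.02, and on 25
  independent nodes at n = 182 it returns an essentially empty network.
* `screening = "min"` (the default for `run_pipeline()`): the CV-minimum
  penalty throughout. This is the liberal variant implemented by the
  classical adaptive-lasso GGM tools used in the questionnaire-network
  literature; it reproduces the dense networks those studies report
  (20–40% of the 300 possible edges at n = 182 on the demo scenario
  depending on the cohort draw — 40%/35% at the default seed, against
  roughly 44%/41% in the motivating study), at the price of many small
  false edges and visible seed-to-seed variability in the selected
  density. The pipeline mirrors the published analyses, so it defaults to
  this variant.

Weights are symmetrized by the AND rule — an edge exists only if both
directed coefficients are nonzero with equal sign — with geometric-mean
magnitude `sign · sqrt(β(j←i) β(i←j))`, which equals the partial
correlation via `β(j←i) = -K(ij)/K(jj)`. The OR rule is available behind
`rule = "or"`. With the penalty forced to zero (`lambda = 0`) the
estimator reduces to nodewise OLS and agrees with the matrix-inversion
partial correlations (`unregularized_pcor()`) to < 0.01 at n = 5000,
which the test suite uses as an oracle. An entry with `|w| < 1e-8` is an
absent edge everywhere: the lasso produces exact zeros, the epsilon only
guards float noise. The Gram-form coordinate-descent core (in C++) makes
one network fit cost O(p²) per penalty value after a single O(np²) pass,
which is what keeps the resampling analyses affordable; it matches glmnet
coefficient-for-coefficient to 1e-6 in the tests.

## Topology

`centrality_table()` reports, per node: expected influence (the signed
one-step sum of edge weights — equal to strength on all-positive
networks, smaller when negative edges are present), strength (absolute
sum), degree (edges with `|w| ≥ 1e-8`), weighted clustering and nodal
efficiency, plus the network's global efficiency. Betweenness and
closeness are deliberately not computed (their instability on
questionnaire networks is the reason expected influence is used instead).
Choices the literature leaves open, recorded in the output metadata:

* clustering is the Onnela form on max-normalized absolute weights
  (Barrat's variant behind `variant = "barrat"`); signs are dropped.
* shortest-path lengths use `1/|w|`; disconnected pairs contribute zero
  to efficiency.
* hubs are nodes at or above the 90th percentile of the degree
  distribution (ties included), configurable via `percentile`.

`find_paths()` formalizes the visual path-tracing of published network
figures: edges below `threshold` (default 0.15, just under the weakest
printed chain edge of 0.18 in the motivating study) are dropped, all
maximal simple paths are enumerated, ranked by total absolute weight, and
up to `max_paths` node-disjoint paths of ≥ 2 edges are picked greedily,
ties broken lexicographically so the result is deterministic and
relabeling-invariant. On dense networks the number of maximal simple
paths grows combinatorially, so enumeration carries a deterministic
budget (`max_explored`, default 50 000 paths) and warns when it is hit.
Path extraction is meaningful on sparse, strongly-thresholded structure;
on a 40%-dense estimated network it describes only the strongest backbone.

## Communities

`spinglass()` minimizes the signed Reichardt–Bornholdt Potts Hamiltonian
with per-sign-layer configuration-model nulls (`p±(ij) = s±(i) s±(j) /
2W±`), by single-node Metropolis sweeps under geometric cooling — by
default γ = 1, start temperature 1, stop 0.01, cooling 0.99, spins = 25,
and one sweep per node per temperature step. These annealing settings are
the ones conventional for 25-node questionnaire networks. The annealer is
seeded and deterministic; `restarts` (default 10 in the pipeline, 1 for
unit-scale work) keeps the best of m seeded runs by final Hamiltonian. On
8-node planted two-block instances it reaches the exhaustive minimum over
all 4140 partitions in ≥ 95% of seeds, and it always separates
disconnected positive cliques. `compare_partitions()` gives the adjusted
Rand index and normalized mutual information.

## Robustness

`predictability()` reports per-node R² from an OLS regression of each
node's normal scores on all others — an absolute interconnectedness
measure (all nodes treated as Gaussian on the transformed scale; the
values are invariant to monotone rescaling of any column).
`bootstrap_edges()` resamples subjects with replacement and re-runs the
full estimation per replicate; per-edge 95% percentile intervals are
widened, if necessary, to contain the full-sample point estimate.
Replicates run on indexed seed substreams, so results are independent of
scheduling. Interval coverage is calibrated on the Gaussian scale: a
planted partial correlation of 0.3 (n = 500, B = 200, pipeline estimator)
is covered by ~95% of intervals. On 5-point ordinal data all
rank-based quantities estimate the *attenuated* ordinal-scale association
(about 4–8% below the latent value at L = 5), which is a property of the
scale, not of the bootstrap. `case_drop_stability()` drops growing
fractions of subjects, re-estimates, and correlates each centrality
vector with the full-sample one; the CS-coefficient is the largest drop
proportion whose correlation stays ≥ 0.7 in ≥ 95% of subsamples (both
constants configurable).

## Pre/post comparison

`paired_t()` runs per-subscale paired Student t-tests on the raw (not
transformed) scores, matched by subject id, with raw p-values by default
(`adjust = "holm"` available) — mirroring how intervention tables are
reported. `centrality_change()` gives post-minus-pre deltas and the top
five movers per index; `layer_correlation()` correlates the vectorized
upper-triangle edge weights and each centrality index across layers, low
values indicating reorganization; `compare_pre_post()` bundles these with
the partition agreement.

## The synthetic-cohort generator

Because the motivating study's raw data are not deposited, the generator
is a first-class module. `make_planted_network()` encodes a target sparse
signed partial-correlation structure as a unit-diagonal precision matrix
(chains, community blocks, single edges; explicit edges take precedence
over block fill-in). If the assembled matrix is not positive definite,
the smallest ridge lifting the minimum eigenvalue to 1e-6 is applied and
the matrix re-standardized; the *realized* (possibly shrunken) partial
correlations are the declared truth for every recovery experiment, so
tests never chase an unattainable target. For diagonally dominant
structures the realized weights equal the requested ones exactly.
`random_planted_network()` draws benchmark truths as degree-capped
near-regular graphs with per-node weight budgets, which keeps the
precision matrix comfortably positive definite — a uniformly random
support with all |pcor| ≥ 0.2 at 15% density is nearly never PD, and
minimal-ridge repair of such a structure produces a degenerate latent
correlation that no estimator can recover from.

`sample_cohort()` draws latent multivariate-normal vectors with the
implied correlation and discretizes each margin at equal-probability
normal thresholds (L = 5 by default; skewed margins via `thresholds`;
L = 0 keeps the continuous scores; the latent draws travel with the
cohort for imputation-recovery checks). `make_pre_post()` couples the two
occasions through a shared subject-level component so each node's
pre/post latent correlation equals `subject_rho` when the two layers
share a network (the study design gives no empirical anchor for this
dependence; the default 0.5 represents moderate trait stability and
affects only paired analyses, not either layer's marginal structure).
`apply_mcar()` masks cells independently of everything at the study's
overall missingness rate (10.8% by default). What the generator does
*not* emulate: item-level responses (subscales are the atoms), skewed
margins by default, non-random missingness, measurement drift between
occasions. Passing recovery tests on these cohorts therefore demonstrates
correctness of the machinery under the Gaussian-copula design, not
robustness to MNAR or item-level pathologies.

The packaged demo (`demo_scenario()`) plants, pre-intervention, the two
dominant chains reported for the motivating study's baseline network
(0.33, 0.29, 0.22, 0.23, 0.25, 0.22 across mindfulness/self-compassion;
0.45, 0.18, 0.20, 0.21 across distress/rumination) inside six construct
communities whose within-block partial correlation (0.12) deliberately
sits below the 0.15 path threshold, plus two negative
distress–mindfulness edges; post-intervention, five reorganized blocks at
0.18. At n = 182 the estimated *post* layer recovers its planted
communities exactly (ARI = 1), while the weak pre blocks are only
partially recoverable from an estimated layer (ARI ≈ 0.7 with the
pipeline estimator; 1.0 from the truth layer): six communities held
together by 0.12 partial correlations are at the edge of detectability at
this sample size, which is itself an instructive property of the design.

## Preprocessing

`em_impute()` runs multivariate-normal EM on the normal scores
(convergence when the relative observed-data log-likelihood change drops
below 1e-6, at most 100 iterations, warning and best iterate otherwise;
zero-variance columns are dropped with a warning), then maps conditional
means back to the nearest observed ordinal category; observed entries are
never altered. Under 10.8% MCAR on a 25-node planted cohort the
post-imputation Spearman matrix stays within 0.05 of the complete-data
one. `spearman_matrix()` (mid-rank, pairwise-complete, eigenvalue-clipping
PSD repair with a logged flag) is the correlation input of record;
`polychoric_matrix()` implements the two-step pairwise estimator
(thresholds from marginal cumulative proportions, then bounded
likelihood maximization to tolerance 1e-6) for internal-consistency work:
`cronbach_alpha()` is the standardized alpha `k r̄ / (1 + (k-1) r̄)` on
any correlation subset. The two-step (not joint-ML) polychoric is the
standard, fast choice adequate at n ≈ 182.

## Numerical choices and degenerate inputs

* Coordinate descent converges on a coefficient-change tolerance of 1e-6
  with warm starts and active-set cycling; CV folds are fixed by the seed
  and shared across nodes.
* PD repairs: generator, minimal ridge to eigenvalue 1e-6; correlation
  matrices, eigenvalue clipping then re-standardization (flagged).
* Constant columns: errors naming the column (correlations, scores), or
  dropped with a warning (imputation); bootstrap replicates with constant
  columns are redrawn (at most 10 times, logged).
* Edgeless networks: singleton communities with a warning; efficiency and
  clustering are 0; layouts still render.
* Ties everywhere are broken deterministically (mid-ranks, lexicographic
  path order, first-appearance community relabeling).

## Problem sizes used by the packaged checks

The test suite and the acceptance script exercise the pipeline at the
scale the package targets: 25-node cohorts at n = 182 and n = 1000,
oracle comparisons at n = 5000, bootstrap coverage at n = 500 with
B = 200 over 100 repetitions, case-dropping at desk scale (B ≤ 25 in unit
tests), and 1000-run t-test calibration. These sizes are the package's
own benchmarking choices; all of them regenerate their data on the fly
from seeds.

## Known limitations

* Estimation assumes a Gaussian copula; severely skewed margins or
  item-level floor effects are outside the generator's emulation.
* The two CV rules bracket, but do not resolve, the selection/estimation
  trade-off; no EBIC-graphical-lasso estimator is provided.
* Path extraction on dense networks is budgeted enumeration, not an
  exact search.
* CS-coefficients use the 0.7/95% convention; other conventions require
  re-running with different constants, not a reinterpretation of the
  same output.
* Paired tests are reported without multiplicity correction by default,
  matching the reporting style of intervention tables; use
  `adjust = "holm"` for confirmatory claims.
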