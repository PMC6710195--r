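---
title: "Information-flow connectivity: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information-flow connectivity: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoflow)
```

This vignette documents the scientific model behind the package, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design decisions that were genuinely
open.

## 1. The connectivity model

The package treats a multivariate time series — one row per node, one
column per timepoint — as a communication network and asks, for every
ordered node pair, how many bits per step the source can deliver to the
sink, directly or through intermediaries.

**Stage 1: capacities from transfer entropy.** The directed edge
capacity from node $A$ to node $C$ is the transfer entropy

$$TE_{A\to C} = \sum p\!\left(C_{n+1}, C_n^{(k)}, A_n^{(l)}\right)\,
  \log \frac{p\!\left(C_{n+1} \mid C_n^{(k)}, A_n^{(l)}\right)}
            {p\!\left(C_{n+1} \mid C_n^{(k)}\right)},$$

the reduction in uncertainty about the target's next value obtained
from the source's past over and above the target's own past ($k$ and
$l$ are the history lengths). TE is a *predictive*, not causal,
quantity: it measures statistical transfer under observation, without
intervention, and is directional ($TE_{A\to C} \neq TE_{C\to A}$ in
general). It is nonnegative in theory but its estimators are not — an
estimate near zero can come out negative — so negative estimates are
treated as measurement error and clipped to zero, yielding the sparse
TE matrix.

**Stage 2: connectivity from maximum flow.** The sparse TE matrix is
the adjacency matrix of a directed capacity graph, and connectivity
from $i$ to $j$ is the maximum flow between them. The classic toy
example: with edges $A\to C$ of capacity 2, $A\to B$ of 3 and $B\to C$
of 3, the flow from $A$ to $C$ is 5 — the direct 2 plus 3 along the
indirect path. Flow-based connectivity therefore credits node pairs
that are joined by many strong indirect routes, which plain pairwise
coupling measures ignore. The max-flow value is unique (it equals the
minimum cut capacity) even though optimal flow assignments are not, so
the measure is well defined regardless of algorithm.

Three variants are computed. The *unrestricted* full matrix uses the
whole graph for every pair. The *restricted* full matrix allows, for a
pair $(A, C)$, only edges whose tail lies in $A$'s macroscale group and
whose head lies in $C$'s group (the within-group edge set when the two
groups coincide); this confines flow to the anatomical route of
interest and makes the group reduction well defined. The *reduced*
matrix sums restricted flows over ordered group pairs; its diagonal
holds within-group totals. With the standard scheme of 10 lobes per
hemisphere (20 groups), 71,824 node-pair cells reduce to 400 group
flows, a feature space small enough for cohort-level modeling without
aggressive regularization.

## 2. The KSG estimator

Continuous-valued TE is estimated with the Kraskov–Stögbauer–
Grassberger nearest-neighbor method, algorithm 1, written as the
conditional mutual information
$I(C_{n+1};\, A_n^{(l)} \mid C_n^{(k)})$:

$$\widehat{TE} = \psi(k_{nn}) - \Big\langle
  \psi(n_{xz}+1) + \psi(n_{yz}+1) - \psi(n_z+1) \Big\rangle,$$

where $\varepsilon_i$ is each point's distance to its $k_{nn}$-th
nearest neighbor in the joint embedding space under the max-norm, and
the $n_\bullet$ count neighbors strictly inside $\varepsilon_i$ in the
marginal subspaces. Estimation runs in nats and is converted to bits by
default, the unit in which flows are reported.

Parameters, defaults and rationale:

* `k_neighbors = 4` — the convention of the widely used information-
  dynamics toolkits; small $k$ keeps bias low at the cost of variance,
  which the downstream clipping and cohort averaging tolerate.
* `history_target = history_source = 1` — lag-1 embeddings. The
  synthetic ground truth is a lag-1 process, and for slow, temporally
  smoothed signals such as parcellated fMRI a single-step history is
  the standard starting point. Longer embeddings are supported.
* `jitter_sd` — seeded Gaussian micro-noise of amplitude $10^{-8}$
  times each series' sd, added before the neighbor search to break
  exact distance ties on discretized data. The amplitude is far below
  any signal scale; given the config seed the estimate is
  deterministic.
* Distance metric: max-norm in the joint space, per the original KSG
  construction.

Self-TE is defined as 0 and never estimated. The estimator's accuracy
is verified against an exact oracle: for a stationary Gaussian VAR
process,

$$TE = \tfrac{1}{2}\log_2
  \frac{\operatorname{var}(x^{tgt}_t \mid x^{tgt}_{t-1})}
       {\operatorname{var}(x^{tgt}_t \mid x^{tgt}_{t-1}, x^{src}_{t-1})},$$

with conditional variances taken from the stationary covariance (the
solution of the discrete Lyapunov equation) by Schur complements. At
$T = 10{,}000$ and $k_{nn} = 4$ the mean absolute error across seeds
and couplings up to 0.6 is about 0.01 bits.

## 3. The synthetic-data generator

`simulate_var_panel()` draws from $x_t = C^\top x_{t-1} + \varepsilon_t$
with spectral radius below 1, initialized from the exact stationary law
plus a 100-step burn-in: every retained sample is stationary by
construction. `random_var_model()` provides sparse random couplings
rescaled to a target spectral radius (default 0.7 — strong enough for
detectable transfer, far enough from instability that per-subject
jitter keeps models stationary).

`simulate_cohort()` emulates a study cohort: each subject's coupling
matrix is the template perturbed by multiplicative Gaussian jitter
(default 10%), the per-subject reduced flow matrix is computed by the
*real* pipeline (KSG, clipping, restricted flow, reduction), and the
behavior score is a planted weighted sum of reduced flow cells plus
Gaussian noise. The jitter is what creates the inter-subject flow
variance the predictive model exploits; `noise_relative = TRUE` lets
the score noise be specified as a multiple of the realized signal sd,
which is how recovery conditions are naturally stated.

A nonlinear fixture, `simulate_threshold_pair()`, generates
$y_t = c\,\mathbf{1}\{|x_{t-1}| > \theta\} + \sigma\eta_t$ with a
Gaussian white-noise source. Because the response is an even function
of a symmetric source, the Pearson correlation between the series is
zero at every lag while the information transfer is large (about 0.8
bits at the defaults) — the canonical demonstration that TE captures
coupling invisible to correlation. A threshold response on a
*one-sided* chaotic map was considered and rejected: a monotone
response keeps a strong linear correlation and thus cannot demonstrate
the point.

What the generator does **not** emulate: hemodynamics, measurement
noise spectra, spatial voxel structure, inter-regional delays beyond
one step, or nonstationarity. Passing tests therefore certify the
pipeline's statistical machinery — estimator consistency, flow
computation, selection, cross-validation, calibration — not its
behavior on real fMRI, where preprocessing and physiological
confounds dominate.

## 4. The predictive model

The CPM layer works on the flattened reduced flow matrix (row-major,
diagonal included, 400 features under the 20-group scheme, in a
documented stable order):

1. **Selection.** Two-sided Spearman correlation of every flow with the
   behavior score; keep flows with $p \le \alpha$ (default 0.05,
   asymptotic $t$ approximation — appropriate for cohort sizes in the
   dozens; constant features are never kept). An optional prior filter
   drops flows correlated with any nuisance covariate (e.g. head-motion
   summaries) at the same threshold.
2. **Aggregation.** PCA of the selected flows, centered but not
   variance-scaled — the features share a unit (bits), and scaling
   would inflate near-constant flows; a scaling switch is deliberately
   not exposed to keep serialized models unambiguous.
3. **Component count.** Chosen by an inner leave-one-out loop over
   candidates $1..\min(n_{train}-1, n_{selected})$, scored by Spearman
   correlation of the inner left-out predictions with behavior; ties go
   to the smallest count (parsimony, reproducibility). The upper bound
   is the PCA rank limit after centering — candidates cannot exceed it
   even though "up to the number of subjects" is the looser folk rule.
4. **Regression and z-scoring.** Ordinary least squares of behavior on
   the component scores. Predictions for new subjects are z-scored
   against the *training subjects' own leave-one-out predictions*
   (each made by a model fit without that subject, under the final
   mask and component count) — so the z-score locates a new subject
   within the distribution of honestly cross-validated training
   predictions rather than optimistic in-sample fits.

**Validation.** `loocv_internal_validation()` redoes the entire
pipeline inside every fold — selection, component choice, PCA,
regression — so the left-out subject influences nothing; the test suite
audits this by refitting each fold independently and comparing
parameters bit for bit, and by corrupting the left-out row and
verifying the fold is unchanged. `permutation_test()` reruns the full
pipeline per permutation (preserving exchangeability) and reports
$p = (1 + \#\{\rho_{perm} \ge \rho_{obs}\})/(1 + B)$, one-sided in the
direction of the trained association, with the add-one correction so a
finite $B$ never yields $p = 0$; two-sided and fixed-component-count
modes are available since it is ambiguous whether a study's permutation
loop should rechoose the component count (full rerun is the default and
the stricter choice).

**Empty selection.** On null data, often no flow passes $p \le 0.05$.
The LOOCV aborts by default (a fold with nothing selected is a
diagnostic, not a prediction), but `empty_action = "fallback"` lets a
fold keep its single best-ranked feature. The permutation test defaults
to the fallback for both the observed and permuted statistics: under
the null the statistic must remain computable and exchangeable, and the
fallback keeps it continuous, which preserves the test's nominal level
(verified by Monte-Carlo calibration in the test suite: at
$\alpha = 0.05$ the empirical type-I rate over 100 null cohorts stays
inside the binomial 95% band).

## 5. Numerical choices and degenerate inputs

* Zero-capacity edges are dropped at graph construction — identical
  flow values on smaller graphs; a group containing a single node has
  an empty within-group edge set and zero within-group flow.
* Flow values are reproducible across runs to floating-point
  tolerance; the matrix drivers share one prebuilt graph per edge set
  (one per ordered group pair in the restricted variant), and pair
  computations are order-independent.
* PCA rank is cut at $10^{-10}$ times the leading singular value;
  candidate component counts beyond a training block's rank reuse the
  full-rank model rather than erroring.
* Spearman ties use average ranks; a constant behavior vector yields no
  selectable feature and a clear error.
* The full information-flow matrices have a zero diagonal by
  definition (self-flow is undefined); writers emit it explicitly so a
  268-node matrix always has $268^2 = 71{,}824$ cells.
* Serialization (`write_matrix`, `write_cpm_model`) uses 17 significant
  digits / JSON without rounding, so round-trips are exact.

## 6. Problem sizes used in the tests

The suite validates at sizes a laptop handles comfortably: estimator
consistency at $T = 10{,}000$ over 10 seeds and three couplings;
planted-effect recovery on 20 cohorts of 20 subjects (12 nodes, 4
groups, score noise 0.1 times signal sd, $T = 250$); permutation
calibration on 100 null cohorts of 20 subjects (8 nodes, $T = 150$,
200 permutations each); the min-cut oracle on 200 random graphs of up
to 6 nodes. These sizes were chosen so each check's Monte-Carlo error
is small relative to its acceptance margin.

## 7. Known limitations

* Pairwise TE only: multivariate/conditional TE, spectral variants and
  per-edge significance testing are out of scope, so common-driver
  effects appear as (predictive, not causal) transfer.
* The lag-1 Gaussian oracle cannot certify the estimator on processes
  with long memory or heavy tails; the nonlinear fixture covers one
  qualitative regime only.
* Max flow is the only routing model; minimum-cost and multi-commodity
  formulations are not provided.
* The brute-force min-cut oracle is exponential and only guards graphs
  of a few nodes; larger graphs rest on the max-flow/min-cut theorem
  and the library implementation.
* Rank-correlation evaluation is insensitive to calibration of the
  predicted scale; absolute-error metrics are deliberately not
  reported.
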