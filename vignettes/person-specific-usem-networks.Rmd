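---
title: "Person-specific directed connectivity with unified SEM: models, search, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-specific directed connectivity with unified SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`usemnet` estimates, one person at a time, a directed network among $p$
regions of interest (ROIs) from their BOLD time series. The model is the
unified structural equation model (uSEM), a structural VAR of order one:

$$\eta_t = A\,\eta_t + \Phi\,\eta_{t-1} + \zeta_t, \qquad
\zeta_t \sim \mathcal N(0, \Psi),\ \Psi \text{ diagonal},$$

where $A$ holds *contemporaneous* directed paths (same volume; no
self-paths) and $\Phi$ holds *lagged* paths (previous volume to current;
the diagonal of $\Phi$ are the autoregressive, AR, paths). Estimation
treats the lagged-augmented observation $(\eta_{t-1}, \eta_t)$ as a
$2p$-variate vector: lagged pairs are formed within runs only (a pair
never spans a run boundary; two runs of length $T$ give an effective
$N = 2(T-1)$), columns are mean-centered over the pooled pairs, and the
ML discrepancy

$$F_{\mathrm{ML}} = \log|\Sigma(\theta)| - \log|S| +
\operatorname{tr}\!\big(S\,\Sigma(\theta)^{-1}\big) - 2p$$

is minimized with the covariance of the lagged (predictor) block
saturated. The model chi-square is $(N-1)\,F_{\mathrm{ML}}$. Means are
not modeled; centering is the conventional choice and this package makes
it explicitly (standardization of the series is left to the user, and the
generator emits raw series).

## How the likelihood is actually minimized

Profiling the saturated predictor block ($\hat V = S_{11}$) and the
diagonal $\Psi$ ($\hat\psi_j$ = residual variance of equation $j$)
reduces the discrepancy to

$$F(A, \Phi) = \sum_j \log g_{jj}(A, \Phi) - 2\log|\det(I - A)| -
\log|S_{22\cdot1}|,$$

with $g_{jj}$ the structural residual variance of equation $j$. Two
classical facts shape the implementation:

* when the contemporaneous graph is **acyclic**, $\det(I-A) = 1$ and the
  minimizer is exactly per-equation least squares (the recursive
  path-model result) — no iteration at all;
* in general, the determinant factors over the **strongly connected
  components** of the contemporaneous graph, so only the equations inside
  a cycle block are coupled. Within a block, every coefficient other than
  the in-block contemporaneous ones is profiled out analytically (a Schur
  complement), and a damped Newton iteration with analytic gradient and
  Hessian runs in the few remaining dimensions, with a quasi-Newton
  fallback.

Reciprocal contemporaneous pairs deserve a note: with weak lagged
instruments the two directions are only weakly identified, and the
profile likelihood develops a flat ridge. The optimizer accepts the
ridge value (which is the correct minimized discrepancy), and standard
errors are taken from an eigendecomposition pseudo-inverse of the
observed information, so nearly unidentified paths carry very large
standard errors and $z \approx 0$ — they are then removed by the
pruning z-tests rather than crashing the search.

Degrees of freedom follow the lagged-block convention: of the
$p(2p+1)$ unique moments of the $2p$ block, $p(p+1)/2$ are fixed by the
saturated predictor block; the remainder minus the free parameters
(paths plus $p$ residual variances) is the df. At $p = 10$ this gives
$145$ df for the AR-only null model and $145 - k$ for $k$ non-AR paths.

## Fit indices

`fit_indices()` computes the standard set against the baseline model
with no structural paths (free diagonal $\Psi$, saturated predictor
block): RMSEA $= \sqrt{\max(\chi^2 - df, 0)/(df\,(N-1))}$ (0 when
$df = 0$), SRMR as the root mean square of standardized residuals over
the unique moments of the full $2p$ block, CFI (clamped to $[0,1]$) and
NNFI/TLI (unclamped; reported as 1 with a flag for a saturated model).

# The two-stage search

The search mirrors the group-iterative strategy used for person-specific
connectivity (GIMME): structure is discovered from the data, but paths
supported by most of the sample enter everyone's model first, and all
weights are always estimated per person.

**Scores.** A candidate path's score is the exact chi-square drop from
freeing that single path (the likelihood-ratio form of the modification
index / Lagrange multiplier statistic), with a $\chi^2_1$ p-value.
Because the profiled likelihood separates over equations and cycle
blocks, a score is a one-equation least-squares update in the common
case and a small block re-optimization otherwise; after an addition,
only scores the new path could have changed are recomputed.

**Group stage** (`group_search()`): starting from the AR-only null
model, the candidate significant (at `alpha_mi`, default .05) for the
most participants is added to *every* participant's structure whenever
that count reaches `ceiling(group_threshold * n)` — 9 of 11 at the
default 75% threshold. Ties are broken by the larger summed score, then
lexicographically by (lag, source, target) for determinism. When no
candidate reaches the criterion, group paths whose estimated weight is
significant (two-sided z at `alpha_prune`) for fewer than the criterion
count are pruned — stepwise, weakest first, refitting between removals,
because removing one member of a collinear pair (typically the reverse
direction of the same pair) changes the z-tests of the rest. When the
path about to leave has its contemporaneous reverse twin in the model,
the pair is weakly identified and their z-tests cannot tell the
directions apart; the likelihood can, so whichever direction costs the
sample fit less is the one removed. AR paths are never pruned. Participants whose model fails to converge at a step
are excluded from that step's counts (logged); the search aborts if more
than a quarter fail.

**Individual stage** (`individual_search()`): per participant, the
largest significant candidate is added until the model "fits well" —
operationalized, as is conventional for this procedure, as at least 2 of
the 4 excellent-fit cutoffs (RMSEA $\le .05$, SRMR $\le .05$, CFI
$\ge .95$, NNFI $\ge .95$) — or no significant candidate remains, or
`max_iterations` is reached. Non-significant individual paths are then
pruned stepwise (group and AR paths never). A non-converged addition is
rolled back and flagged. Every final network contains every group path
by construction.

Two conventions the procedure leaves open were decided as follows and
are exposed in `search_config()`: the "at least 75%" criterion is
integerized by the ceiling (9 of 11), and modification-index p-values
are used per candidate without multiple-testing correction, mirroring
the reference implementation's default (`mi_correction = "bonferroni"`
is available). Group pruning is on by default (`prune_group`).

# Network metrics

`compute_metrics()` reduces a person's network to its **complexity**
(total number of estimated connections, AR included by default) and
three **subnetwork densities**: the number of non-AR connections with
both endpoints in the mental rotations network (MRN), both in the
default mode network (DMN), or one in each, divided by complexity.
Contemporaneous and lagged connections between the same pair count as
two (they are separate estimated parameters). AR self-loops count toward
complexity but toward none of the three densities under the default
rule — with 10 AR paths in a 35-connection network the three densities
then sum to about .71, matching how the published averages behave; the
`count_ar_in` flag (`"complexity"`, `"densities"`, `"neither"`) exposes
the alternatives.

# The synthetic-data generator

Real multimodal fMRI/hormone data of this kind are restricted, so
`generate_truth()`, `simulate_timeseries()` and `generate_covariates()`
produce complete synthetic studies with a known ground truth. The
defaults *are* the emulated study conditions and are not tuned
per-analysis:

* $n = 11$ participants, 10 ROIs (6 MRN, 4 DMN), two runs of 134
  volumes, concatenated downstream;
* a shared group structure of 12 non-AR paths (6 within-MRN, 3
  within-DMN, 3 between) plus 10–15 person-unique paths per participant
  placed with block probabilities .48/.24/.28 — chosen once so that
  total estimated connections land near a complexity of 35 with
  within-MRN density above the between-network and within-DMN densities;
* path weights of magnitude $U(0.3, 0.6)$ with random sign, positive AR
  weights $U(0.3, 0.6)$, unit innovation variances (diagonal $\Psi$ is
  the standard uSEM noise assumption; the generator mirrors it);
* 25% of planted non-AR paths are lagged.

Individual-level paths are meant to be *person-unique* (that is what
individual-level heterogeneity means in this design), but the within-
block path pools are small — the within-DMN block has only 24 ordered
pair-lag slots for roughly 33 draws across the sample — so sampling
down-weights any slot already used by another participant (factor 0.25
per prior use) and reuses slots only when the pool forces it.
Contemporaneous reciprocal pairs are avoided within a participant by
default (`allow_reciprocal`).

Weights are rejection-resampled per participant until $(I - A)$ is
invertible and the induced lag-1 system has spectral radius below 0.95 —
a numerical margin strictly inside the stationarity requirement — with a
bounded number of tries. Runs are simulated as independent realizations
(each with its own burn-in of at least 50 discarded steps) because the
real runs were acquired separately and concatenated after processing.

Hormones (estradiol, progesterone, testosterone, in pg/mL) are drawn
from zero-truncated Gaussians. Because truncation at zero inflates the
mean of a Gaussian (by about 3% at the progesterone mean/SD ratio), the
underlying Gaussian mean is moment-matched by root-finding so the
*truncated* distribution has exactly the target mean. Task performance
(% correct) is Gaussian clipped to $[0, 100]$. The `coupling` parameters
plant correlations between a variable and the participant's true number
of individual-level paths; the default couples task performance at
$\rho = 0.5$ (a moderate-to-strong positive performance–complexity
association, the pattern the analysis is designed to recover) and leaves
hormones uncoupled.

What the generator does **not** emulate: hemodynamic convolution,
scanner drift, motion, physiological noise — BOLD realism beyond the
lag-1 structure. Passing tests therefore show that the pipeline recovers
the model class it assumes; they do not certify behavior under real
scanner artifacts.

# Multimodal statistics

`describe_sample()` gives means and $n-1$ SDs of the hormone and
behavior records; `correlate_multimodal()` joins them with the network
metrics on participant id (the join must be total) and returns the
Pearson correlation matrix over task performance, the three hormones,
complexity, and the three densities, with pairwise-complete handling of
missing values and per-cell $n$. Pearson is the default because the
published matrix is a continuous color-coded display without a named
estimator; Spearman is available by flag. No significance testing is
attached — at $n = 11$ the matrix is descriptive.

# Numerical choices and degenerate inputs

* Convergence: Newton tolerance $10^{-9}$ on the gradient, with up to 3
  jittered quasi-Newton restarts; coefficients are bounded by $\pm 10$.
* Candidate additions that would push df below zero (or exceed the
  effective N) are reported as unscoreable (`NA`).
* Zero-variance variables yield missing correlation cells with a
  warning; a zero-complexity network reports densities of 0 with a
  degeneracy flag.
* Runs shorter than 2 volumes, missing values, unknown ROI labels,
  ragged or non-numeric CSV cells are classed errors naming the file
  and offending column/line.
* All randomness flows through explicit integer seeds; the pipeline
  derives stage seeds (truth: `seed`, series: `seed + 1`, covariates:
  `seed + 2`) from one master seed, and reruns are byte-identical for
  every analysis output.

# Problem sizes used in the checks

The packaged checks exercise the study scale the package targets:
estimation oracles on 2–3 ROI systems (up to $T = 10\,000$ for weight
recovery), the modification-index contract on 2–4 ROI systems against
brute-force refits, null-model specificity over 20 generator seeds and
truth recovery over 10 seeds at the full paper scale ($n = 11$, $p = 10$,
$2\times134$ volumes), and end-to-end determinism on a 6-participant
configuration. These sizes are the package's own choices, balancing
statistical resolution of each property against a test suite that runs
in minutes.

# Known limitations

* Direction resolution for contemporaneous paths rests on the lagged
  instruments; with modest series lengths a small fraction of
  contemporaneous group paths can be recovered with flipped direction,
  and the reverse member of a reciprocal pair is only weakly identified.
* At the emulated heterogeneity density (about 12 person-unique paths
  per participant at $T = 268$), unmodeled individual structure leaks
  into the group-stage counts: the group stage can temporarily over-add
  and then prune, and a small number of surviving group paths may
  reflect shared indirect structure rather than planted group paths.
  With sparse heterogeneity (up to ~6 unique paths per person) group
  recovery is essentially perfect.
* Only lag-0/lag-1 structure is modeled: no exogenous task regressors,
  higher-order lags, or non-Gaussian likelihoods.
* The search is greedy; it returns one well-fitting model per person,
  not an equivalence class.
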