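---
title: "Latent functional connectivity: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent functional connectivity: model, estimation, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Functional connectivity (FC) — the zero-lag Pearson correlation between two
brain regions' activity time series — is usually estimated from a single brain
state, most often rest. But any single state's FC confounds three sources of
variance: connectivity that persists across states ("intrinsic" FC),
state-specific reconfiguration, and estimation noise. This package treats the
problem as one of psychometric measurement. For each network edge, the FC
values observed across $S$ brain states are modelled as indicators of a single
latent variable:

$$ y_{is} = \lambda_s \, \eta_i + \varepsilon_{is}, \qquad
   \operatorname{Var}(\eta) = 1,\;
   \operatorname{Var}(\varepsilon_{s}) = 1 - \lambda_s^2
   \text{ (standardized metric)}, $$

where $y_{is}$ is subject $i$'s FC at that edge in state $s$, $\eta_i$ is the
subject's latent (state-general) connectivity, $\lambda_s$ is the state's
loading, and $\varepsilon_{is}$ collects state-specific deviation plus noise.
An independent single-factor model is fit for every edge; the matrix of
regression-method factor scores $\hat\eta$ across edges is the subject's
*latent FC*. Setting every $\lambda_s = 1$ and every uniqueness to zero gives
the restricted model whose scores are exactly the across-state average —
`average FC` — which is therefore a special case, not a rival framework.

Assumptions worth stating plainly: linearity of the indicator model, a single
common factor per edge, Gaussian unique parts, independence of edges (each
edge is fit alone; nothing borrows strength across edges), and enough states
($S \ge 3$) for identification. $S = 2$ is refused rather than special-cased.

## Estimation

**Extraction.** The default extractor is minres: minimize the off-diagonal
squared residuals of the indicator correlation matrix against
$\lambda\lambda'$. It is parameterized over the uniquenesses $\psi$, with the
loading taken from the leading eigen-pair of the correlation matrix whose
diagonal is replaced by the communalities $1 - \psi$. This parameterization
matters: a direct search over $\lambda$ has a degenerate direction (a loading
vector concentrated on a single indicator leaves all off-diagonal products
zero), which the $\psi$ parameterization avoids. Gaussian maximum likelihood
is available via `method = "ml"`, implemented through the concentrated
likelihood over $\psi$; it agrees with `stats::factanal` to about $10^{-4}$ on
sampled data, and with minres to $10^{-3}$ on well-conditioned population
matrices.

**Convergence and floors.** L-BFGS-B with a gradient tolerance derived from
`tol = 1e-8`, an iteration cap of 1000, and one restart from the first
solution (the restart absorbs the optimizer's occasional premature line-search
stop at very tight tolerances). Uniquenesses are bounded below by the Heywood
floor `0.001`; any solution at the floor (or implying $\lambda^2 > 1 -$
floor) is flagged `heywood`. A genuinely structureless correlation matrix is
an instructive degenerate case: the true least-squares optimum on *sampled*
independent indicators concentrates the factor on one indicator with its
uniqueness at the floor. The package returns that optimum, flagged, rather
than pretending the loadings are zero; on the exact population identity
matrix the loadings are zero.

**Scores.** Regression-method (Thurstone) scores, $W = R^{-1}\lambda$ applied
to column-standardized indicators, then standardized to mean 0, SD 1 across
subjects. A numerically singular $R$ falls back to a ridge-jittered inverse
with a warning. Loadings are sign-aligned so $\sum_s \lambda_s \ge 0$.

**The group matrix.** Standardized factor scores average to zero across
subjects by construction, so a group-level matrix cannot be the mean
standardized score. The group latent FC matrix is instead computed in the raw
FC metric: each edge's score weights are normalized to sum to one and applied
to the raw indicators, then averaged over subjects. Under equal weights this
reduces exactly to the group average-FC matrix; unequal weights tilt each
edge toward the states that load more strongly.

**Per-edge failures.** Edges whose indicators have zero variance, or whose
fit errors or fails to converge, fall back to the restricted (average) scores
and are flagged; the count is reported. Downstream matrices therefore stay
complete.

**Leave-one-state-out (LOSO).** `latent_fc(stack, exclude_state = s)` drops
state $s$ from the indicator set *before* any fitting, so predictions of the
held-out state are non-circular by construction. The test suite verifies
that corrupting the held-out slice changes nothing in the fit.

## Preprocessing conventions

The design-construction functions encode the standard recipe for
parcellated BOLD: 6 motion parameters, their derivatives, and the quadratics
of all 12 (24 motion regressors), then 5 white-matter + 5 ventricle aCompCor
components, derivatives, and quadratics of all 20 (40 physiological
regressors) — 64 nuisance columns in total. Derivatives are backward first
differences with a leading zero (length-preserving, the common fMRI
convention); quadratics are computed after derivative construction, which is
what makes the 24/40 bookkeeping come out. Task designs use an FIR basis:
one indicator column per within-block timepoint offset per condition, pooled
across blocks of that condition, plus 25 post-offset lag columns for the
hemodynamic tail; a condition with 10-TR blocks therefore owns 35 columns.
TR indices are 0-based and blocks are half-open `[onset, onset + duration)`
throughout. Runs are z-normalized per run and per region before
concatenation; task FC uses on-task TRs only.

TR-budget matching uses the deterministic first-N rule — the first eligible
TRs in scan order — with defaults of 264 TRs per task (the shortest task is
the limiting factor) and $8 \times 264 = 2112$ rest TRs. Whether matched TRs
should be contiguous or sampled is genuinely open; first-N was chosen for
reproducibility, and `sample_seed` switches to seeded uniform sampling.

## What the synthetic generator emulates — and what it does not

`simulate_fc_stack()` generates indicators directly in FC space from the
factor model itself (the fast path): standardized latent scores, specified
loadings, Gaussian unique parts satisfying $\lambda^2 + \sigma^2_u = 1$.
`simulate_timeseries_from_fc()` provides the slow path — Gaussian time series
with an exact target population correlation — so the full
time-series-to-latent pipeline can be exercised end-to-end.
`simulate_actflow_activations()` inverts the activity-flow rule: it draws
input vectors $s$ and solves $(I - W)a = s$ with the connectivity weights $W$
(spectral radius rescaled to 0.9 when needed), so the activity-flow
prediction error equals the injected input *exactly* — an algebraic identity
the tests check to $10^{-10}$. `simulate_behavior()` builds a g factor as the
coupling-weighted sum of latent edge scores plus noise (by default 10% of
edges coupled at standardized weight 0.5, 11 measures loading 0.7, a fifth of
g's variance left unexplained by the brain), mirroring a typical cognitive
battery's positive manifold.

Everything is Gaussian and temporally white. Real BOLD is autocorrelated,
non-stationary, motion-contaminated, and hemodynamically filtered; none of
that is emulated, and no hemodynamic forward model is included. Passing tests
therefore certify the *statistical machinery* — identification, recovery,
calibration, non-circularity — not robustness to physiological artifact.
Seeding is strict: one integer seed expands into fixed substreams per stage
and state, so enlarging `n_states` never perturbs earlier states' draws.

## The data-quantity experiment

`data_quantity_experiment()` reproduces, from time series up, the observation
that a state estimated from more data loads more strongly on the latent
factor purely through lower estimation noise. Each subject gets an intrinsic
region-factor structure (two region factors; subject deviation SD 0.2 around
a common base), each state perturbs it slightly (loading jitter SD 0.08), and
BOLD-like series are simulated: $8 \times 264 = 2112$ TRs for rest, 264 per
task. The state jitter is deliberately small so that FC estimation noise —
the mechanism under study — dominates each state's unique variance; with
large structural state deviations the TR effect is real but masked, which is
a statement about the mechanism's visibility, not its existence. The
experiment fits the per-edge factor model twice: on the full series, where
rest's mean loading exceeds the tasks' (gap ≈ 0.06–0.09 at the default
sizes), and with rest truncated to 264 TRs, where the gap collapses toward
zero. Default sizes (60 subjects, 6 regions, 4 tasks) keep the full
experiment under a second while leaving the effect an order of magnitude
above its sampling noise.

## Inference choices

- **Similarity.** FC-pattern similarity is the Pearson correlation over
  vectorized upper-triangle edges (row-major order, one convention shared by
  every module). Comparisons across subjects use paired t tests on Fisher-z
  similarities with Benjamini–Hochberg FDR across comparisons; BH is used
  wherever "FDR" is called for.
- **Activity-flow evaluation.** Accuracy is estimated per subject and then
  pooled by averaging Fisher-z correlations and back-transforming
  (estimate-then-average) — never by correlating averaged matrices; the test
  suite pins the distinction against a deliberately wrong averaged-first
  oracle. Undefined correlations (zero-variance units) propagate as missing
  with a warning, and are dropped pairwise from model comparisons.
- **Dependent correlations.** Comparing two predictive correlations that
  share an outcome uses the back-transformed-average Fisher-z variant
  (Hittner-style) by default, with Steiger's simple-average variant by flag.
  Two-tailed by default; a one-tailed flag exists.
- **Meta-analysis.** Per-sample correlations are Fisher-z transformed and
  pooled with sample-size weights, $\bar z = \sum w_i z_i / \sum w_i$.
  Significance uses $\chi^2(1) = \bar z^2 \sum w_i$ — the test of the pooled
  z against zero with variance $1/\sum w_i$. The chi-square form is an
  explicit, swappable choice; with one sample it reduces to an ordinary
  z test of that correlation.
- **Behaviour prediction.** Ridge regression (via glmnet) on all
  upper-triangle edges, penalty chosen by 5-fold CV within the training
  split from the grid $10^{-3}..10^{5}$ (half-decade steps), features
  standardized by training-split statistics only. Cross-sample prediction
  trains on one split and predicts the other, in both directions; g factors
  and latent FC must be estimated within splits (the pipeline does this), and
  a test verifies that a split's predictions are bit-identical when that
  split's outcomes are corrupted.

## Problem sizes and runtime

The default test and acceptance runs use deliberately small cohorts chosen so
each check's Monte Carlo error is well inside its decision margin: loading
recovery at $N = 5000$ (tolerance 0.02), free-vs-restricted equivalence at
$N = 2000$, latent-vs-single-state recovery at $N = 300$ subjects, 9 states,
10 regions (45 edges), calibration of the dependent-correlation test at
10,000 replicates of $n = 176$, FDR calibration over 50 replicates of 1000
units, and the data-quantity experiment at 60 subjects with the full 2112/264
TR counts. The complete suite runs in well under a minute on one CPU.

## Known limitations

Single-factor-per-edge only: no multi-factor models, rotations, or fit
indices, and no sharing of information across edges. No partial correlation,
regularized covariance, or dynamic FC. The behavioural module ships the
standard 11-measure polarity table but no confound regression (age, motion).
The chi-square form of the meta-analytic test and the tails of the
dependent-correlation test are documented choices, exposed as flags, since
the conventional descriptions of both leave room for interpretation.
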