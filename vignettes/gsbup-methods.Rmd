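---
title: "Slacks-based efficiency with undesirable factors: models, conventions, and numerical choices"
author: "gsbup"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slacks-based efficiency with undesirable factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsbup)
```

## The model

`gsbup` scores decision-making units (DMUs) — hospitals, hospital clusters,
or any production units — that consume *desirable inputs* $x^D$ (resources
that should shrink, e.g. staff and beds) and *undesirable inputs* $x^I$
(quantities on the input side that should grow, e.g. the in-patient
discharge rate) to produce *desirable outputs* $y^G$ (patient-days,
attendances) and *undesirable outputs* $y^B$ (mortality). For a target
DMU$_0$ evaluated against $n$ peers the model minimizes

$$
\delta_0 \;=\;
\frac{\sum_i \omega_i \alpha_i + \sum_h \nu_h \theta_h}
     {\sum_l \sigma_l \gamma_l + \sum_r \mu_r \beta_r}
$$

over intensity weights $\lambda \ge 0$ and ratio variables
$0 \le \alpha \le 1$ (DI contraction), $\gamma \ge 1$ (UI expansion),
$\beta \ge 1$ (DO expansion), $0 \le \theta \le 1$ (UO contraction),
subject to $\sum_j \lambda_j x^D_j = \alpha \cdot x^D_0$ and its analogues
for the other three blocks, plus an intensity constraint
$\sum_j \lambda_j \in \Gamma$. The preference weights satisfy
$\sum\omega + \sum\nu = 1$ and $\sum\sigma + \sum\mu = 1$. A DMU is
efficient iff the optimal ratio vector is all ones, equivalently iff all
slacks $s^{D-} = (1-\alpha)x^D_0$, $s^{I+} = (\gamma-1)x^I_0$,
$s^{G+} = (\beta-1)y^G_0$, $s^{B-} = (1-\theta)y^B_0$ vanish; then
$\delta_0 = 1$. The non-oriented form means input contraction and output
expansion are sought simultaneously, avoiding the orientation choice of
classical radial models.

The fractional program is solved exactly through the Charnes–Cooper
substitution $t = 1/(\sum\sigma\gamma + \sum\mu\beta)$, $a = t\alpha$,
$b = t\gamma$, $c = t\beta$, $d = t\theta$, $\zeta = t\lambda$, which
yields a linear program whose optimum equals $\delta_0$. Every factor row
is divided by the target's own value before solving, so the LP sees
coefficients of order one whatever the measurement units; this is also why
rescaling a factor column leaves every score bit-identical.

### Intensity sets and a naming caveat

The `gamma` argument selects $\Gamma$: `"CRS"` imposes
$\sum\lambda = 1$, `"IRS"` $\sum\lambda < 1$, `"DRS"` $\sum\lambda > 1`,
`"FREE"` leaves the sum unconstrained. **Caveat:** the label `CRS` here
denotes the *convexity* constraint $\sum\lambda = 1$, which most of the
DEA literature associates with *variable* returns to scale; the labels
follow the model family this package implements, and the mismatch with the
wider literature is deliberate and documented rather than silently
"corrected". The strict IRS/DRS inequalities are not LP-representable and
are closed with a margin $\varepsilon_\Gamma = 10^{-9}$
(`eps_gamma`); the closure can change the optimum only on a measure-zero
boundary. The strict positivity $t > 0$ becomes $t \ge 10^{-6}$ (`tmin`);
the transformation is scale-invariant, so the bound is inert.

### Default weights

When no weights are given, each DI/UO factor receives $1/(m+k)$ and each
UI/DO factor $1/(q+s)$ — the symmetric, parameter-free choice consistent
with the two normalization constraints. All weights are user-settable per
factor through `factor_spec()` or the YAML config.

### Tolerances

* efficiency: a DMU is flagged efficient when every ratio variable is
  within `1e-6` of one — above the solver's feasibility tolerance
  (`1e-9`), below any plausible data resolution;
* projection consistency: the ratio form $(\alpha x^D_0, \ldots)$ and the
  intensity form $\sum_j \lambda_j x_j$ of the projection must agree to a
  relative `1e-6`, else `project()` raises an error rather than returning
  a silently inconsistent point.

### The LP engine

The package carries its own dense two-phase primal simplex with Bland's
anti-cycling rule (`R/lp.R`). The GSBUP programs are small (a few dozen
variables) but heavily degenerate — almost every right-hand side is zero —
which defeats textbook pricing implementations. Bland's rule guarantees
termination on degenerate programs at a modest speed cost that is
irrelevant at these sizes. The solver is exercised in the test suite
against problems with hand-computed optima and against an independent
grid-search oracle of the fractional program.

## Returns to scale

The published application reports an RTS label per DMU but no algorithm.
The package uses a range diagnosis: solve with $\Gamma$ free, pin the
objective to its optimum $\delta^*_{\text{free}}$, and compute
$[\min \sum\lambda^*, \max \sum\lambda^*]$ over the optimal face by two
auxiliary LPs. The auxiliary programs are posed in the *original*
variables $(\alpha,\beta,\gamma,\theta,\lambda)$, where the constraints of
the fractional program are linear and the optimal face is the linear slice
$\{\text{numerator} = \delta^* \times \text{denominator}\}$ — avoiding a
second fractional objective in the transformed space. A range entirely
below one is labeled IRS, entirely above one DRS, a range containing one
CRS. The label therefore does not depend on which optimal vertex the
solver happens to return. The optimality cut allows a slack of `1e-9`
(`cut_tol`) so that round-off in $\delta^*$ cannot empty the feasible set.

## Malmquist productivity

For a DMU observed in periods $t$ and $t+1$, four scores are computed —
each period's data against each period's frontier — and combined as

$$
M_0 = \sqrt{\frac{d_{t,t}}{d_{t,t+1}}\cdot\frac{d_{t+1,t}}{d_{t+1,t+1}}},
\qquad
\mathrm{TEC}_0 = \frac{d_{t,t}}{d_{t+1,t+1}}, \qquad
\mathrm{FS}_0 = \sqrt{\frac{d_{t+1,t+1}}{d_{t,t+1}}\cdot
                      \frac{d_{t+1,t}}{d_{t,t}}},
$$

with $d_{\text{frontier},\text{data}}$, so $M_0 =
\mathrm{TEC}_0\cdot\mathrm{FS}_0$ identically. **Interpretation
convention:** in this model family $M_0 < 1$ denotes productivity
*improvement* and $\mathrm{FS}_0 < 1$ frontier *progress* — the inverse of
the classical Malmquist reading. The package applies the convention
exactly as defined and prints the component scores so users can re-read
them classically if they prefer.

Two conventions had to be fixed where the source application is silent:

* **Averages over period pairs.** Malmquist indices are multiplicative, so
  multi-period "average" columns are geometric means; the arithmetic mean
  of $M_0$ is reported alongside for comparison.
* **Mixed-period infeasibility.** The box bounds
  $\alpha,\theta \le 1 \le \beta,\gamma$ can be unsatisfiable when a
  record lies outside a foreign frontier's attainable set — a standard
  cross-period pathology. A failed mixed-period solve is retried with
  widened bounds ($\alpha,\theta \le 10$, $\beta,\gamma \ge 0.1$) and the
  result is flagged `mixed_period_relaxed`; if even the relaxed program is
  infeasible the index is reported missing rather than guessed.

## Phase II: censored-normal regression

Efficiency scores live in $[0,1]$ and pile up at 1, so the second stage
regresses them on exogenous covariates with a two-sided Tobit model,
censoring bounds $[0,1]$ by default (in practice only the upper bound
binds for DEA scores). The log-likelihood sums the normal log-density for
interior observations and the log tail masses for censored ones. Panel
structure (the same units observed across years) is deliberately ignored —
a pooled likelihood, as in the application this package operationalizes.

Fitting is BFGS in $(\beta, \log\sigma)$ with the analytic gradient from a
least-squares start, followed by a restart and a few observed-information
Newton steps that drive the gradient to numerical zero (quasi-Newton stops
on function change and can leave a gradient of order $10^{-2}$ on flat
likelihoods). Standard errors are the square roots of the diagonal of the
inverse observed information, computed by central differences of the
analytic gradient with per-parameter step scaling. The test suite
cross-checks coefficients, scale, log-likelihood and standard errors
against the interval-censored accelerated-failure-time fit in the
`survival` package, which serves as an independent oracle only.

No standard Tobit $R^2$ exists. `tobit_report()` prints two clearly
labeled surrogates: McFadden's pseudo-$R^2$ against an intercept-only
Tobit, and the squared correlation between the linear predictor and the
observed response.

Degenerate designs fail loudly: an all-censored response (parameters
unidentified), a rank-deficient design matrix, and responses outside the
censoring bounds are errors, not warnings. With a zero latent error
variance the likelihood is unbounded; the generator can produce such data
for testing, but the deterministic response is then recovered by least
squares, not by the MLE.

## Synthetic data with planted truth

`generate_frontier_panel()` builds panels whose efficiency status is known
by construction. Efficient DMUs are sampled on a hyperplane
$\sum_f g_f z_f = c$ whose coefficients are positive on DI/UO and negative
on UI/DO (each scaled by the factor's typical magnitude). Under the
convexity constraint $\sum\lambda = 1$, every point of the production set
is weakly worse than a hull point and every hull point lies on the
hyperplane, so no feasible point can dominate a frontier point: planted
frontier membership is a theorem, not a tendency. Points are sampled with
a multiplicative jitter of ±10% around the magnitude scales and projected
back onto the hyperplane through the first DI. Inefficient DMUs degrade a
random convex combination of the *panel's own* efficient DMUs (DI and UO
inflated, DO and UI deflated by per-factor severities in $[0.8, 0.95]$ by
default) — taking the generating point inside the hull guarantees strict
domination, hence a score strictly below one. Degradations being dominated
points, they leave the frontier itself untouched.

The default magnitude scales reproduce the hospital application's
structure (2 DI, 1 UI, 3 DO, 1 UO at scales 2747, 1030, 84, 445, 126, 733,
22), so synthetic panels are magnitude-realistic for that setting. What
the generator does **not** emulate: the strong inter-factor correlations
of real hospital data (staff and beds correlate above 0.95 in the
application), serial correlation of a unit across years, measurement
error, or zero cells such as a hospital without an emergency department —
zeros are exercised separately through the validation layer's
substitution policy (`1e-3` times the factor's within-period mean, always
logged). Passing the planted-truth suite therefore demonstrates
correctness of the solver and transformations, not robustness to every
real-data pathology.

`generate_drift_series()` scales desirable outputs by $g^{p-1}$ in period
$p$, so the frontier moves multiplicatively while relative positions are
preserved (pure FS, TEC $= 1$); selected units can be frozen
(`static_dmus`, falling behind the frontier) or decayed per period
(`tec_decay`, pure TEC when $g = 1$). `generate_tobit_panel()` draws
standard-normal covariates and clips the latent response to the censoring
bounds; the achieved censoring fraction is reported and checked against an
optional target. All generators take an explicit integer seed and restore
the caller's RNG state.

## The bundled hospital-cluster benchmark

`hk_clusters_2013()` ships the published seven-cluster panel of the Hong
Kong Hospital Authority (2013) with the published scores, slacks and RTS
labels as reference values, and `hk_cluster_benchmark()` recomputes
everything and tabulates computed against published. Running it shows:

```{r benchmark}
bm <- hk_cluster_benchmark()
bm[, c("dmu_id", "delta", "score_published", "rts", "rts_published",
       "score_match", "rts_match")]
```

Three findings deserve the user's attention, because they illustrate how
the comparison is meant to be read:

* The two published efficient clusters (KEC, NTWC) reproduce exactly —
  frontier membership is weight-independent, so this part of the
  reproduction does not rest on any assumption.
* The published HKEC *slack* row is exactly the equal-weight convex-hull
  optimum this package computes (to the printed two decimals), yet the
  published HKEC *score* (0.839) matches neither that slack row nor this
  package's score (0.8757).
* Several published inefficient scores are unattainable from the published
  data under *any* weights or intensity set: HKWC holds the strictly
  smallest undesirable output, so the output constraint forces the
  intensity vector onto HKWC itself and $\delta^*_{HKWC} = 1$ exactly;
  the published 0.754 cannot arise from this table. The same applies to
  KWC and NTEC.

The benchmark therefore reports mismatches as mismatches. The published
score column was evidently computed from data other than the printed
cluster table (hospital-level data, unpublished weights, or a
transcription slip); reproducing it is out of reach without that source,
and the package does not pretend otherwise. The same reasoning applies to
the published "updated" scores: by the projection theorem (verified as a
property test across seeded panels), re-scored projections equal one, so
non-unit updated scores are not reproducible under any reading consistent
with the model.

## Problem sizes and runtime choices

The property suites run at deliberately moderate sizes chosen to exercise
every code path while keeping the whole suite fast: the projection theorem
on 50 seeded panels of up to 20 DMUs (dimensions 2/1/3/1), brute-force
oracle equivalence on panels with up to 4 DMUs and total dimension up to 4
(grid search over the intensity simplex with local refinement, valid
because linear-fractional objectives are pseudolinear), Tobit recovery at
$n = 2000$ with roughly 20% upper censoring and a 50-replication bias
check at $n = 500$. These sizes are the package's own validation design;
the generators scale far beyond them.

## Known limitations

* No super-efficiency ranking among efficient DMUs, weight-restriction
  (assurance-region) extensions, or bootstrap confidence intervals for
  scores.
* No circular or fixed-base Malmquist variants, and no further
  decomposition of the frontier-shift term.
* The undesirable input enters as a rate (a percentage); $\gamma \ge 1$
  can project it above 100%, and no cap is imposed — the model family
  defines none.
* The Tobit stage is pooled maximum likelihood: no random effects, no
  Simar–Wilson bootstrap, no instrumental variables.
* Alternative optima: slacks are determined by the ratio variables, but
  the intensity vector (and hence the reported reference peers) need not
  be unique; RTS labels are made solver-independent through the range
  diagnosis, while reported $\lambda$ is whichever optimal vertex the
  simplex reaches.
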