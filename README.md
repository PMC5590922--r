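# gsbup

Two-phase efficiency analysis for panels of decision-making units (DMUs)
such as hospitals or hospital clusters, for health-services researchers and
operations analysts who need frontier benchmarking that treats *undesirable*
factors (mortality rates, discharge rates) on an equal footing with ordinary
inputs and outputs.

## What it computes

**Phase I — efficiency.** Each DMU consumes desirable inputs `x^D` (staff,
beds), an undesirable input `x^I` (a rate that should be high, e.g.
in-patient discharge), and produces desirable outputs `y^G` (patient-days,
attendances) and an undesirable output `y^B` (mortality). The GSBUP model
(a generalized, non-oriented slacks-based DEA model with preference
weights) scores DMU₀ by

    min δ₀ = (Σᵢ ωᵢ αᵢ + Σₕ νₕ θₕ) / (Σₗ σₗ γₗ + Σᵣ μᵣ βᵣ)

subject to `Σⱼ λⱼ x^D_j = α·x^D₀` (and analogues for the other blocks),
`Σλ ∈ Γ`, with `0 ≤ α, θ ≤ 1 ≤ β, γ` and weights normalized group-wise
(`Σω + Σν = 1`, `Σσ + Σμ = 1`). The fractional program is solved exactly
through the Charnes–Cooper linearization; δ = 1 with zero slacks means
efficient. On top of the scores the package computes frontier projections,
returns-to-scale labels (via the range of `Σλ` over alternative optima),
and a Malmquist productivity index `M₀ = TEC₀ × FS₀` across periods (in
this model family `M₀ < 1` means improvement).

**Phase II — explanation.** Efficiency scores, censored in `[0, 1]`, are
regressed on exogenous covariates by a censored-normal (Tobit) maximum
likelihood regression with observed-information standard errors.

Seeded generators (`generate_frontier_panel()`, `generate_drift_series()`,
`generate_tobit_panel()`) produce panels with *planted* ground truth —
efficient units provably on the frontier, known drift, known coefficients —
so every stage is testable offline.

## Worked example

The package ships the seven Hong Kong Hospital Authority clusters (2013):
2 desirable inputs, 1 undesirable input, 3 desirable outputs, 1 undesirable
output, with equal preference weights.

```r
library(gsbup)
hk <- hk_clusters_2013()
efficiency_table(hk$panel)
#>  dmu_id period delta efficient  status slack_DI1 slack_DI2 slack_UI1 slack_DO1
#>    HKEC   2013 0.876     FALSE optimal     0.000     9.744     1.890   241.838
#>    HKWC   2013 1.000      TRUE optimal     0.000     0.000     0.000     0.000
#>     KCC   2013 0.747     FALSE optimal   984.838     0.000     0.252   274.379
#>     KEC   2013 1.000      TRUE optimal     0.000     0.000     0.000     0.000
#>     KWC   2013 1.000      TRUE optimal     0.000     0.000     0.000     0.000
#>    NTEC   2013 1.000      TRUE optimal     0.000     0.000     0.000     0.000
#>    NTWC   2013 1.000      TRUE optimal     0.000     0.000     0.000     0.000
#>  ...
#>  Summary by period
#>  period mean_delta n_efficient n_above_mean
#>    2013  0.9460414           5            5
```

HKEC scores 0.876: it could reach the frontier by shedding ~10 beds,
raising its discharge rate by 1.9 points, and expanding its three outputs
by the `slack_DO*` amounts — the projection is the convex combination
`0.18·HKWC + 0.50·KEC + 0.32·NTWC`:

```r
solve_gsbup(hk$panel, "HKEC")
#> GSBUP solution for HKEC (2013), Gamma = CRS: status optimal
#>   delta = 0.8757
#>   alpha: 1 0.9968
#>   beta:  1.2037 1.1928 1.1432
#>   gamma: 1.0229
#>   theta: 1
#>   lambda: HKWC=0.1806, KEC=0.4984, NTWC=0.3210
classify_rts(hk$panel, "HKEC")
#> HKEC (2013): IRS; sum(lambda) in [0.948485, 0.948485]; delta_free = 0.828318
```

`hk_cluster_benchmark()` compares these computed values against the
published reference scores and flags where they disagree — the published
score column is partly inconsistent with its own data (see the methods
vignette, `vignettes/gsbup-methods.Rmd`), and the package reports such
mismatches instead of reconciling them.

For a multi-period panel, `run_phase1()` writes scores, RTS and Malmquist
reports; `run_phase2()` fits the Tobit stage:

```r
pans  <- generate_drift_series(frontier_design(4, 3, seed = 1), periods = 3, g = 1.05)
phase1 <- run_phase1(pans, out_dir = "out")           # scores.csv, rts.csv, malmquist.csv
d      <- generate_tobit_panel(2000, c(0.8, 0.12, -0.08, 0.1), 0.15,
                               censor_rate_target = 0.2, seed = 3)
fit_tobit(d)                                          # recovers the coefficients
```

A thin command-line wrapper lives at `inst/cli/gsbup.R`
(`Rscript gsbup.R efficiency --panel panel.csv --spec spec.yml --out dir/`).

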