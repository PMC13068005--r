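# delaytwin

Stochastic delay differential equation (SDDE) digital twins of
inflammatory biomarker cascades.

Inflammatory responses are delayed, nonlinear and noisy: neutrophils react
within hours, C-reactive protein (CRP) rises with an intermediate lag, and
albumin — a negative acute-phase protein — falls and recovers slowly.
`delaytwin` simulates virtual patient cohorts in which these three
biomarkers and a latent cardio-inflammatory output Y evolve under a
delayed, multiplicative-noise SDDE system

    dB1 = [α1 S(t−τ1) − α2 B1(t−τ2)] dt + σ1 B1(t−τ2) dW1   (neutrophils)
    dB2 = [γ1 B1(t−τ3) − γ2 B2(t−τ4)] dt + σ2 B2(t−τ4) dW2  (CRP)
    dB3 = [θ1 − θ2 B2(t−τ5) − θ3 B3(t−τ6)] dt + σ3 B3(t−τ6) dW3  (albumin)
    dY  = [β1 B2(t−τ7) − β2 B3(t−τ8) − β3 Y(t−τ9)] dt + σ4 Y(t−τ9) dW4

integrated by a delay-aware Euler–Maruyama scheme with discrete-index
delayed lookups and constant pre-history.  Cardiovascular events are
labelled by prevalence-calibrated threshold exceedance of max Y(t), and the
package provides the downstream analyses: rank-sum comparison of
time-to-peak by event status, rank-based AUC, an explicit
complete-separation diagnostic (in place of a divergent logistic fit),
Kaplan–Meier curves by time-to-peak tertile with log-rank tests, the three
robustness analyses (prevalence variation, outcome noise at the
event-definition stage, inter-individual parameter heterogeneity), and the
cross-sectional delay-proxy ratios CRP/(neutrophils+1) and CRP/albumin for
tabular biomarker data.

It is intended for researchers exploring how temporal delay and
stochasticity structure risk in mechanistic simulations — a
hypothesis-generation instrument, not a clinical tool.

## Worked example

```r
library(delaytwin)

m  <- cascade_model("paper2026")        # frozen reference parameterisation
co <- simulate(m, nsim = 100, seed = 1) # 100 virtual subjects, 20% events
summary(co)
#> Cohort of 100 subjects, 20 events
#>   raw threshold 0.6939 (x 2.162 -> nominal 1.5)
#>   mean time-to-peak Y: 36.9 (events) vs 25.9 (non-events)
#>   rank-sum test: U = 1597, p = 5.65e-12
#>   AUC of time-to-peak vs event: 0.998
#>   near-complete separation (overlap fraction 0.040)
```

Event-positive subjects reach their output peak markedly later (36.9 vs
25.9 abstract time units); the rank-sum test confirms the separation and
the diagnostic flags it as near-complete (only 4% of subjects fall inside
the overlap of the two groups' time-to-peak ranges — the regime in which a
logistic fit would fail to converge).  The raw calibrated threshold 0.6939
corresponds to the nominal cutoff 1.5 on the normalised Y scale.

Survival stratification by time-to-peak tertile:

```r
km <- km_by_delay_tertiles(co)
round(km$event_fraction, 2)
#> [1] 0.00 0.00 0.61
km$comparison
#> log-rank: statistic = 58.626, p = 1.86e-13 (n = 34 vs 33 vs 33)
```

Events concentrate entirely in the slowest tertile: delay structure alone
reorganises event timing in the simulated population.

Robustness analyses and proxy ratios:

```r
report <- run_sensitivity_suite("paper2026", master_seed = 1)
tab <- proxy_table(data.frame(crp = c(2, 4), neutrophils = c(3, 1),
                              albumin = c(40, 38)))
```

A thin command-line wrapper with `simulate`, `metrics`, `sensitivity`,
`km` and `proxies` subcommands ships in `inst/scripts/delaytwin`.

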