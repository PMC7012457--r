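# collareffects

Quantifies the short-term effects of GPS-collar fitting on a tagged
ungulate from three independent data streams, for wildlife ecologists and
welfare reviewers who need to know whether collaring effects are transient:

1. **Behavior** — six-category ethogram tallies from 15-s scan sampling in
   10-minute windows, modelled as a Bayesian multinomial logistic
   regression with per-individual random effects across pre-treatment /
   treatment / post-treatment periods, with a credible-interval
   significance rule against the pre-treatment median.
2. **Stress physiology** — fecal glucocorticoid metabolite (FGM)
   concentrations (ng/g) around the collaring date, fit by four competing
   piecewise regressions (no response / stress / habituation / handling)
   with a fixed 1-day gut-passage lag and, for the handling model, an
   estimated recovery breakpoint k2; selected by leave-one-out
   cross-validation SSE.
3. **Activity** — 8 Hz tri-axial collar accelerometry: static/dynamic
   decomposition (2-s moving window), VeDBA, running min/max, a
   random-forest behavior classifier (rest / feed / locomote / headshake),
   hourly binomial aggregation of classified headshaking, and three
   binomial time-series models of its post-collaring decay:

   - model 1: `logit(p_t) = a·exp(-b·t) + c`
   - model 2: model 1 with a daytime amplification exponent `d`
     (`p = phi^d` by day)
   - model 3: a mixture of two harmonic processes with weights
     `alpha_1t = exp(-b·t)`, `alpha_2t = 1 - alpha_1t` and diel frequency
     `omega = 1/24`

   with derived half-life `ln(2)/b` and percent treatment effect
   `(handling - recovery)/recovery × 100`.

A synthetic-data module generates all three data streams with the
statistical structure the analyses assume, so the full pipeline is testable
end-to-end without animals. All fitting uses a shared adaptive
random-walk Metropolis engine with split-chain convergence diagnostics and
seed-derived, bitwise-reproducible chains. See the methods vignette
(`vignettes/collar-effects-methods.Rmd`) for models, priors, numerical
choices, and known limitations.

## Worked example

```r
library(collareffects)

# the handling-response identity: baseline 43.35 ng/g + 6.59 ng/g between
# the 1-day lag and the 5.03-day recovery breakpoint
predict_fgm_response("handling",
                     list(beta0 = 43.35, beta1 = 6.59, k1 = 1, k2 = 5.03), 3)
#> [1] 49.94

# simulate a 48-h accelerometer deployment, aggregate headshaking hourly,
# fit the day/night decay model, and derive the treatment effect
sim <- simulate_accel_stream(accel_sim_config(duration_h = 48, seed = 3))
ser <- aggregate_hourly(sim$stream)
fit <- fit_headshake_model(ser, "daynight",
                           settings = mcmc_settings(n_iter = 8000, thin = 8,
                                                    seed = 3))
treatment_effect(fit)
#> Derived treatment effects (daynight model):
#>             parameter         mean           sd       median         q2.5        q97.5
#>             half_life 3.500661e+00 1.540384e-01 3.495094e+00 3.209395e+00 3.813626e+00
#>         handling_rate 1.778346e-02 6.678912e-04 1.777936e-02 1.645697e-02 1.921634e-02
#>         recovery_rate 2.357953e-03 5.473927e-05 2.357442e-03 2.250401e-03 2.460855e-03
#>  treatment_effect_pct 6.543204e+02 2.628363e+01 6.542471e+02 6.039484e+02 7.055894e+02
```

The generator's truth was a half-life of `ln(2)/0.2 = 3.47` h and a ~630%
treatment effect; the fit recovers both (3.50 h, 654%) with headshaking
declining from ~1.8% of records immediately after fitting to a ~0.24%
baseline.

```r
# FGM model competition at the published effect size (beta1/sigma ~ 0.8):
d <- simulate_fgm_dataset(fgm_sim_config(seed = 1))
fgm_cv_select(d, settings = mcmc_settings(n_iter = 2000, thin = 4, seed = 1))
#> Leave-one-out CV (SSE); winner: stress
#>        model      sse n_failed rank
#>       stress 5045.011        0    1
#>     handling 5188.645        0    2
#>         none 5198.797        0    3
#>  habituation 5238.649        0    4
```

This run is deliberately honest about data strength: at the published
effect size the four shapes differ by little inside a 19-day window (stress
and handling coincide until the recovery breakpoint), so the CV winner
varies across realizations. Parameter *recovery* is reliable — the
acceptance suite shows the handling model's 95% intervals cover the
generating (beta0, beta1, k2) in 10/10 replicates — while model *identity*
at this signal-to-noise is genuinely uncertain.

## Pipeline and CLI

```r
run_pipeline(default_pipeline_config(seed = 1), "out/")   # simulate -> fit
                                                          # -> select -> report
```

writes per-stage CSVs, `report.md`, and a reproducibility manifest
(`manifest.json`: config, config hash, seed, package version). A thin CLI
wraps the same entry points:

```sh
Rscript inst/cli/collareffects-cli.R simulate fgm --seed 5 --out fgm.csv
Rscript inst/cli/collareffects-cli.R reproduce --seed 1 --out out/
```

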