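# smchr

Hazard ratios estimated from randomized trials carry a *built-in selection
bias*: even with perfect randomization and independent censoring, the
individuals still at risk in the exposed and unexposed arms drift apart
over time, because surviving is itself informative about latent risk. This
package is for biostatisticians and epidemiologists who want to quantify
that drift — to compute exactly what a trial's hazard ratio converges to
under specified latent heterogeneity, and how far that is from the causal
effect.

## The model and the two estimands

Individual hazards follow the multiplicative structural model

```
lambda_i^a(t) = U_0i * (U_1i)^a * lambda_0(t) * f_1(t, a),   f_1(t, 0) = 1
```

with latent frailty `U_0` (heterogeneous baseline risk) and latent effect
modifier `U_1` (heterogeneous hazard ratio). Two estimands are contrasted:

* **CHR** (causal hazard ratio) — the population contrast of the
  all-exposed vs all-unexposed worlds,
  `CHR(t) = f_1(t,1) * (E[U_1] + cov(U_0, U_1))` when `E[U_0] = 1`;
* **SMCHR** (survivor marginalized causal hazard ratio) — what the trial's
  observed hazard ratio actually estimates,
  `SMCHR(t) = f_1(t,1) * E[U_0 U_1 | T^1 >= t] / E[U_0 | T^0 >= t]`.

The survivor-conditional means come from the Laplace transform of the
latent law, `E[U | T >= t] = -L'(Lambda) / L(Lambda)`, implemented in log
space for gamma, inverse Gaussian, compound Poisson (with a nonsusceptible
point mass at zero), three-point benefit–harm–neutral (BHN), and
degenerate laws. The package computes SMCHR curves analytically where a
route exists (frailty-only, modifier-only, or the independent mixture
`L_{U0 U1}(c) = sum_k p_k L_{U0}(mu_k c)`), by importance-weighted Monte
Carlo otherwise (Gaussian-copula dependence, continuous modifiers with
frailty), simulates potential-outcome trial data from the structural model,
and evaluates the estimand a misspecified proportional-hazards fit targets
under censoring, `exp(E[log OHR(T) | uncensored])`.

## Worked example

Gamma frailty (mean 1, variance 1) combined with an independent BHN effect
modifier of mean 3 and variance 1 — an exposure that triples the expected
hazard, with 5% of the population benefiting:

```r
library(smchr)

sc <- scenario(
  frailty  = frailty_law("gamma", theta0 = 1),
  modifier = modifier_law("bhn", mean = 3, variance = 1, p1 = 0.05, mu1 = 0.5)
)

smchr_curve(sc, times = c(0, 1, 2, 4, 8))
#> # A tibble: 5 × 3
#>    time   chr smchr
#>   <dbl> <dbl> <dbl>
#> 1     0     3  3
#> 2     1     3  2.87
#> 3     2     3  2.28
#> 4     4     3  1.30
#> 5     8     3  1.03
```

The CHR is 3 at every time, but the trial's expected hazard ratio has
fallen below 1.31 by `t = 4`: exposed survivors are increasingly the less
frail and less harmed. The long-time limit under gamma frailty is exactly 1
— the effect is eventually masked completely:

```r
smchr_limit(sc)
#> [1] 1
```

A proportional-hazards fit averages over this moving target. With
follow-up truncated at `t = 4`:

```r
expected_cox_estimand(sc, censoring_scheme(follow_up = 4),
                      n_rep = 1e5, seed = 1)
#> <cox_estimand> exp(E[log OHR(T) | uncensored]) = 1.9480 (log 0.6668, se 0.0010)
#>   62376 events of 100000 subjects; follow-up 4, loss rate 0
```

So a trial reporting a Cox hazard ratio of about 1.95 here would
understate the causal hazard ratio of 3 by a factor of ~1.5 — and a
longer follow-up would make the reported value *smaller*, not more
accurate. `scenario_presets()` lists ready-made scenarios (frailty-only,
modifier-only, combined, copula-dependent, and the censoring sweep);
`run_scenario()` writes curve CSVs; `autoplot()` draws any curve; a thin
command-line wrapper lives at `inst/cli/smchr`.

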