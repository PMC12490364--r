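# coxbf

Bayes factors for two-group comparisons in Cox proportional hazards
regression — from full time-to-event data, and from nothing more than the
summary statistics a published article reports.

## The problem

Clinical and biomedical studies routinely compare a control and an
experimental condition on a time-to-event outcome with the semi-parametric
Cox model

λ(t | x) = λ(t) e^{xβ},   x ∈ {0, 1},  HR = e^β,

and report a hazard ratio with a confidence interval and a p-value. A
frequentist analysis cannot quantify evidence *in favor of* the null
hypothesis of equal hazards, and interim looks at the p-value inflate the
false-positive rate. `coxbf` instead computes the Bayes factor

BF₁₀ = ∫_{Ω₁} f(D | β) f(β) dβ / f(D | β₀),

where f(D | β) is the exponential of Efron's approximation to the Cox log
partial likelihood (ties handled throughout), f(β) is a Normal — or, for
one-sided alternatives, truncated-Normal — prior on the log hazard ratio,
and β₀ is the null value (0 by default). The marginal likelihood is
evaluated by adaptive Gauss–Kronrod quadrature on a recentred integrand.

When the raw data are unavailable — the typical situation when reanalyzing
a published trial — `coxbf` reverse-engineers pseudo-raw datasets from the
reported summary statistics: starting from times drawn Uniform(1, t_max)
with the reported group sizes and event counts fixed exactly, a particle
swarm optimizer adjusts per-subject times Y′ = e^ξ ∘ Y to minimize

φ(ξ) = log [ (1/|E|) Σ_r ((O_r − E_r)/E_r · w_r)² ],

the log mean squared weighted relative deviation between the candidate
dataset's statistics O and the published ones E. Repeating this for many
replicates yields a distribution of Bayes factors that closely brackets
the (unobtainable) full-data Bayes factor. The recommended targets are the
hazard ratio (weight 2) and its CI bounds (weight 1 each); Kaplan–Meier
medians can be added but increase bias and variance. A closed-form
Savage–Dickey Normal approximation,

BF₀₁ = √((σ² + SE²)/SE²) · exp(−½[(β̂ − β₀)²/SE² − (β̂ − μ)²/(σ² + SE²)]),

is included as a fast comparator that needs only β̂ and SE(β̂).

## Worked example

```r
library(coxbf)

# a synthetic trial: 60 + 60 subjects, true log HR 0.4, ~30% censoring
d <- simulate_survival(simulation_spec(60, 60, beta_true = 0.4,
                                       censor_rate = 0.04, seed = 11))
fit_cox(d)
#> Two-group Cox proportional hazards fit (Efron ties)
#>   log HR (beta): 0.776883  (SE 0.232182)
#>   HR: 2.17468  95% CI [1.37963, 3.42791]
#>   log partial likelihood: -312.397 (MLE), -318.053 (beta = 0)

bayes_factor_full(d, prior_spec(0, 1, side = "greater"))
#> BF10 = 97.2127  (log BF10 = 4.5769)  [gauss_kronrod_adaptive]
#>   jeffreys:        very strong evidence for H1
#>   lee_wagenmakers: very strong evidence for H1
#>   kass_raftery:    strong evidence for H1
```

The data are ~97 times more likely under the superiority hypothesis
(HR > 1) than under equal hazards. Now pretend only the fitted summary
statistics had been published, and reconstruct:

```r
st <- summarize_survival(d)   # HR = 2.17468, 95% CI [1.37963, 3.42791]
reconstruct(st, n_datasets = 5, max_iter = 300,
            prior = prior_spec(0, 1, side = "greater"), seed = 1)
#> Reconstruction: 5 datasets (0 flagged), master seed 1
#>   targets: hr, hr_ci_lower, hr_ci_upper  weights: 2, 1, 1
#>   BF10 over replicates: median 99.7313, range [96.4795, 100.758]
#>   final loss: median -13.68, iterations: median 145

savage_dickey_bf(0.776883, 0.232182, prior_spec(0, 1, side = "greater"))
#> BF10 = 91.6195  (log BF10 = 4.51764)  [savage_dickey_closed_form]
```

The reconstructed Bayes factors (median 99.7) tightly bracket the
full-data value of 97.2; the Savage–Dickey shortcut lands nearby (91.6)
and is useful when a rough answer suffices.

## Command line

```sh
Rscript inst/cli/coxbf.R bf --input data.csv --prior-mean 0 --prior-sd 1 --alternative greater
Rscript inst/cli/coxbf.R reconstruct --nc 60 --ne 60 --vc 39 --ve 45 \
    --hr 2.17468 --ci-lower 1.37963 --ci-upper 3.42791 \
    --n-datasets 100 --max-iter 300 --seed 1 --out results.csv
```

Input CSVs carry time, event (0/1), group (0 = control, 1 = experimental)
in that column order. Subcommands: `fit`, `bf`, `sd-approx`, `simulate`,
`reconstruct`, `weight-sweep`.

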