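# priormatch

Simulation-based prior elicitation for parametric Bayesian models: `priormatch`
learns the hyperparameters λ of fixed prior families (normal coefficients,
Gamma scales, half-normal variance components, an LKJ correlation) so that the
model's prior predictions match statistics elicited from a domain expert.

It is aimed at analysts who can say what they expect of *observable* or
near-observable quantities — "the median reaction time on day 0 is about
250 ms", "the interquartile range of deaths per 100 patients at zero nodes is
such-and-such", "R² is usually around 0.3" — but not at priors on raw
regression coefficients. The package turns those statements into priors.

## Method

Given a generative model with likelihood p(y | θ) and priors p(θ | λ), the
analyst picks target quantities z_i = g_i(θ) (group means, differences,
predictions at design points, R², or parameters themselves) and an elicitation
technique per target (quartiles, mean/sd, or a histogram of samples). The
expert supplies statistics t̂_m; the model implies statistics t_m(λ) computed
from forward simulations. `priormatch` solves

    λ* = argmin_λ  Σ_m α_m · MMD²_b( t_m(λ), t̂_m )

where MMD²_b is the biased squared maximum mean discrepancy with the energy
kernel k(x, y) = −‖x − y‖ (no bandwidth to tune; zero iff the sample sets
coincide). Optimization is mini-batch SGD (Adam, cosine-decay restarts) with
all sampling reparameterized; discrete likelihoods (binomial, Poisson
truncated at t^u) are relaxed with the Gumbel-Softmax trick so gradients flow
through them. Gradients are carried by a built-in forward-mode dual-number
engine — no external autodiff framework. Equal weights α_m = 1 are the
default; dynamic weight averaging is available.

Four closed-loop recovery studies ship with the package (normal linear,
binomial-logit, truncated-Poisson log-link, hierarchical normal with varying
intercepts/slopes): a simulated expert generates the statistics from a known
ground truth λ*, and training must recover it. See the vignette
(`vignettes/prior-elicitation-methods.Rmd`) for the models, all numeric
choices, and limitations.

## Worked example

Closed-loop recovery of the binomial-logit study's ground truth
λ* = (μ₀ = −0.51, σ₀ = 0.06, μ₁ = 0.26, σ₁ = 0.04), desk-scale settings:

```r
library(priormatch)

study  <- study_definition("binomial")
expert <- simulate_expert_statistics(study, S_expert = 10000, seed = 7)
res    <- run_study(study, seed = 1, expert = expert,
                    config = training_config(B = 32, E = 300, S = 50,
                                             lr0 = 0.1))
print(res)
```

```
<study_result> binomial
    name truth    estimate        error
1    mu0 -0.51 -0.50909180 9.082049e-04
2 sigma0  0.06  0.06083087 8.308723e-04
3    mu1  0.26  0.26002333 2.333233e-05
4 sigma1  0.04  0.04006361 6.361000e-05
```

Each row is a learned prior hyperparameter on its natural scale (the final
estimate is the average of the last 30 epochs) next to the ground truth the
simulated expert encoded; the errors above are two orders of magnitude inside
the study's ±0.05 recovery tolerance. `res$trace` holds per-epoch losses,
gradients and λ for diagnostics (`convergence_report(res$trace)`), and the
total loss fell from 839 at epoch 1 to 2.7 at epoch 300 in this run.

The same interface runs the other studies (`"normal_linear"`, `"poisson"`,
`"hierarchical"`) and a fast toy model (`recover_toy()`). A thin CLI wraps
these functions:

```sh
inst/cli/elicit run --study binomial --epochs 300 --batch 32 --samples 50 \
    --seed 1 --out runs/binomial
inst/cli/elicit oracle --study poisson --out expert.json
inst/cli/elicit diagnose --trace runs/binomial/trace.csv
```

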