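---
title: "Learning prior hyperparameters from expert statistics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning prior hyperparameters from expert statistics: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A Bayesian analyst must give every model parameter a prior. When the prior
families are fixed (normal coefficients, a Gamma residual scale, ...), the
remaining task is choosing their hyperparameters $\lambda$ so that the model's
prior predictions agree with what a domain expert believes about observable
quantities. `priormatch` solves this as an optimization problem: find

$$\lambda^{*}=\arg\min_{\lambda}\ \sum_{m=1}^{M}\alpha_m\,
L_m\!\left(t_m(\lambda),\ \hat t_m\right),$$

where the $\hat t_m$ are *expert-elicited statistics* — quartiles, a mean and
standard deviation, or a histogram (a sample set) of analyst-chosen *target
quantities* (a group mean, a difference of group means, an expected count at
a design point, a predictive $R^2$, or a model parameter itself) — and the
$t_m(\lambda)$ are the same statistics computed from forward simulations of
the generative model under hyperparameters $\lambda$. Each discrepancy $L_m$
is the biased squared maximum mean discrepancy with the energy kernel
$k(x,y) = -\lVert x-y\rVert$,

$$\mathrm{MMD}^2_b=\frac{1}{n^2}\sum_{i,j}k(x_i,x_j)
+\frac{1}{m^2}\sum_{i,j}k(y_i,y_j)-\frac{2}{nm}\sum_{i,j}k(x_i,y_j),$$

which compares sample sets directly, needs no bandwidth tuning, and is zero
exactly when the two multisets coincide. The weights are $\alpha_m = 1$ by
default; dynamic weight averaging (weights proportional to a softmax of each
component's loss ratio over the last two epochs, scaled to sum to $M$) is
available as an option for unbalanced problems.

Optimization is mini-batch stochastic gradient descent with Adam under a
cosine-decay-with-restarts schedule. Gradients flow through the simulation by
the reparameterization trick; every sampling step is written as a
deterministic, differentiable function of $\lambda$ and exogenous noise.

## How gradients are computed

No automatic-differentiation framework is used: the package carries
derivatives through the pipeline with a small forward-mode dual-number engine
(`R/dual.R`). Every simulated array holds its value and its Jacobian with
respect to the unconstrained $\lambda$. Forward mode is the natural choice
here because $\lambda$ has at most 14 entries in the shipped models while
intermediate arrays can have millions, so one pass computes the whole
gradient at a cost of $P$ extra array columns. Two operations have bespoke
analytic gradients rather than composed elementwise rules:

* **Gumbel-Softmax relaxation.** Discrete likelihoods are made differentiable
  by replacing a categorical draw over the support with its softmax-weighted
  average under Gumbel noise at temperature $\tau$ (default 1). For both
  shipped discrete families the score $\partial \log p(c;\theta)/\partial
  \theta$ is affine in $c$, so the gradient of the relaxed value collapses to
  $\mathrm{Var}_w(c)$ times a scalar per element — no per-category gradient
  arrays are ever formed.
* **Energy-kernel MMD.** The gradient with respect to the model-side points
  has a closed form in the pairwise difference vectors; the kink of
  $\lVert\cdot\rVert$ at coincident points is smoothed with
  $\varepsilon = 10^{-12}$ inside the square root, i.e. a zero subgradient at
  exact ties.

Prior sampling is reparameterized per family: location-scale for the normal,
the inverse CDF for the half-normal (`TruncatedNormal(0, omega)` on the
positive half-line), and implicit reparameterization for the Gamma, where
$x = F^{-1}(u;\alpha)/\beta$ and $\partial x/\partial\alpha =
-(\partial F/\partial\alpha)/f(x;\alpha)$ with $\partial F/\partial\alpha$
obtained by a central numeric difference of the regularized incomplete gamma
function in $\alpha$. The 2x2 LKJ correlation uses the Beta-marginal
construction $(\rho+1)/2\sim\mathrm{Beta}(\eta,\eta)$; its shape $\eta$ is a
fixed model constant (here 1, a uniform correlation), never learned.

Positive hyperparameters (prior scales, Gamma concentration and rate,
truncation scales) are stored and optimized on the log scale, which makes the
optimization unconstrained and matches the initialization conventions below.

The piecewise-linear pieces of the pipeline (order statistics inside the
quantile, absolute values inside the energy kernel) make the loss continuous
but not everywhere differentiable; the computed gradient is an exact
subgradient. Finite-difference checks therefore agree to high precision at
small steps and only to a few percent at coarse steps that straddle kinks.

## Statistics and their comparison

Statistics are computed across the $S$ prior-sample axis, once per batch
element, giving $B$ replicates of each statistic per epoch:

* *Quantiles*: type-7 (linear interpolation between order statistics), the
  common default in statistical software; chosen once for reproducibility.
* *Moments*: mean and standard deviation with the population divisor $S$ —
  smooth in the samples and indistinguishable from $S-1$ at the sample sizes
  used.
* *Histogram*: the samples themselves, no binning — the MMD compares sample
  sets, and binning would discard both information and gradients. Model-side
  histogram sets are thinned deterministically to at most 1000 points and the
  expert histogram holds 1000 draws, keeping the pairwise-distance matrices
  small.

Each quantile/moment component enters the MMD as $B$ points in
$\mathbb{R}^{|p|}$ or $\mathbb{R}^2$ against the expert's single replicate
point; histogram components are scalar sample sets on both sides. The expert
side holds one large-$S$ replicate ($S_{\text{expert}} = 10^4$ draws) rather
than $B$ noisy ones: the expert answers once, and the $B$ model replicates
retain the sampling variability that the mini-batch SGD needs.

The predictive $R^2$ is the variance ratio
$\mathrm{var}(\theta_i)/\mathrm{var}(y_i)$ across design rows (sample
variance, same divisor in both). Degenerate draws with zero response variance
return 0 instead of NaN so that early, extreme SGD iterates cannot poison the
run. Linear predictors are clipped to $\pm 30$ before the logistic/exp links
and probabilities to $[10^{-12}, 1-10^{-12}]$ before logs, for the same
reason.

## The simulated expert and the closed loop

Validity is assessed by *closed-loop recovery*: fix a ground truth
$\lambda^{*}$, let a simulated expert generate the elicited statistics from
it, and check that training recovers $\lambda^{*}$. The oracle runs the same
forward simulator as training (with its own fixed seed and a single batch),
including the Gumbel-Softmax relaxation for discrete likelihoods. Sharing the
relaxation means the relaxation's small bias cancels between the two sides
and $\lambda^{*}$ is the actual optimum of the loss; with a hard-sampling
expert the recovered location hyperparameters would inherit a bias of order
one count. What passing recovery shows is that the optimizer can invert the
simulator; it does not certify that a *human* expert's statistics are
consistent with any $\lambda$, nor quantify uncertainty about $\lambda$ —
the method returns a point estimate.

## The four studies

1. **Normal linear** (true/false judgment proportions): a 2 (repetition) x 3
   (encoding depth) factorial with treatment contrasts, baselines *new* and
   *deep*; responses $y_i \sim \mathrm{Normal}(\theta_i, s)$ with six normal
   coefficient priors and $s \sim \mathrm{Gamma}(\alpha,\beta)$ — 14
   hyperparameters. Elicited: quartiles of the five factor-level marginal
   means, quartiles of the repeated-minus-new difference per encoding level,
   and an $R^2$ histogram. The marginal means are unweighted means over the
   collapsed factor's cells (the design is balanced).
2. **Binomial-logit** (5-year mortality out of $T = 100$ per axillary-node
   count): 31 node counts spanning 0-59; quartiles of the expected deaths at
   the seven design points $x\in\{0,5,\dots,30\}$ — 4 hyperparameters. The
   node count enters the linear predictor raw; with the logit link nothing
   overflows over the observed range.
3. **Truncated-Poisson log-link** (counts of anti-discrimination laws per
   state): 50 synthetic states, urban share evenly spaced on 38.7-94.7
   percent and a cyclically assigned 3-level voting factor (Democrat
   baseline). The urban share is standardized: on the raw percentage scale
   the reference coefficient magnitudes would push the log-link rate far
   beyond the truncation threshold, so the ground truth is only coherent for
   a standardized predictor. The upper truncation $t^u = 80$ (the elicited
   "maximum conceivable count") bounds the relaxed support. Elicited:
   quartiles of the three voting-group means and histograms of the predicted
   counts for six indexed states — 8 hyperparameters. Because expert and
   learner share the design, the exact synthetic covariate values are
   immaterial to the recovery claim.
4. **Hierarchical normal** (reaction time under sleep deprivation): days 0-9
   for $J$ participants with varying intercepts and slopes,
   $\Sigma_u$ from half-normal scales $\tau_k$ and an LKJ(1) correlation;
   8 hyperparameters ($\mu_k$, $\sigma_k$, $\omega_k$, $\alpha$, $\beta$).
   Elicited: quartiles of the across-participant mean reaction time at days
   \{0, 2, 5, 6, 9\}, mean/sd of the within-person scale $s$ (elicitation in
   the parameter space), and $R^2$ histograms at days 0 and 9 (which carry
   the information about $\tau_0$, $\tau_1$ versus $s$).

## Algorithm parameters

Reference-scale defaults are $B = 128$, $S = 200$, $E = 600$ epochs (400 for
the hierarchical study), initial learning rate $\phi^0 = 0.1$ with period-50
cosine restarts decayed by 0.9, Adam defaults, and the final estimate is the
average of the last 30 epochs. Those settings are sized for long unattended
runs; all recovery experiments in the tests and the acceptance script use a
desk-scale setting chosen once — $B = 32$, $S = 50$, and 250-400 epochs per
study — which converges comfortably within each study's tolerance on a single
CPU in a few minutes per study. The hierarchical study uses $\phi^0 = 0.25$
and $J = 50$ participants at desk scale.

Initialization follows the normal-linear study's reference scheme —
$\mu_k \sim \mathrm{Normal}(0, 0.1)$,
$\log\sigma_k \sim \mathrm{Uniform}(-4, -2)$,
$\log\alpha \sim \mathrm{Normal}(3, 0.1)$,
$\log\beta \sim \mathrm{Normal}(5, 0.1)$ — generalized to studies 2 and 3.
For the hierarchical study the same pattern is shifted to the data's
magnitude ($\mu_0$ near 200, $\log$-scales near their order of magnitude),
mirroring how that scheme centers the Gamma parameters near a weak
guess of the right order.

Training stops at the epoch budget; `convergence_report()` (loss slopes over
the last quarter, trailing gradient magnitude, trailing $\lambda$ stability)
is a diagnostic, not a stopping rule. Non-finite gradients skip the update
and are recorded; more than ten consecutive failures abort the run.

## Known limitations

* Identifiability degrades with model complexity: different $\lambda$ can
  imply nearly identical elicited statistics, and scale-type hyperparameters
  (prior sds, Gamma concentration/rate separately) are more weakly determined
  by the shipped statistic sets than locations. The recovery tolerances in
  the tests reflect that asymmetry.
* The single-replicate expert side makes each quantile/moment component an
  energy distance to a point; with very small $S$ the model-side replicate
  spread is partly MC noise, which mildly penalizes spread. At the shipped
  $S$ this effect is far below the recovery tolerances.
* Only the four prior families and four likelihood families needed by the
  studies are implemented; the LKJ correlation is 2x2 and its shape is fixed.
* The Gumbel-Softmax temperature is not annealed; $\tau = 1$ throughout.
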