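---
title: "Change sensitivity of longitudinal designs: effective error, ECR, and power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Change sensitivity of longitudinal designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgcmsens)
```

## The model

`lgcmsens` works with the univariate linear latent growth curve model
(LGCM) for complete, balanced longitudinal designs. Subject $i$ observed at
occasions $t_1 < \dots < t_M$ (in years) follows

$$x_{ij} = I_i + S_i\, t_j + \epsilon_{ij},$$

with latent intercept $I_i$ and slope $S_i$ jointly normal with means
$(\mu_I, \mu_S)$, variances $(\sigma_I^2, \sigma_S^2)$ and covariance
$\sigma_{IS}$, and i.i.d. residuals $\epsilon_{ij} \sim N(0,
\sigma_\epsilon^2)$, homoscedastic and uncorrelated across occasions. In
moment form, with $\Lambda = [\mathbf{1} \;\; \mathbf{t}]$,

$$\Sigma = \Lambda \Psi \Lambda' + \sigma_\epsilon^2 I, \qquad
  \mu = \Lambda \nu.$$

The scientific question the package serves is a design question: how well
can a planned study *detect individual differences in change*, i.e. reject
$H_0\!: \sigma_S^2 = 0$? The intercept is defined at time 0, so shifting
the time axis changes the meaning (and variance contribution) of the
intercept; this is a modelling choice with real power consequences, not a
cosmetic one.

## Precision and reliability indices

**Effective error.** A power-equivalent reduction of the LGCM condenses
the whole measurement side of the design into the error variance a
hypothetical *direct* one-shot measurement of the slope would have. With
$\sigma_{IS} = 0$,

$$\sigma^2_{\mathrm{eff}} =
  \frac{\sigma_\epsilon^2}{\sum_j t_j^2 - \eta \left(\sum_j t_j\right)^2},
  \qquad
  \eta = \frac{1}{M + \sigma_\epsilon^2 / \sigma_I^2},$$

implemented in `effective_error()`. $\eta$ is defined as 0 at
$\sigma_I^2 = 0$ by continuity (it is the limit from above, and matches
the ICC$_2 = 0$ limiting case). Effective error grows with residual
variance and with intercept variance, and shrinks as occasions are added
or spread out; because only $\sum t_j^2$ and $(\sum t_j)^2$ enter, it is
exactly invariant under a sign flip of the time axis — anchoring the
intercept at the first or the last occasion gives identical precision —
and, over all time shifts, it is *maximized* by the centered design
($\sum t_j = 0$).

**Reliability-style effect sizes.** Scaling a hypothesized slope variance
against error yields standardized, metric-free indices:

* `ecr()`: effective curve reliability,
  $\mathrm{ECR} = \sigma_S^2 / (\sigma_S^2 + \sigma^2_{\mathrm{eff}})$ —
  coherent with likelihood-ratio (LR) tests of zero slope variance;
* `grr()`: growth rate reliability,
  $\mathrm{GRR} = \sigma_S^2 / (\sigma_S^2 + \sigma_\epsilon^2 /
  \mathrm{SST})$, with SST the squared deviations of the occasions about
  their mean time — blind to intercept variance, coherent with the Wald
  test;
* `icc2()`: the intraclass correlation of $M$ repeated measures,
  $\sigma_I^2/(\sigma_I^2 + \sigma_\epsilon^2/M) = M\eta$.

ECR reduces to GRR when ICC$_2 \to 1$, when $\sigma_I^2 = 0$ with a
centered design, or whenever $\sum t_j = 0$. The "dispersion" column
reported by `compare_designs()` is SST$/(M-1)$, the sample variance of the
occasion times — a report convention, not a model quantity.

## From ECR to statistical power

Under the alternative, the LR statistic is approximately noncentral
$\chi^2$. From the minimal power-equivalent model the noncentrality is

$$\lambda = N \left[ \frac{1}{1-\mathrm{ECR}}
  - \ln \frac{1}{1-\mathrm{ECR}} - 1 \right],$$

(`noncentrality_from_ecr()`), and power is the noncentral tail beyond the
null critical value (`power_from_lambda()`). `satorra_saris_lambda()`
computes the same quantity without the closed form, as $N$ times the
minimized ML discrepancy

$$F = \ln|\Sigma_0| + \mathrm{tr}(\Sigma_1 \Sigma_0^{-1}) - \ln|\Sigma_1| - M$$

of the restricted model ($\sigma_S^2 = 0$, $\sigma_{IS} = 0$) against the
population moments $\Sigma_1$, with the mean structure unrestricted. With
nuisance parameters held at their true values the two routes agree to
machine precision for $\sigma_{IS} = 0$ (this identity is asserted in the
test suite to $10^{-6} N$ over randomized scenarios); with nuisance
parameters re-optimized (`nuisance = "free"`) $\lambda$ is smaller, which
is why analytic power systematically exceeds Monte Carlo power of fully
estimated models.

A second printed approximation, $\lambda \approx N\,
\mathrm{ECR}^2/(1-\mathrm{ECR})$, is provided verbatim as
`noncentrality_approx()` but never used internally: its leading Taylor
term is $N\,\mathrm{ECR}^2$, twice that of the exact expression
($N\,\mathrm{ECR}^2/2$), so the two disagree even for small effects.

**Generalized ECR.** For $\sigma_{IS} \neq 0$ no closed form exists.
`generalized_ecr()` computes the per-subject noncentrality $f = \lambda/N$
of the chosen test (1-df specific or 2-df generalized) via the discrepancy
construction and inverts $f = 1/(1-E) - \ln(1/(1-E)) - 1$ for $E$ by
bracketed root-finding (tolerance $10^{-12}$; $f$ below $10^{-12}$ is
treated as exact fit because $f \approx E^2/2$ amplifies noise near zero).
This is an interpretation of the published computational route — the
original algorithm's listing was not available — but it is the unique
construction consistent with the power-equivalence identity above, and it
collapses to the closed form when $\sigma_{IS} = 0$. One consequence worth
knowing: 2-df ECR is *not* monotone in $|\mathrm{cor}(I,S)|$; a mildly
negative covariance flattens observed variance growth and can transiently
lower the restricted model's misfit. The package tests therefore check
what actually holds: ECR tracks the ordering of 2-df Monte Carlo power.

## Null references at the boundary

$\sigma_S^2 = 0$ lies on the boundary of the parameter space, so with
non-negativity constraints the LR null distribution is a 50:50
$\chi^2_0/\chi^2_1$ mixture (df = 1) or $\chi^2_1/\chi^2_2$ mixture
(df = 2). The package's default is *unconstrained* variance estimation
(estimates may go negative) compared against plain $\chi^2$ critical
values: the plain reference is then the correctly calibrated one (the
type-I test in the acceptance suite verifies the empirical rate against
$\alpha$), and the mixture issue shifts all designs equally, so it cannot
change design *comparisons*. A constrained mode
(`mc_power(..., constrained = TRUE)`) with the mixture reference is
available for sensitivity analysis, as is
`power_from_lambda(..., null_reference = "boundary_mixture")`.

## ML fitting and the three tests

`lgcm_fit()` minimizes the multivariate-normal ML discrepancy between
sample moments and model-implied moments. Free latent means are profiled
out by GLS at each candidate covariance, so the optimizer (Nelder–Mead
with a simplex restart, relative tolerance $10^{-12}$) runs over at most
four covariance parameters; starting values come from a method-of-moments
decomposition of per-subject least-squares growth coefficients. On
failure the fit is retried from up to 5 jittered starts and flagged (never
silently dropped). Standard errors come from the observed information
(numerical Hessian of $-2\mathrm{LL}$ at the optimum).

The three tests of zero slope variance:

* `lr_test(s, "specific_1df")`: $\{\sigma_S^2 = 0, \sigma_{IS} = 0\}$
  versus $\{\sigma_{IS} = 0,\ \sigma_S^2\ \mathrm{free}\}$;
* `lr_test(s, "generalized_2df")`: the same null versus all three latent
  (co)variances free;
* `wald_test(fit)`: $\hat\sigma_S^2 / \mathrm{SE}(\hat\sigma_S^2)$,
  one-sided standard normal reference (the reference is a package choice;
  it is stated here because only relative behavior across designs
  matters).

For the Wald path of `mc_power()` the statistic is taken from the *fully
estimated* model (covariance free). This is deliberate: with the
covariance pinned at zero the Wald power inherits a strong dependence on
intercept variance through the information matrix, whereas the full-model
Wald is flat in ICC$_2$ — the behavior that motivates pairing GRR with the
Wald test in the first place. `wald_test()` itself accepts any fit with a
free slope variance, so the restricted variant remains available.

If the two nested fits ever produce a negative LR statistic, the larger
model is refit starting from the restricted solution and any residual
negative value is clipped at zero and flagged.

## Monte Carlo power

`mc_power()` simulates `nrep` complete samples, refits the model pair on
each, and reports the rejection fraction with its binomial standard
error. Per-replication seeds are derived from the master seed by a
Lehmer-style counter step, so replication $r$ is reproducible in
isolation. Non-convergent replications (after restarts) are excluded and
counted; more than 5% aborts the run. `nuisance = "fixed_true"` is an
oracle mode that holds untested parameters at truth, mirroring the
analytic construction — useful for validating the
analytic-versus-operational power gap.

## What the simulator does and does not emulate

`simulate_sample()` draws exactly from the model: multivariate normal,
complete data, a common occasion grid, homoscedastic uncorrelated
residuals, strictly linear mean and subject-level change. Means default to
zero where a scenario does not state them; the power of the variance tests
is invariant to the mean structure (it is unrestricted in both members of
every comparison), so this is a normalization, not an assumption about
data. Consequently, passing tests demonstrate internal coherence of the
indices and correct calibration *under the model*; they say nothing about
robustness to attrition, heteroscedastic or autocorrelated residuals,
nonlinear change, or floor/ceiling effects, all of which are out of scope.

## Numerical and design choices

* Simulation scenarios with "three equally spaced occasions" are
  instantiated as $\{0, 1, 2\}$ with the intercept at the first occasion;
  only spacing ratios matter for the qualitative patterns, and the choice
  is recorded in the scenario fixtures. Planning cases use
  $\{0, 2.5, 5\}$ ("3 times over 5 years") and
  $\{0, 0.25, 0.5, 0.75, 1\}$ ("every 3 months for 1 year").
* The reliability/stability heuristics
  (`params_from_reliability()`, `slope_var_from_stability()`) assume
  T-score scaling (total variance 100) by default and $\sigma_{IS} = 0$ as
  a starting point; a non-zero covariance is accepted as a sensitivity
  input. Reliability–stability combinations whose implied slope variance
  would be negative raise an error (or `NA` cells in
  `reliability_stability_table()`), reflecting that identical reliability
  and stability leave no room for individual differences in change.
* Test-suite problem sizes are chosen to keep the full suite at a few
  minutes on one core while leaving comfortable Monte Carlo margins: the
  headline power comparison uses the published 1000 replications at
  $N = 100$ (acceptance band ±0.05 ≈ 3 binomial SEs); qualitative pattern
  sweeps use 300 replications per condition; type-I calibration uses 2000
  replications on a three-occasion design; parameter recovery uses one
  $N = 5000$ fit checked within 3 SEs.
* Root-finding and λ-inversion tolerances are $10^{-12}$ absolute;
  noncentral $\chi^2$ tails use the library implementation, never
  hand-rolled quadrature.

## Limitations

Everything here assumes the linear LGCM is correctly specified. The
analytic chain further assumes known nuisance parameters, so treat
`analytic_power()` as an upper envelope and confirm a chosen design with
`mc_power()` — the gap is real (about 0.71 versus 0.50 in the five-annual-
occasion planning case at $N = 100$). Effective error comparisons across
studies require outcomes in a common metric. Attrition and
individually-varying occasion grids are not supported; neither are
nonlinear growth or dual-change-score models.
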