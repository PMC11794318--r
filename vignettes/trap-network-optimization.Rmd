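---
title: "Optimizing a pest-monitoring trap network: model, loss, and search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing a pest-monitoring trap network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A regional network of pheromone traps records weekly counts of an
agricultural pest (the motivating case is adult male *Helicoverpa zea*
caught in Hartstack-style traps across a row-crop landscape). Operating
every candidate location is expensive — each weekly collection round is a
long drive — so the practical question is: **which K of the L candidate
locations should stay in operation so that a model fitted to those K sites
predicts the unobserved sites as well as possible?**

`trapnet` implements the full pipeline for answering that question:

1. a data model for weekly trap counts (`trap_dataset()`, with imputation
   and cumulative transforms);
2. a Bayesian spatially-varying logistic growth model for cumulative
   counts (`fit_growth_model()`), with kriging prediction at unobserved
   locations (`predict_cumulative()`);
3. the mean-log-error loss on held-out sites (`mean_log_error()`,
   `holdout_loss()`), optionally cost-penalized
   (`cost_penalized_loss()`);
4. a Bayesian-Optimization loop over binary site-inclusion vectors
   (`bo_loop()`), with a brute-force oracle (`brute_force()`);
5. a Monte-Carlo experiment harness (`run_sweep()`) producing the mean
   loss per subset size and per-site inclusion proportions;
6. a synthetic-data generator (`generate_dataset()`) emulating the
   structure of the motivating four-season study, because the field data
   themselves are not publicly distributable.

## The growth model

Let $Z_{tsx}$ be the weekly count (in **hundreds of pests**) at site $s$
in season $t$, week $x$, and let $Y_{tsx} = \sum_{j \le x} Z_{tsj}$ be the
cumulative count, non-decreasing in $x$ by construction. The observation
model is

$$Y_{tsx} \sim \mathrm{Normal}\!\left(\mu(x; s), \sigma^2\right),
\qquad
\mu(x; s) = \frac{\beta(s)}{1 + \exp\{-(x - \gamma(s)) / k\}}.$$

$\beta(s)$ is the season-total asymptote at site $s$, $\gamma(s)$ the
midpoint week ($\mu(\gamma(s); s) = \beta(s)/2$), and $k > 0$ a growth
scale in weeks shared across sites (larger $k$ = slower growth). There is
no year effect — all seasons are pooled — and no covariates; spatial
structure enters only through the parameter fields:

$$\beta(\cdot) \sim \mathrm{GP}\!\left(\mu_\beta,\,
  \sigma_\beta^2 \Sigma_{\rho_\beta}\right), \qquad
\gamma(\cdot) \sim \mathrm{GP}\!\left(\mu_\gamma,\,
  \sigma_\gamma^2 \Sigma_{\rho_\gamma}\right),$$

with exponential correlation $\Sigma_{ij} = \exp(-\lVert s_i - s_j\rVert
/ \rho)$ over planar-kilometre coordinates. Note the process means
$\mu_\beta, \mu_\gamma$: a literally zero-mean field for a strictly
positive asymptote cannot generate plausible data, so the fields are
modelled as deviations around unknown means with weakly-informative
priors. This is a deliberate reading of the zero-mean notation common in
spatial-model write-ups.

### Posterior computation

No general-purpose MCMC engine is assumed; the sampler is part of the
package (`R/mcmc.R`). It exploits the model's conditional structure:

* $\beta$-field, $\sigma^2$, $\mu_\beta$, $\mu_\gamma$,
  $\sigma_\beta^2$, $\sigma_\gamma^2$ — exact conjugate Gibbs draws (the
  likelihood is linear in $\beta(s)$ given the logistic factor);
* $\gamma$-field — per-site random-walk Metropolis with the exact GP
  conditional prior;
* $k$, $\rho_\beta$, $\rho_\gamma$ — random-walk Metropolis on the log
  scale.

Proposal scales adapt toward a 0.44 acceptance rate during warm-up only.
Priors: Normal (data-centred, very wide) on the process means;
Inverse-Gamma(2, data-scaled) on the three variances — conjugacy is the
reason Inverse-Gamma was chosen over half-Normal on the standard
deviations; both are weakly informative here and the originating study's
exact priors are not public; Gamma(2, rate 0.5) on $k$; uniform on
$[d_{\min}/10,\, 10\,d_{\max}]$ for the ranges, where $d_{\min}, d_{\max}$
are the extreme pairwise distances among training sites. A jitter of
$10^{-8}$ is added to correlation diagonals before factorization.
Convergence is summarised by split-$\widehat R$; values above 1.05 raise a
warning, never an error, because the optimization loop must tolerate the
occasional hard fit.

Profiles: `mcmc_config(profile = "full")` (4 chains, 1000 + 1000) for
final analyses; `"fast"` (1 chain, 300 + 300, thinned to 50 draws) for
the many fits inside the optimization loop; `"turbo"` for test-scale
runs. A fast fit of the 21-site schedule takes well under a second, which
is what makes the Monte-Carlo experiment tractable.

### Prediction at unobserved sites

Simple kriging per posterior draw:
$\beta_d(s^*) = \mu_{\beta,d} + r^\top C_d^{-1}(\beta_d - \mu_{\beta,d})$
with $r_i = \exp(-\lVert s^* - s_i \rVert / \rho_{\beta,d})$, same for
$\gamma$; the predicted cumulative count is the posterior mean of the
logistic curve over draws. At a training site the weights collapse to an
indicator, so predictions interpolate the fitted values exactly (there is
no nugget in the process layer). Kriged asymptotes can in principle be
negative under the Normal field; predictions are clipped at zero in the
reporting layer only, never in the likelihood.

## The loss and the search

For a subset $S_i$ of size $K$, the model is fitted on $S_i$ and scored at
the held-out sites by the **mean log error**

$$\mathrm{MLE}(S_i) = \frac{1}{n}\sum_{\text{cells}}
\log\!\left(\lvert Y - \hat Y(S_i)\rvert + 1\right),$$

with the natural log, counts in hundreds, and $n$ the number of evaluation
cells. The normalizer is implemented as the generic cell count, which
reduces to the fixed-schedule constant when every held-out site has the
full test-season week range. Cumulative counts span orders of magnitude
within a season; the log transform keeps early- and late-season cells
comparable. An MLE of $m$ corresponds to a typical miss of
$(e^m - 1) \times 100$ pests (`mle_to_count_error()`). During
optimization the loss is computed within the training seasons
(leave-sites-out, in-years); the final evaluation scores the held-back
test season. For the final fit window the package defaults to fitting the
chosen subset on **all** seasons including the test season and scoring
the held-out sites in the test season; `fit_window = "test_only"`
restores the alternative reading in which the final model sees only the
test season. An additive cost extension
$\mathrm{MLE}(S_i) + \lambda C(S_i)$ is provided; $C$ defaults to a sum
of per-site costs, and any callable (e.g. a tour length) can replace it.

Minimizing over $\binom{L}{K}$ subsets is combinatorial (50 candidates
choose 20 already exceeds $10^{13}$), and each evaluation is an MCMC fit,
so the search is Bayesian Optimization with a deliberately simple
surrogate: $f_b(x) = x^\top b$ over the binary inclusion vector, fitted
by Bayesian linear regression with no intercept (the fixed row sum makes
one unidentifiable) and a vague proper Normal prior (so the posterior
survives fewer evaluations than sites). $b_j$ is interpretable as site
$j$'s marginal contribution to the loss. The acquisition rule picks the
$K$ smallest posterior-mean coefficients — the exact constrained minimizer
of the linear surrogate — with ties at the $K$-th order statistic broken
by site index so exactly $K$ sites are always proposed. Because that rule
is pure exploitation it can re-propose an evaluated design; the loop then
draws up to 10 Thompson samples of $b$ and falls back to a random unseen
subset, so every round adds a new design. After $B$ rounds the incumbent
over all $N_0 + B$ evaluations is returned. $N_0 = 20$ and $B = 30$ are
package defaults (the originating description leaves them unstated).

## The synthetic world

`sim_scenario()` defaults to the schedule of the motivating study: 21
sites, seasons of 6/7/10/11 weekly collections, site 3 absent for the
whole first season (excluded, not imputed — 83 observed site-year
combinations), and site 13's week-2 collection of the final season
flagged missing (imputed as the mean of the other sites' counts for that
week). That schedule implies 708 weekly records; the study's own printed
total is 705, an unexplained three-record difference that the generator
does not attempt to reproduce. Truth values are documented package
choices, not published values: $\mu_\beta = 15$ (hundreds), $\mu_\gamma =
6$ weeks, $k = 1.5$, $\sigma = 0.5$, $\sigma_\beta = 4$, $\sigma_\gamma =
1$, $\rho_\beta = \rho_\gamma = 10$ km, sites uniform in a 30 × 30 km
box with 1% minimum separation. They are sized so trajectories run from
tens of counts early to thousands late on the raw-pest scale.

One numerical subtlety: Normal noise on the cumulative scale can violate
monotonicity, but real cumulative counts cannot decrease. The generator
therefore applies a running maximum (isotonic projection) to the noisy
cumulative path before differencing into weekly counts, while the fitted
likelihood remains plain Normal. The projection binds mainly where the
curve is flat relative to the noise (early season), where it slightly
inflates near-zero cells; at the default noise level this biases the
posterior of $k$ upward by a few percent. Calibration statements about
the sampler are therefore tested at low noise, where the projection is
inert; the mismatch at moderate noise is a property of the emulated world,
not a sampler defect. `generate_dataset(allow_nonmonotone = TRUE)`
additionally returns the raw unprojected paths for likelihood-exactness
experiments.

What a green synthetic test does and does not establish: the generator
shares the fitted model's functional form, so recovery and dominance
results confirm the machinery, not the model's adequacy for real trap
data (no trap failures beyond the scripted ones, no year effects, no
covariate structure, no overdispersion).

## Scaling choices in the shipped tests

* The BO-dominance experiment runs the stated K grid {5, 8, 11} and 10
  Monte-Carlo repetitions with the fast MCMC profile, but a reduced
  per-repetition budget ($N_0 = 6$, $B = 8$) so the whole suite stays
  within a continuous-integration time budget; thresholds are unchanged
  (BO mean loss ≤ random at every K, Spearman $\rho \le -0.8$ across K).
* Parameter recovery uses 2 chains × 800 + 800 thinned draws.
* The k-interval calibration check uses 8 replicates of a 3-season,
  8-site schedule at low noise (see above).

## Known limitations

* The Normal observation model ignores the monotone support of cumulative
  counts; a monotone likelihood (or increment-level model) would be the
  principled fix and is out of scope here.
* Simple kriging of the parameter fields propagates parameter uncertainty
  but not field-interpolation uncertainty into the reported predictive
  interval; intervals at far-away targets are therefore optimistic.
* The linear surrogate cannot represent interaction between sites
  (complementarity/redundancy of nearby traps); it is the stated design
  and the reason multiple Monte-Carlo restarts are reported rather than a
  single run.
* Inverse-Gamma variance priors are a conjugacy-motivated substitute for
  half-Normal priors on standard deviations; at these data sizes the
  difference is immaterial, but very small training subsets (K = 2, 3)
  lean more on the prior.
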