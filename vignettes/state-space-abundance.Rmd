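---
title: "A zero-inflated state-space model for multi-colony abundance indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A zero-inflated state-space model for multi-colony abundance indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Emperor penguins breed on fast ice in winter and early spring, mostly far
from research stations, so only a handful of colonies have ever been
counted directly. Very-high-resolution satellite imagery detects every
colony, but what it delivers is the area of guano-stained "penguin
pixels" — an imprecise, potentially biased index that exists for some
colony-years only, with subjective image quality varying from poor to
good. A few colonies add repeated within-season aerial, ground or
remote-camera counts. `pengindex` fuses these unbalanced sources in a
single Bayesian state-space model and reports colony, regional and
global indices of adult abundance with full posterior uncertainty.

## The model

Let $X_{j,y} > 0$ be the latent abundance index of colony $j$ in year
$y$ and $z_{j,y} \in \{0,1\}$ its presence; the reported index is
$N_{j,y} = z_{j,y} X_{j,y}$.

**Process.**
$$X_{j,1} \sim \mathrm{lognormal}(\log \bar X_1,\ \sigma^2_{\log X_1}),
\qquad
X_{j,y} \sim \mathrm{lognormal}(\log X_{j,y-1} + r_j,\ \sigma^2_{proc}),$$
$$z_{j,y} \sim \mathrm{Bernoulli}(p), \qquad
r_j \sim \mathrm{Normal}(\bar r, \sigma^2_r).$$

The colony-level random effect $r_j$ regularizes growth-rate estimates
for colonies with sparse data; $p$ is global because colony "blinking"
(a colony failing to form in a year and reappearing later) is too rare
to estimate per colony. The latent trajectory $X$ keeps evolving through
absent years: absence suppresses the observable index, not the colony's
underlying size.

**Direct counts** (aerial, ground and camera pooled, conditional on
$z = 1$), with centred survey day $d$ (day-of-year minus 289, the
survey-season mid-point):
$$c \sim \mathrm{lognormal}\!\left(\log X_{j,y} + \alpha d -
\tfrac{1}{2}\sigma^2_{a},\ \sigma^2_{a}\right).$$
The $-\sigma^2_a/2$ term is the lognormal variance correction that makes
$\mathbb E[c] = X_{j,y} e^{\alpha d}$ exactly; $\alpha$ (per day,
log-linear) absorbs the within-season decline in attendance as failed
breeders and non-breeders leave.

**Satellite values** (area-derived, pre-converted to the adult-count
scale), with quality class $q \in \{1,2,3\}$:
$$S \sim \mathrm{Normal}\!\left(\beta_q\, \mu,\ (\mu\, \mathrm{CV}_q)^2\right),
\qquad \mu = N_{j,y} e^{\alpha d}.$$
The constant coefficient of variation means larger colonies get larger
absolute but equal proportional error, and the error vanishes when a
colony is truly absent: at $N = 0$ the distribution is a point mass at
zero. The displayed variance uses $\mu$, not $\beta_q \mu$; the text
description puts the bias constant in the mean. We follow both (mean
with $\beta$, sd without), and both choices are switchable
(`prior_config(beta_in_mean=, beta_in_variance=)`) because the source
presentation is ambiguous.

**Observed zeros.** A zero count or zero satellite value is taken as
evidence of absence and routed through the degenerate branch: it is
consistent (log-density 0) with $z = 0$ and impossible under $z = 1$.
The absolute tolerance `eps_abs` (default $10^{-6}$ on the count scale)
only guards against floating-point noise. A colony-year carrying both a
zero and a positive observation is rejected at fit time — the model
assigns it no consistent presence state.

## Priors

The hyperpriors are package defaults (the source's exact priors live in
unpublished supplementary material): $\bar r \sim N(0, 0.5^2)$;
$\sigma_r, \sigma_{proc}, \sigma_a \sim$ half-Normal(0, 1);
$p \sim U(0,1)$; $\alpha \sim N(0, 0.1^2)$ (a 10%-per-day effect is
already extreme); $\beta_q \sim \mathrm{lognormal}(0, 0.5^2)$;
$\mathrm{CV}_q \sim$ half-Normal(0, 0.5). All are overridable via
`prior_config()` or a plain-text `key: value` file. $\bar X_1$ and
$\sigma_{\log X_1}$ are estimated empirically from first-year
observations at initialization and held fixed (geometric mean and log-sd
of the initialized first-year abundances; the sd is floored at 0.3 so a
near-empty first year cannot produce a degenerate prior).

## Sampling

`fit_colony_model()` runs an adaptive Metropolis-within-Gibbs sampler
(compiled): log-scale random walks for each $X_{j,y}$ and for the
non-conjugate scalars ($\alpha$, $\sigma$'s, $\beta_q$, CV$_q$), exact
conjugate draws for $r_j$, $\bar r$ (normal) and $p$ (beta), and the
exact two-point full conditional for free $z_{j,y}$. Because positive
observations force $z = 1$ and zero observations force $z = 0$, only
unobserved colony-years have free presence indicators, and their full
conditional reduces to Bernoulli($p$). Proposal scales adapt in batches
of 50 toward 44% acceptance during burn-in only and are then frozen, so
the retained kernel is fixed and draws are bit-reproducible given the
seed. Chains start from jittered data-derived initial values
(observation means carried forward/backward; see `initialize_state()`).

The reference protocol is 3 chains, 50 000 burn-in iterations, then
every 50th kept until 10 000 draws per chain. Desk-scale work (tests,
simulation replicates) uses `mcmc_config_test()` (1000 burn-in, thin 5,
1000 stored): on 50 colonies x 10 years this passes the same
convergence bar (all potential scale reduction factors < 1.1) in about
two seconds, which is what makes the 100-replicate identifiability
study runnable on one CPU in minutes.

## Diagnostics and checks

`gelman_rubin()` implements the classic (non-split) potential scale
reduction factor including the sampling-variability term
$\hat R = \sqrt{\hat V/W + B/(mnW)}$, optionally on split chains;
`effective_sample_size()` uses Geyer's initial monotone
positive-sequence truncation of FFT-computed autocorrelations, summed
over chains. That estimator is mildly conservative for strongly
autocorrelated chains, which is the safe direction for a convergence
bar. Diagnostics cover hyperparameters, colony effects and latent $X$;
the binary $z$ is excluded (a frequently-constant indicator has no
defined PSRF) and is monitored through $N = zX$.

`posterior_predictive_check()` simulates every observed slot from the
observation models, pairing replicate $r$ with stored draw $r$, and
compares RMSE discrepancies against each draw's expectations — the
realized-discrepancy construction; the source does not pin down the
conditioning, and this is the standard choice. Direct-count and
satellite checks are separate statistics. On model-generated data both
Bayesian p-values should sit in roughly (0.2, 0.8) — but note that the
pooled RMSE is dominated by the few largest colonies, so the p-value of
any one dataset is heavy-tailed across datasets; occasional excursions
outside that band on a single synthetic dataset are expected, and the
calibration tests therefore judge the median over several independent
datasets. A p-value pinned near 0 or 1 across datasets flags systematic
misfit.

## The simulator and what a green test establishes

`simulate_truth()` / `simulate_observations()` generate from exactly
the model above. The default `design_config()` encodes the empirical
survey imbalance: 5 of 50 colonies with 1–5 direct counts per year,
every colony-year carrying 0/1/2 satellite images with probabilities
0.3/0.5/0.2 (mean 0.9 images per colony-year, matching ~460 images over
500 colony-years), quality probabilities 0.25/0.35/0.40, and survey
days uniform on 274–319. `fixture_hyperparams()` stands in for the
unpublished empirical estimates: $\bar r = -0.013$ (≈ −1.3%/yr),
$\sigma_r = 0.05$, $\sigma_{proc} = 0.15$, $p = 0.97$,
$\alpha = -0.005$/day, $\sigma_a = 0.1$, $\beta = (0.8, 0.9, 1.0)$ and
CV = (0.30, 0.20, 0.10) ordered so poor images are more biased and
noisier, $\bar X_1 = 5000$, $\sigma_{\log X_1} = 1$. Counts are rounded
to integers (floored at 1 when the colony is present, so rounding never
fabricates an absence).

The generator deliberately omits features real data may have: spatial
correlation between neighbouring colonies, movement of birds between
colonies (which can masquerade as local decline), colony-specific
phenology ($\alpha$), and any detectability process distinct from true
absence. A green simulate–refit test therefore establishes
self-consistency — the sampler targets the stated posterior and the
trend is identifiable under realistic sparsity — not robustness to
those violations.

## Numerical choices

* Latent abundances are sampled as $\log X$; positivity is structural.
* Adaptation uses the batch log-step rule with $\pm\min(0.1,
  \text{batch}^{-1/2})$ increments, frozen after burn-in.
* `prob_decline()` uses strict `<` against the threshold (ties have
  probability zero for continuous posteriors); the inclusive variant is
  a flag.
* `annual_trend()` is the per-draw OLS slope of log index on year
  (closed form), reported as $100(e^b - 1)$; an endpoint-ratio variant
  is provided because "log-linear annual rate of change" is not
  operationally defined in the source.
* Draws with a zero base-year index (global extinction in that draw)
  make percent change undefined and are excluded with a logged count;
  `change_summary()` returns `NA` rows when no draw defines the change.
* Quantiles use R's default rule (type 7).
* Replicate seeds in `run_study()` are `seed + i`, making studies
  restartable and individually reproducible.

## Known limitations

* No colony-specific $\alpha$ or $p$, and no detectability layer — both
  flagged as future work in the source and out of scope here.
* The sea-ice correlation is reported for both candidate regional
  scalars (probability of decline, median change) because the source is
  ambiguous about which produced its printed value.
* With very sparse data the posterior of $X$ at unobserved
  colony-years is prior-dominated; regional summaries inherit that
  uncertainty honestly rather than imputing.
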