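---
title: "Modeling rapid guessing from responses and response times: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling rapid guessing from responses and response times: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its model, its sampler, the
synthetic-data generator, and the numerical and design choices behind
them — including the ones that were genuinely open and the limitations a
user should know about.

## The mixture hierarchical model

Speeded tests produce two behaviors per person-item cell. The latent
indicator $\eta_{ij}\in\{0,1\}$ separates them:

*Solution behavior* ($\eta_{ij}=0$): the response follows the
two-parameter logistic (2PL) model
$$P(Y_{ij}=1\mid\theta_i) = \frac{\exp[a_j(\theta_i-b_j)]}{1+\exp[a_j(\theta_i-b_j)]},$$
and the response time is lognormal,
$\log T_{ij}\sim N(\lambda_j-\tau_i,\ \sigma_j^2)$: $\lambda_j$ is how
time-consuming the item is (its exponential is the median time in
minutes for an average-speed person), $\tau_i$ is how fast the person
works, and $\sigma_j^2$ is the item's log-time dispersion.

*Rapid guessing* ($\eta_{ij}=1$): the response is correct with an
item-specific probability $g_j$ regardless of ability, and the time
follows one common lognormal law
$\log C_{ij}\sim N(\mu_c,\sigma_c^2)$ shared by all cells — rapid
guesses are fast in the same way everywhere.

Persons carry a guessing propensity $\pi_i=P(\eta_{ij}=1)$, and
$(\theta_i,\tau_i)$ are bivariate normal so that the model can express
whether able examinees also work fast. Assumptions worth stating
explicitly: $\eta_{ij}$ are conditionally independent Bernoulli given
$\pi_i$ (the model does not itself know that time pressure puts guesses
at the *end* of a test — that structure enters only through the data);
guessing times do not depend on person or item; and response times are
conditionally independent of responses given the parameters.

**Units.** Time is minutes throughout. With $\lambda_j$ near zero the
median item time is near one minute, so 20- and 40-item tests pair
naturally with 40- and 80-minute limits.

**Identification.** Location and scale trade-offs between person and
item parameters are removed structurally: $\mu_\theta=0$,
$\sigma^2_\theta=1$, $\mu_\tau=0$ are fixed and never sampled
(`population_params()` stores them; `enforce_identification()` resets
them). The free population parameters are $\sigma_{\theta\tau}$,
$\sigma^2_\tau$, $\mu_c$, $\sigma^2_c$.

## Priors

`speedmix_priors()` defaults, chosen diffuse except where a parameter
needs gentle regularization:

| parameter | prior | default |
|---|---|---|
| $a_j$ | $N(\mu_a,\sigma_a^2)\,I(a_j>0)$ | $N(0,10^5)$ truncated |
| $b_j$, $\lambda_j$ | normal | $N(0,10^5)$ |
| $g_j$ | Beta$(\iota_3,\iota_4)$ | Beta$(5,17)$ (mean 0.23) |
| $\pi_i$ | Beta$(\iota_1,\iota_2)$ | Beta$(1,5)$ |
| $\sigma_j^2$, $\sigma_c^2$, $\sigma_\tau^2$ | inverse gamma | IG$(10^{-4},10^{-4})$ |
| $\mu_c$ | flat | — |
| $\sigma_{\theta\tau}$ | uniform over the constraint region | — |

The Beta$(5,17)$ prior keeps $g_j$ near the plausible multiple-choice
range even for items almost nobody guesses on; everything else lets the
data speak.

## The sampler

Each iteration runs a fixed scan of fourteen updates. The logistic
likelihood of the 2PL is made conditionally Gaussian by Pólya-gamma
augmentation: for every solution-behavior cell an auxiliary
$W_{ij}\sim \mathrm{PG}(1, |a_j(\theta_i-b_j)|)$ is drawn, after which
$a_j$, $b_j$ and $\theta_i$ have closed-form (truncated) normal full
conditionals. All sums in those conditionals run over
solution-behavior cells only — rapid-guess cells carry no information
about the 2PL or the solution-time parameters, and their conditionals
reduce exactly to the prior when a whole item or person is guessed
(empty-sum reduction; this is also how the updates behave at the
degenerate edge, rather than erroring). $W$ values of guessed cells are
left stale: no downstream sum reads them, and skipping them halves the
augmentation cost at high speededness.

The remaining conjugate updates are standard: Bernoulli for
$\eta_{ij}$ from the two branch likelihoods (computed in log space),
Beta for $\pi_i$ and $g_j$, normal for $\tau_i$ and $\lambda_j$,
inverse gamma for the variances, and a normal/inverse-gamma pair for
$(\mu_c,\sigma_c^2)$ from the currently-guessed cells; when no cell is
flagged as a guess, that update is skipped and counted (the count is in
the run log).

**PG(1, z) generation.** The exact Devroye-type rejection sampler is
implemented in C++ against R's RNG (so `set.seed()` makes whole chains
bit-reproducible; `rpg()` exposes it). The defining infinite gamma
mixture, truncated at $K$ terms, is kept as a deliberately slow,
independent test oracle (`rpg_series()`); its truncation bias is bounded
by $(2\pi^2)^{-1}\sum_{k>K}(k-\tfrac12)^{-2}$ and the exact sampler is
required to match it in distribution and to satisfy
$E[W]=\tanh(z/2)/(2z)$.

**Constrained covariance.** $\sigma_{\theta\tau}$ and $\sigma^2_\tau$
get random-walk Metropolis-Hastings updates with truncated-normal
proposals whose bounds are exactly the positive-definiteness region
(given $\sigma_\theta^2=1$): $|\sigma_{\theta\tau}|<\sigma_\tau$ first,
then $\sigma_\tau^2>\sigma_{\theta\tau}^2$. Acceptance ratios include
the $\Phi$-based normalization of the truncated proposals, so the
covariance matrix is positive definite at every retained iteration — a
property the test suite asserts draw by draw. Proposal scales default to
$s_{01}=s_{02}=0.05$ with batch adaptation during burn-in toward a
25–40% acceptance rate, frozen afterwards to preserve the stationary
distribution. Adaptation is floored at 0.01: near the
positive-definiteness boundary the acceptance rate stays low at *any*
scale, and letting the proposals shrink indefinitely would freeze the
chain's movement along the boundary (see Limitations).

**Initialization.** Starting values are method-of-moments quantities:
standardized logit proportion-correct for $\theta$, centered negative
row-mean log-times for $\tau$ (at their natural scale), column-mean
log-times for $\lambda$, neutral item values otherwise, and — for the
covariance block — the empirical covariance of those person proxies,
disattenuated by Cronbach's $\alpha$ of the responses and clipped inside
the positive-definiteness region. The data-driven covariance start
matters: with strongly correlated populations the posterior over
$(\sigma_{\theta\tau},\sigma_\tau^2)$ is a narrow ridge along the
boundary, and a far-off start would let the chain settle at an arbitrary
ridge point (which silently rescales abilities and discriminations).
Multi-chain fits with `overdispersed = TRUE` jitter the measurement and
person starts but share the covariance start, so that convergence
diagnostics measure mixing of the monitored item parameters rather than
the boundary geometry.

**Numerical choices.** All densities are evaluated in log space; the
only clamp is on the log odds of the behavior update (at $\pm700$,
counted and reported, essentially never hit away from degenerate
$\pi_i$). Chains abort with the offending update named if a non-finite
value appears. Label switching needs no handling: the two mixture
components are anchored by different response *and* time models, so they
are not exchangeable.

## Model assessment

`assess()` computes DIC and LPML from the per-draw joint log-likelihood,
evaluated cell by cell conditional on that draw's $\eta$ (the mixture
likelihood factorizes over cells given $\eta$):
$\overline{\mathrm{Dev}}=-\tfrac2M\sum_m \log f^{(m)}$,
$\widehat{\mathrm{Dev}}=-2\max_m \log f^{(m)}$,
$\mathrm{DIC}=\widehat{\mathrm{Dev}}+2(\overline{\mathrm{Dev}}-\widehat{\mathrm{Dev}})$.
The plug-in uses the best retained draw, so the effective number of
parameters $p_D$ is nonnegative by construction. Whether a
$\eta$-marginalized likelihood would be preferable is a genuinely open
question; the conditional version is what the sampler can accumulate
exactly and is used consistently for both models being compared. The
per-cell log CPO uses the stabilized harmonic-mean estimator (subtract
the per-cell maximum of $-\log f^{(m)}$ before exponentiating — without
it the estimator overflows on any realistic dataset), accumulated
streamingly during sampling with a rescaling max-tracker so the
$M\times N\times J$ array never needs to be materialized
(`store_cell_loglik = TRUE` keeps it anyway for small fits; the suite
checks the streaming and batch paths agree to $10^{-9}$).

## Diagnostics

`psrf()` implements the Gelman-Rubin statistic in the
$\sqrt{(M-1)/M + B/(MW)}$ between/within form (cross-checked in the
tests against `coda`'s implementation), computed per scalar parameter
across chains; the package's studies use the conventional 1.2
threshold. `hpdi()` is the shortest-interval-of-sorted-draws (Chen-Shao)
construction at 95% mass by default — chosen over equal tails because
posterior summaries here are routinely needed for skewed variance
parameters.

## The synthetic-data generator

`simulate_speeded()` emulates a linear (fixed-form) timed test:

1. Draw item truth: $a_j\sim N(0,1)I(>0)$, $b_j\sim N(0,1)$,
   $\lambda_j\sim U(-0.25,0.25)$ (low speededness) or $U(0.25,0.75)$
   (high), $g_j=0.25$, $\sigma_j^2=0.25$; persons from the reference
   population below; guessing times $\log C\sim N(-2,0.25)$ (median
   8 seconds).
2. Simulate the full solution phase: 2PL responses, lognormal times.
3. Impose the limit (2 minutes per item by default): each person whose
   solution-phase total exceeds it switches to rapid guessing *from the
   last item backward* — each switched cell's time is replaced by a
   fresh guessing-time draw and its response by Bernoulli($g_j$), the
   running total recomputed after every replacement until it fits.
   Guessed cells therefore form a contiguous suffix, and everyone
   flagged ends within the limit; both properties are asserted in the
   tests.

Responses of switched cells are regenerated rather than kept because the
model defines guessed responses by $g_j$; keeping the solution-phase
response would contaminate the truth the recovery studies score
against.

**The reference population is deliberately degenerate.** The default
`population_params()` covariance is $\sigma_{\theta\tau}=0.5$ with
$\sigma^2_\tau=0.25$ — correlation exactly 1, i.e. speed *determines*
ability in the generated data. This is the package's reference stress
condition: it produces the strongest speed-accuracy coupling the model
permits and exercises the sampler at the positive-definiteness boundary
where estimation is hardest. It is a valid (singular) bivariate normal;
the fitted model never needs the generating covariance to be
nonsingular. Any other covariance can be supplied
(`population_params(sigma_thetatau = 0.25, sigma2_tau = 0.25)` gives a
well-conditioned correlation-0.5 population), and
`simulate_study2()` uses unit-variance populations with correlation 0.3
or 0.8 for the model-comparison study.

Under the reference conditions the 20-item, 1000-person generator
leaves about 13–14% (low speededness) and 45% (high) of examinees unable
to finish, and marks about 3.4% and 15% of cells as rapid guesses —
these proportions, averaged over 50 replications, are what the
acceptance script reports. A single dataset's proportions scatter by
roughly ±2 percentage points around those means because all persons
share one draw of the 20 time intensities.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: adaptive item selection (real
speeded data often come from CATs), missing responses, partial
disengagement (slow guessing, item skipping), guessing times that vary
by person or item, non-lognormal time distributions, and guessing that
arises anywhere but at the end of a test.

## Study harnesses and problem sizes

`study_recovery()` replicates simulate-and-refit and scores EAPs against
truth (bias and MSE per parameter block); `study_model_selection()` fits
both models to data from a chosen generator and reports DIC/LPML
quartiles and selection rates. Truth is redrawn each replication
(replication $r$ seeds with `seed + r`).

The package's own test and acceptance runs use desk-scale sizes, chosen
to keep the full suite in the tens of minutes on one CPU: recovery at
N = 1000, J = 20 with 6–10 replications of 5000 iterations (1000
burn-in), the N = 2000, J = 40 condition with 2 replications of 1200
iterations, model selection at N = 250, J = 40 with 10 replications, and
four chains of 2000 iterations for the convergence check. Production
analyses should scale these up (the reference study design behind the
defaults used 20 000 iterations with 10 000 burn-in and 50
replications); estimates reported here are stable at the desk scale for
everything except the covariance block, whose posterior is
boundary-ridge-shaped under the reference population.

## Known limitations

- **A broad guessing-time mode under weak contamination.** With the
  scale-invariant IG$(10^{-4},10^{-4})$ prior on $\sigma_c^2$, the
  guessing component can absorb the fast tail of *solution* responses:
  $(\mu_c,\sigma_c^2)$ drift toward a wide distribution centered near
  $-1$ to $-1.5$ and $g_j$ and $\pi_i$ inflate. Every full conditional
  has been verified against grid and brute-force oracles, so this is
  genuine posterior behavior of the diffuse-prior model, most visible at
  low speededness (few true guesses) and weaker person correlation; with
  strong contamination or a near-singular population the well-separated
  mode dominates. Consequences show up as upward bias in $\mu_c$,
  $\sigma_c^2$ and mild upward bias in $g$. A mildly informative
  $\sigma_c^2$ prior (or a propensity prior concentrated near zero when
  no guessing is expected — the mixture then reduces to the plain
  hierarchical model, as the tests check) suppresses it.
- **Weak scale identification at the correlation boundary.** When the
  data carry a person correlation at or near 1, the posterior over
  $(\sigma_{\theta\tau},\sigma^2_\tau)$ collapses onto the
  positive-definiteness boundary and is nearly flat along it; the
  single-site random-walk updates cannot traverse that ridge at
  desk-scale chain lengths, so where a chain settles depends on its
  start (hence the data-driven covariance initialization), and the
  ability/discrimination scale is correspondingly soft. Population
  covariance estimates from such data should be read as
  ridge-constrained, not as precise marginals.
- **Near-zero discriminations leave difficulty unidentified.** The
  reference truth draw $a_j\sim N(0,1)I(>0)$ puts ~8% mass below 0.1;
  such an item's $b_j$ posterior under the diffuse prior is essentially
  its prior, so replication-averaged MSE($b$) is heavy-tailed and can be
  dominated by a single weak item. This is a property of the design, not
  of the sampler; with discriminations bounded away from zero the
  difficulty recovery is tight.
- The non-mixture fit keeps the guessing-block parameters frozen at
  their starting values (they are reported in the draws matrix for
  shape-compatibility; ignore them).
- Missing responses are rejected, not modeled; alternative
  identification schemes (anchor items, sum/product constraints) are not
  implemented.
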