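# speedmix

Bayesian mixture modeling of rapid guessing on speeded tests, from item
responses and response times jointly.

When a timed test runs out, many examinees stop engaging with the items
and start guessing rapidly. Treating those responses as ordinary answers
biases item calibration and ability estimation. `speedmix` is for
psychometricians and measurement researchers who have an N × J binary
response matrix and the matching response-time matrix (in minutes) and
want to (i) detect rapid-guessing behavior at the person-item level,
(ii) calibrate items and score examinees with that behavior modeled, and
(iii) test whether the mixture structure is warranted at all.

## The model

Each person-item cell carries a latent behavior indicator
η<sub>ij</sub> (1 = rapid guessing, 0 = solution behavior):

- **Responses.** Under solution behavior, a two-parameter logistic model
  P(Y<sub>ij</sub> = 1) = exp[a<sub>j</sub>(θ<sub>i</sub> − b<sub>j</sub>)] /
  (1 + exp[a<sub>j</sub>(θ<sub>i</sub> − b<sub>j</sub>)]) with item
  discrimination a<sub>j</sub>, difficulty b<sub>j</sub> and ability
  θ<sub>i</sub>. Under rapid guessing, success is an item-specific
  constant g<sub>j</sub>.
- **Response times.** Under solution behavior,
  log T<sub>ij</sub> ~ N(λ<sub>j</sub> − τ<sub>i</sub>, σ²<sub>j</sub>)
  with time intensity λ<sub>j</sub> and person speed τ<sub>i</sub>.
  Rapid guesses share a common lognormal law,
  log C<sub>ij</sub> ~ N(μ<sub>c</sub>, σ²<sub>c</sub>).
- **Persons.** η<sub>ij</sub> ~ Bernoulli(π<sub>i</sub>) with a
  per-person guessing propensity; (θ<sub>i</sub>, τ<sub>i</sub>) are
  bivariate normal with μ<sub>θ</sub> = μ<sub>τ</sub> = 0 and
  σ²<sub>θ</sub> = 1 fixed for identification, and free covariance
  (σ<sub>θτ</sub>, σ²<sub>τ</sub>) kept positive definite.

Estimation is fully Bayesian: a Gibbs sampler whose logistic updates are
made conditionally Gaussian by Pólya-gamma augmentation (an exact
Devroye-type PG(1, z) generator is implemented in C++), with
Metropolis-Hastings updates for the constrained person covariance. Model
comparison against the no-guessing hierarchical model uses DIC and
CPO/LPML; convergence is monitored with the Gelman-Rubin PSRF.

## Worked example

Simulate a 15-item, 300-person speeded test at a high speededness level
(items draw time intensities from U(0.25, 0.75), 30-minute limit), then
fit the mixture and the non-mixture models:

```r
library(speedmix)
design <- sim_design(N = 300, J = 15, speededness = "hsl")
sim <- simulate_speeded(design, seed = 42)
sim
#> Simulated speeded-test data: 300 persons x 15 items
#>   time limit: 30 min; 42.7 % unfinished; 15.16 % of cells rapid-guessed

fit <- speedmix(sim$Y, sim$time, iter = 1000, burnin = 500, seed = 1)
fit
#> Rapid-guessing mixture model fit (Polya-gamma Gibbs)
#>   data: 300 persons x 15 items
#>   chains: 1, iterations: 1000 (burn-in 500, thin 1)
#>   posterior mean guessing rate: 0.1541
#>   MH acceptance (covariance, speed variance): 0.076, 0.067

head(summary(fit), 4)
#>  parameter    eap     sd  hpdi_low hpdi_high
#>       a[1] 1.9096 0.3153 1.2973437    2.5003
#>       a[2] 0.1747 0.1287 0.0001192    0.3896
#>       a[3] 0.4812 0.1326 0.2209787    0.7305
#>       a[4] 0.2714 0.1175 0.0702190    0.4930

assess(fit)
#> Model assessment (mixture model)
#>   DIC  = 14393.051  (pD = 142.96, Dev_bar = 14250.091, Dev_hat = 14107.131)
#>   LPML = -7781.608
```

The posterior guessing rate (15.4%) recovers the simulated contamination
(15.2% of cells); the per-cell posterior guessing probabilities in
`fit$eta_prob` correlate 0.994 with the true indicators. Refitting
without the mixture shows the fit loss from ignoring rapid guessing —
DIC rises from 14393 to 17241 and LPML drops from −7782 to −8763, so
both criteria select the mixture model (smaller DIC, larger LPML are
better). `summary(fit)` rows are EAP (posterior mean), posterior SD and
the 95% highest-posterior-density interval per parameter; person scores
are in `fit$person_eap`.

Real datasets enter the same way: `read_response_data("Y.csv", "T.csv")`
validates and bundles the two matrices, and `write_speedmix(fit, dir)`
exports chains, posterior summaries, the assessment report and a run
log.

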