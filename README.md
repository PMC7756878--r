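# spipm

Spatially explicit integrated population models (IPMs) for assessing the
source–sink status of breeding habitats.

## The problem

Classifying a habitat as a **source** (per-capita contribution to the
population C > 1) or a **sink** (C < 1) requires unbiased survival
estimates — but in any finite study area, mark–resighting data confound
mortality with permanent emigration, biasing apparent survival downward
and over-diagnosing sinks.  When dispersal distances differ between
habitats, the bias differs too, corrupting the habitat comparison
itself.

`spipm` is for population ecologists with the standard long-term data of
a territory-mapping study on a two-habitat ("Short"/"Tall" ground
vegetation) landscape: annual territory counts, breeding success,
brood sizes, and resighting histories of individually marked birds with
sighting coordinates.  It fits a Bayesian integrated model that embeds a
spatial multi-event capture–mark–resighting layer:

- latent states alive-in-Short / alive-in-Tall / dead with transition
  matrix Ω built from survival φ and habitat-switch probabilities ψ;
- a heavy-tailed yearly movement kernel (independent Student-t steps in
  x and y, df = 5, scale σ_move per age × habitat) with Bernoulli site
  fidelity P_stay for breeders;
- detection probability p and habitat-determination probability c by
  monitoring zone (core / peripheral), with p ≡ 0 outside the total
  study area — the mechanism that lets the model separate emigration
  from death;
- a two-habitat Leslie projection NB_{t+1} = A_t NB_t + Im_{t+1} with
  demographic stochasticity and Poisson-observed counts, where the
  yearly net-immigration terms Im are estimated residuals;
- binomial breeding success and shifted-Poisson brood sizes,
  B ~ Bin(R, b) and F − S ~ Pois(2fS − S), with year random effects.

The derived per-capita contribution C_h,t = b·f·φ_fl + φ_br (the column
sums of A_t) drives the source–sink classification; derived emigration
rates are Monte-Carlo kernel mass outside the study area.  A matching
non-spatial variant (`variant = "nonspatial"`) quantifies the bias that
ignoring movements would induce.  An individual-based simulator
generates all four data streams under the exact model with known truth.

## Worked example

```r
library(spipm)

set.seed(1)
land <- generate_landscape(n_core = 124, n_peripheral = 55)  # 60 km^2 plane
scn  <- sim_scenario(years = 15, n_mark_fl = 12, n_mark_br = 5)
d    <- simulate_dataset(land, scn)

fit <- fit_ipm(d, cfg = fit_config("spatial", n_chains = 2, n_adapt = 400,
                                   n_burn = 200, n_iter = 600, seed = 2))
summarize_posterior(fit, pars = "C_mean|phi_fl_mean|imrate_mean")
```

```
        parameter   mean     sd   lower  upper  rhat n_eff
1       C_mean[1]  1.123 0.1171  0.9035 1.3341 1.673  37.2
2       C_mean[2]  0.961 0.1664  0.6448 1.2729 1.000  24.6
3  imrate_mean[1] -0.303 0.1749 -0.6232 0.0734 1.225  17.1
4  imrate_mean[2] -0.234 0.1688 -0.5795 0.0694 1.001  46.6
5  phi_fl_mean[1]  0.261 0.0498  0.1712 0.3572 1.707  83.6
6  phi_fl_mean[2]  0.191 0.0911  0.0344 0.3585 1.047  11.7
```

Reading this (one desk-scale simulated dataset; the generating truth had
mean first-year survival 0.23/0.15): `C_mean` is the across-year mean
per-capita contribution per habitat — both credible intervals span 1, so
neither habitat is classified as a clear source or sink
(`classify_status()` applies the rule draw-wise).  `imrate_mean` is the
net-immigration rate (net immigrants / same-year breeders); the data
were simulated with a closed population and both intervals duly straddle
zero.  `phi_fl_mean` is emigration-corrected first-year survival, whose
intervals cover the truth.  Comparing against
`fit_ipm(..., fit_config("nonspatial", ...))` shows the non-spatial
fledgling survival sitting below the spatial one — the bias the spatial
model exists to remove.  `emigration_rates(fit)` returns the posterior
age × habitat emigration probabilities, and
`posterior_predictive_check(fit, d)` Bayesian p-values for the four data
streams.

A thin command-line front end over the same functions ships in
`inst/cli/spipm` (subcommands `simulate`, `fit`, `summarize`,
`contrast`, `emigration`).

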