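---
title: "Controlled viscoelastic encapsulation: models, parameters and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controlled viscoelastic encapsulation: models, parameters and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropletrain)
```

## The problem

Encapsulating exactly one particle (or cell) per droplet is the goal of
most droplet-microfluidic workflows, and random particle arrivals cap the
achievable fraction at the Poisson value $P(k,n) = k^n e^{-k}/n!$ — about
37% of droplets at mean occupancy $k = 1$. A dilute shear-thinning
viscoelastic suspending liquid (here the reference system is hyaluronic
acid at 0.1 wt% in PBS, dispersed into mineral oil at a T-junction)
changes the arrival statistics: hydrodynamic interactions space the
particles into a single-file train, so arrivals become near-periodic and
can be *synchronised* with droplet generation. `dropletrain` packages the
closed-form relations governing that synchronisation, the statistics used
to evaluate it, and a stochastic simulator that stands in for the
microfluidic experiment.

## Scaling laws of droplet formation

Two empirical master curves summarise droplet generation at a T-junction,
with flow rates in µL/min throughout:

* **Length.** $L/W = c_0 + c_1\, Q_d/Q_c$ with $c_0 = 1$, $c_1 = 2$ for
  both Newtonian and viscoelastic dispersed phases
  (`normalised_length()`). The droplet size depends on the flow-rate
  *ratio* only.
* **Frequency.** $f_d = A\,(Q_d Q_c)^B$ with $A = 1.64$ Hz (µL/min)$^{-2B}$
  and $B = 2/3$ (`droplet_frequency()`). The frequency depends on the
  *product* only, hence is symmetric in the two flow rates.

The capillary number $\mathrm{Ca} = \mu_c U_c/\gamma$, with
$U_c = Q_c/(WH)$, locates the breakup regime (`capillary_number()`; the
mean velocity is attached as an attribute). Unit conversions to SI happen
inside the function; everything user-facing stays in µL/min and
micrometres. One bookkeeping note: with $\mu_c = 29$ mPa s,
$\gamma = 3.35$ mN/m and a $100 \times 100$ µm channel, $Q_c$ from 1 to
10 µL/min gives Ca from 0.0144 to 0.144, slightly above the nominal
0.01–0.1 window often quoted for this regime; the package computes the
definition exactly and leaves the rounding to the reader.

### Fitting the laws

`fit_length_law()` is ordinary least squares of $L/W$ on the ratio in
*linear* space: droplet lengths are measured by imaging, for which
additive, roughly homoscedastic noise is the natural model.
`fit_frequency_law()` works in *log* space, where the power law is linear
($\log f_d = \log A + B \log Q_d Q_c$) and multiplicative lognormal noise
becomes homoscedastic — matching the log–log collapse on which such data
are plotted. `A` is reported with a delta-method standard error
$\mathrm{se}(A) = A\,\mathrm{se}(\log A)$. The exponent can be held fixed
(`fixed_B = 2/3`, the convention under which the default prefactor was
obtained) or fitted jointly. No weighting is applied in either fit.
Degenerate designs — fewer than two distinct ratios, or products when $B$
is free — raise errors rather than returning `NaN` parameters, and
non-positive flow rates or frequencies are rejected on input.

## Occupancy statistics

`build_histogram()` tabulates per-droplet counts into relative frequencies
over the full support $0..n_{\max}$. Empty droplets are deliberately part
of the denominator: the Poisson baseline is a probability distribution
over *all* occupancies, so the observed frequencies must be normalised the
same way, and $k$ is estimated as the sample mean (the maximum-likelihood
rate for a Poisson model). `compare_to_poisson()` evaluates the baseline
at the histogram's own $k$ and reports the *excess at one*,
$\hat f(1) - P(k, 1)$ — positive when ordering has beaten the stochastic
limit. No goodness-of-fit test is imposed on experimental histograms; a
pooled chi-square helper (`occupancy_poisson_gof()`, tail bins merged
until expected counts reach 5, one df deducted for the estimated $k$) is
provided for validating simulations.

## Frequency matching

An ordered train of particles with diameter $d$, velocity $u$ and local
linear concentration $\phi_l = Nd/L$ passes the junction at
$f_p = u\phi_l/d$ (`particle_frequency()`). Matching $f_d = f_p$ and
solving for the oil flow rate gives

$$Q_{oil} = \frac{1}{Q_{HA}} \left( \frac{u\,\phi_l}{A\,d} \right)^{1/B},$$

implemented in `matched_oil_flow()` with the mixed units of the fitted
law: flow rates in µL/min, $d$ in metres, $u$ in m/s. The identity
$f_d(Q_{HA}, Q_{oil}) = f_p$ is exact by construction and is enforced in
the test suite to $10^{-9}$ relative error over 1000 random parameter
draws. `design_table()` tabulates the solution over a grid of $Q_{HA}$ and
flags (never clips) rows whose $Q_{oil}$ falls outside the 1–10 µL/min
window in which the frequency law was calibrated — outside it the law is
an extrapolation.

Two modelling choices here were genuinely open. First, the particle
velocity $u$ is a user input: it is best measured, and when it is not
available `plug_flow_velocity()` offers $u = \beta Q_d/(WH)$ with
$\beta = 1$ by default — an *approximation*, since particles riding the
channel centreline move faster than the cross-section mean; $\beta$ is
exposed rather than hidden inside the solver. Second, $\phi_l$ fluctuates
in real trains; the solver takes it as a point value (use the mean of
window counts via `local_concentration()`), because no distributional
information about $\phi_l$ survives into the design equation.

## The train simulator

`generate_arrivals()` draws a renewal process: independent inter-arrival
gaps from a Gamma distribution with mean $1/f_p$ and coefficient of
variation `gap_cv` (shape $1/\mathrm{cv}^2$, scale $\mathrm{cv}^2 f_p^{-1}$).
The Gamma family was chosen because a single parameter sweeps continuously
between the two physical regimes — `gap_cv = 0` degenerates to perfectly
periodic spacing (an ideal train) and `gap_cv = 1` is exactly exponential
(a Poisson process, i.e. no ordering) — while staying positive and
closed under the moments we need. Each arrival independently carries two
particles with probability `aggregate_fraction`, an idealisation of
doublets that survive the aggregate-breaking elements upstream (deposited
at a single instant; default 0.1, consistent with >90% singlets after
breakup). All randomness flows from one explicit integer seed per call,
and the caller's RNG stream is restored afterwards.

`encapsulate()` forms droplets at a strictly constant frequency — the
experimental observation this emulates — as half-open periodic intervals
$[\,\texttt{phase} + (i-1)/f_d,\ \texttt{phase} + i/f_d)$; an arrival
exactly on a boundary (possible only in the degenerate `gap_cv = 0` case)
goes to the later droplet. Arrivals before the first boundary or after the
last complete droplet are discarded, so particle conservation inside the
covered span is exact integer equality (and is tested as such). The phase
is drawn uniformly unless pinned.

Expected behaviours, all under test: mean occupancy converges to
$f_p(1 + \texttt{aggregate\_fraction})/f_d$; at `gap_cv = 1` the counts
are Poisson (chi-square checked at $k \in \{0.5, 1, 2\}$); at
`gap_cv = 0` with $f_p = f_d$ every droplet holds exactly one particle;
and the single-encapsulation fraction at matched frequency decreases
monotonically in `gap_cv` — the mechanism by which ordering beats the 37%
ceiling.

```{r monotone}
sapply(c(0, 0.25, 0.5, 1), function(cv) {
  s <- generate_arrivals(50, cv, duration = 100, aggregate_fraction = 0,
                         seed = 7)
  mean(encapsulate(s, 50, phase = "random", seed = 8)$counts == 1)
})
```

`synth_frequency_dataset()` and `synth_length_dataset()` complete the
synthetic-data surface: law values on a flow-rate grid perturbed by
multiplicative lognormal (frequency) or additive Gaussian (length) noise,
zero noise reproducing the law to machine precision. Noisy lengths may dip
below the intercept, as real measurements do; the fitters accept that.

### What the simulator does and does not emulate

It reproduces the *statistics* that matter for occupancy: arrival
regularity on a continuum from ordered to random, a constant droplet
clock, residual doublets, and measurement noise around the two master
curves. It contains no hydrodynamics — no viscoelastic migration or
ordering dynamics, no inter-particle forces, no feedback of droplet
pinch-off on particle capture, no satellite droplets. `gap_cv` is
phenomenological: no published spacing distribution exists for the
reference system, so it cannot be calibrated to reproduce the
experimentally observed ≃40%/≃50% efficiencies quantitatively, and
passing tests demonstrate internal consistency of the statistical model,
not agreement with any particular device. Likewise the rheological
metadata ($\lambda$, the viscosity curve) are inputs, not predictions.

## Default parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| $W, H$ | 100, 100 | µm | reference channel cross-section |
| $\mu_c$ | 0.029 | Pa s | mineral-oil viscosity |
| $\gamma$ | 3.35e-3 | N/m | HA/PBS–oil interfacial tension |
| $\lambda$ | 7.27e-3 | s | dispersed-phase relaxation time (metadata) |
| $d$ | 20e-6 | m | particle diameter |
| $u$ | 0.01 | m/s | typical centreline velocity at a few µL/min |
| $\phi_l$ | 0.1 | — | one particle per 10 diameters, a workable train |
| $A, B$ | 1.64, 2/3 | Hz (µL/min)$^{-2B}$, — | fitted frequency law |
| intercept, slope | 1, 2 | — | length master curve |
| `gap_cv` | 0.25 | — | ordered train with realistic $\phi_l$ fluctuation |
| `aggregate_fraction` | 0.1 | — | residual doublets after breakup elements |

With these defaults $f_p = 50$ Hz, inside the droplet-frequency range the
power law covers. The bundled YAML config
(`system.file("extdata", "default_config.yaml", package = "dropletrain")`)
carries the same values and drives all CLI subcommands; flags override
file keys, and every run logs its resolved parameters and seed to stderr
so outputs are regenerable.

## Numerical choices and problem sizes

The Poisson pmf is evaluated in log space (`stats::dpois`), stable to
large $n$. Fits go through `stats::lm`; standard errors are the usual OLS
covariance. Simulated validation sizes were chosen so that sampling error
is an order of magnitude below the effects being checked while keeping the
whole suite in seconds: 50,000 droplet periods for the Poisson-equivalence
check (binomial standard error ≈ 0.2 points on a 37% fraction), 20,000
for chi-square goodness of fit and the ordering sweep, 100 and 60
observations for the frequency- and length-law recoveries (matching the
scale of a real flow-rate campaign), and 1000 random draws for the
matching-identity property.

## Known limitations

* The scaling laws are empirical for one device family and fluid pair;
  nothing constrains them outside the calibrated flow-rate window (the
  design table only flags this).
* No criterion predicts *whether* a train forms — channel length and
  elasticity requirements for ordering are out of scope; the simulator
  assumes the train's statistics as given.
* Doublets are idealised as two particles at one instant; triplets and
  higher aggregates are not modelled.
* Co-encapsulation of two particle species and sub-/super-Poisson
  mechanism inference are out of scope.
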