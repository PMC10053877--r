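# dropletrain

Design and analysis tools for controlled single-particle encapsulation in
T-junction droplet microfluidics.

When a suspension is dispersed into droplets, particles arrive at the
junction at random, so the fraction of droplets containing exactly one
particle is capped by Poisson statistics,

    P(k, n) = k^n e^(-k) / n!,

at most P(1, 1) = e^(-1) ≈ 37% at mean occupancy k = 1. Suspending the
particles in a weakly viscoelastic, shear-thinning liquid (e.g. dilute
hyaluronic acid in PBS) makes them self-organise into an equally spaced
single-file *train*, so they arrive at a near-constant frequency

    f_p = u φ_l / d,

where `u` is the particle velocity, `d` the particle diameter and
φ_l = N d / L the local linear concentration. Droplets, meanwhile, are
generated at a strictly constant frequency that follows the power law

    f_d = A (Q_d Q_c)^B        (flow rates in µL/min; A = 1.64, B = 2/3),

while the droplet length follows the linear master curve
L/W = 1 + 2 Q_d/Q_c. Setting f_d = f_p and solving for the continuous-phase
(oil) flow rate gives the frequency-matching design equation

    Q_oil = (1 / Q_HA) · (u φ_l / (A d))^(1/B),

the operating condition under which one droplet collects one particle and
the Poisson ceiling can be beaten. `dropletrain` implements:

* the three closed-form scaling relations (normalised length, generation
  frequency, capillary number) and least-squares estimation of their
  parameters from observation tables (`fit_length_law()`,
  `fit_frequency_law()`);
* the Poisson occupancy baseline and comparison of observed
  particles-per-droplet histograms against it (`poisson_pmf()`,
  `build_histogram()`, `compare_to_poisson()`);
* the frequency-matching solver and design tables (`matched_oil_flow()`,
  `design_table()`);
* a renewal-process Monte Carlo simulator of particle trains — gamma
  inter-arrival gaps interpolating from a perfect train (`gap_cv = 0`) to
  fully stochastic arrivals (`gap_cv = 1`), with a residual doublet
  fraction — and their encapsulation into periodically formed droplets
  (`generate_arrivals()`, `encapsulate()`), plus noisy synthetic
  scaling-law datasets (`synth_*_dataset()`);
* a YAML-configured command line (`run_cli()`; wrapper script in
  `inst/cli/dropletrain`) covering `simulate`, `fit-frequency`,
  `fit-length`, `design` and `poisson-compare`.

## Worked example

Twenty-micron particles moving at 1 cm/s with local concentration
φ_l = 0.1 arrive at f_p = u φ_l / d = 50 Hz. The design table solves the
matching equation over a grid of dispersed-phase flow rates:

```r
library(dropletrain)
tr <- train_spec(particle_spec(d = 20e-6, u = 0.01), phi_l = 0.1)
design_table(c(2, 4, 8, 10, 13), tr)
#>   Q_HA_uL_min Q_oil_uL_min matched_frequency_Hz in_explored_range
#> 1           2     84.17037                   50             FALSE
#> 2           4     42.08519                   50             FALSE
#> 3           8     21.04259                   50             FALSE
#> 4          10     16.83407                   50             FALSE
#> 5          13     12.94929                   50             FALSE
```

Every row satisfies f_d(Q_HA, Q_oil) = 50 Hz exactly; `Q_HA · Q_oil` is
constant because the frequency law depends only on the product. Here no
solution lands inside the 1–10 µL/min window where the law was calibrated
(`in_explored_range`), signalling that this train is too fast for the
calibrated device — lower φ_l or u, or accept the extrapolation.

Simulating a moderately ordered train (gap_cv = 0.25, 10% doublets) at the
matched frequency and comparing to the Poisson baseline:

```r
s  <- generate_arrivals(f_p = 50, gap_cv = 0.25, duration = 200,
                        aggregate_fraction = 0.1, seed = 42)
dc <- encapsulate(s, f_d = 50, phase = "random", seed = 43)
compare_to_poisson(build_histogram(dc))
#> Occupancy histogram: 9999 droplets, mean occupancy k = 1.105
#>      0      1      2      3      4
#> 0.1004 0.7168 0.1621 0.0192 0.0015
#> Poisson baseline at k = 1.105; excess at n = 1: +0.3508
```

72% of droplets hold exactly one particle — 35 points above the Poisson
value at the same mean occupancy. Rerunning with `gap_cv = 1` (no
ordering) drives the excess to zero: ordering, not concentration, is what
beats the limit.

The same pipeline runs from a shell:

```sh
Rscript inst/cli/dropletrain simulate --config inst/extdata/default_config.yaml \
    --seed 42 --out-dir out/
Rscript inst/cli/dropletrain design --Q-HA 4,8 --out-dir out/
```

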