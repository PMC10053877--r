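Package: dropletrain
Title: Droplet-Formation Scaling Laws, Poisson Occupancy Statistics and
    Particle-Train Encapsulation Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for designing and analysing controlled single-particle
    encapsulation in T-junction droplet microfluidics. Implements the
    linear master curve for normalised droplet length, the power law for
    droplet-generation frequency with least-squares parameter estimation,
    capillary-number bookkeeping, the Poisson occupancy baseline for
    particles-per-droplet histograms, and the frequency-matching design
    equation that selects the continuous-phase flow rate synchronising
    droplet formation with the arrival of an ordered particle train. A
    renewal-process Monte Carlo simulator generates particle-arrival
    series spanning perfectly ordered trains to fully stochastic
    suspensions, encapsulates them into periodically formed droplets, and
    produces noisy synthetic scaling-law datasets for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
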