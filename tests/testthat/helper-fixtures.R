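# shared fixtures: the hyaluronic-acid/mineral-oil system defaults and a
# flow-rate grid spanning the explored 1-10 uL/min window

default_geom <- function() geometry(100, 100)
default_fluids <- function() fluid_properties(mu_c = 0.029, gamma = 3.35e-3,
                                              lambda = 7.27e-3)
default_train <- function(gap_cv = 0.25, aggregate_fraction = 0.1) {
  train_spec(particle_spec(d = 20e-6, u = 0.01), phi_l = 0.1,
             gap_cv = gap_cv, aggregate_fraction = aggregate_fraction)
}

# n pairs drawn (with a fixed seed) from the explored flow-rate window
grid_pairs <- function(n, seed, qmin = 1, qmax = 10) {
  pts <- dropletrain:::.with_seed(seed, list(
    Q_d = runif(n, qmin, qmax), Q_c = runif(n, qmin, qmax)))
  flow_pair(pts$Q_d, pts$Q_c)
}

# pairs whose ratio Q_d/Q_c spans [0.1, 10] on a log scale at fixed Q_c
ratio_pairs <- function(n, Q_c = 10) {
  ratio <- exp(seq(log(0.1), log(10), length.out = n))
  flow_pair(ratio * Q_c, Q_c)
}

# single-encapsulation fraction of a simulated train at matched frequency
single_fraction <- function(gap_cv, n_droplets = 20000, f = 50, seed = 101) {
  s <- generate_arrivals(f_p = f, gap_cv = gap_cv, duration = n_droplets / f,
                         aggregate_fraction = 0, seed = seed)
  dc <- encapsulate(s, f_d = f, phase = "random", seed = seed + 1L)
  mean(dc$counts == 1L)
}
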