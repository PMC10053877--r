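#' Simulate a particle-train arrival series
#'
#' Draws a renewal process of particle arrivals at the encapsulation area.
#' Inter-arrival gaps follow a Gamma distribution with mean `1/f_p` and
#' coefficient of variation `gap_cv` (shape `1/gap_cv^2`, scale
#' `gap_cv^2/f_p`), which interpolates continuously between the two regimes
#' of interest with a single parameter:
#'
#' * `gap_cv = 0` — degenerate gaps of exactly `1/f_p`: a perfect
#'   viscoelastically ordered train;
#' * `gap_cv = 1` — exponential gaps: a Poisson process, i.e. fully
#'   stochastic arrivals with no ordering at all.
#'
#' Each arrival independently carries two particles with probability
#' `aggregate_fraction`, modelling residual doublets that survive the
#' aggregate-breaking elements upstream of the junction.
#'
#' @param f_p Mean arrival frequency, Hz.
#' @param gap_cv Coefficient of variation of the gaps; `>= 0`.
#' @param duration Simulated time span, seconds; arrivals fill `[0, duration)`.
#' @param aggregate_fraction Doublet probability per arrival, in `[0, 1]`.
#' @param seed Integer seed; all randomness in the call flows from it and
#'   the caller's RNG state is left untouched.
#' @return An object of class `"arrival_series"`: list with `times`
#'   (strictly increasing, seconds), `particles_per_arrival` (1 or 2),
#'   `duration`, `seed` and the generating parameters.
#' @examples
#' s <- generate_arrivals(f_p = 50, gap_cv = 0, duration = 1, seed = 1)
#' diff(s$times)[1:3]   # all exactly 0.02 s
#' @export
generate_arrivals <- function(f_p, gap_cv, duration,
                              aggregate_fraction = 0.1, seed) {
  .assert_scalar(f_p, "f_p"); .assert_positive(f_p, "f_p")
  .assert_scalar(gap_cv, "gap_cv"); .assert_nonneg(gap_cv, "gap_cv")
  .assert_scalar(duration, "duration"); .assert_positive(duration, "duration")
  .assert_scalar(aggregate_fraction, "aggregate_fraction")
  if (aggregate_fraction < 0 || aggregate_fraction > 1) {
    stop("`aggregate_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (missing(seed)) stop("a `seed` must be supplied", call. = FALSE)

  .with_seed(seed, {
    if (gap_cv == 0) {
      # degenerate gaps: the perfect train
      n <- floor(duration * f_p)
      times <- (seq_len(n)) / f_p
      times <- times[times < duration]
    } else {
      shape <- 1 / gap_cv^2
      scale <- gap_cv^2 / f_p
      expected <- duration * f_p
      chunk <- ceiling(expected + 10 * sqrt(expected + 1) + 10)
      gaps <- stats::rgamma(chunk, shape = shape, scale = scale)
      while (sum(gaps) < duration) {
        gaps <- c(gaps, stats::rgamma(chunk, shape = shape, scale = scale))
      }
      times <- cumsum(gaps)
      times <- times[times < duration]
    }
    particles <- 1L + stats::rbinom(length(times), 1L, aggregate_fraction)
    structure(
      list(times = times, particles_per_arrival = particles,
           duration = duration, seed = as.integer(seed), f_p = f_p,
           gap_cv = gap_cv, aggregate_fraction = aggregate_fraction),
      class = "arrival_series"
    )
  })
}

#' Encapsulate an arrival series into periodically formed droplets
#'
#' Droplets are generated at the strictly constant frequency `f_d`; droplet
#' `i` (1-based) collects every arrival whose time falls in the half-open
#' interval `[phase + (i-1)/f_d, phase + i/f_d)`. Arrivals before the first
#' boundary (`t < phase`) are discarded, as are arrivals after the last
#' complete droplet; an arrival exactly on a boundary belongs to the later
#' droplet. The number of droplets is `floor((duration - phase) * f_d)`.
#'
#' @param series An [generate_arrivals()] result.
#' @param f_d Droplet-generation frequency, Hz.
#' @param phase First droplet boundary, seconds in `[0, 1/f_d)`, or
#'   `"random"` to draw it uniformly (requires `seed`).
#' @param seed Integer seed, used only when `phase = "random"`.
#' @return An object of class `"droplet_counts"`: list with
#'   `droplet_period`, `phase`, integer `counts` (one per droplet) and
#'   `f_d`.
#' @examples
#' s <- generate_arrivals(50, gap_cv = 0, duration = 10,
#'                        aggregate_fraction = 0, seed = 1)
#' table(encapsulate(s, f_d = 50, phase = 0.01)$counts)   # all 1
#' @export
encapsulate <- function(series, f_d, phase = "random", seed = NULL) {
  stopifnot(inherits(series, "arrival_series"))
  .assert_scalar(f_d, "f_d"); .assert_positive(f_d, "f_d")
  period <- 1 / f_d
  if (identical(phase, "random")) {
    if (is.null(seed)) stop("`seed` is required when phase = \"random\"",
                            call. = FALSE)
    phase <- .with_seed(seed, stats::runif(1, 0, period))
  } else {
    .assert_scalar(phase, "phase")
    if (!is.numeric(phase) || is.na(phase) || phase < 0 || phase >= period) {
      stop("`phase` must lie in [0, 1/f_d)", call. = FALSE)
    }
  }
  n_droplets <- floor((series$duration - phase) * f_d)
  if (n_droplets < 1L) {
    stop("duration too short for a single droplet at this f_d", call. = FALSE)
  }
  idx <- floor((series$times - phase) / period) + 1
  keep <- series$times >= phase & idx <= n_droplets
  counts <- tabulate(rep(idx[keep], times = series$particles_per_arrival[keep]),
                     nbins = n_droplets)
  structure(
    list(droplet_period = period, phase = phase,
         counts = as.integer(counts), f_d = f_d),
    class = "droplet_counts"
  )
}

#' Synthetic droplet-frequency observations
#'
#' Emulates a measured frequency dataset: evaluates the power law on a grid
#' of flow-rate pairs and perturbs it with multiplicative lognormal noise,
#' `f_obs = f_law * exp(eps)`, `eps ~ N(0, noise_sigma^2)` — the noise model
#' under which a log-space fit is homoscedastic.
#'
#' @param law A [frequency_law()].
#' @param pairs A [flow_pair()] grid.
#' @param noise_sigma Lognormal sigma; `0` reproduces the law exactly.
#' @param seed Integer seed.
#' @return Data frame with columns `Q_d`, `Q_c`, `f_d`, ready for
#'   [fit_frequency_law()].
#' @export
synth_frequency_dataset <- function(law, pairs, noise_sigma, seed) {
  stopifnot(inherits(law, "frequency_law"))
  pairs <- as_flow_pair(pairs)
  .assert_nonneg(noise_sigma, "noise_sigma")
  f <- droplet_frequency(pairs, law)
  if (noise_sigma > 0) {
    f <- f * exp(.with_seed(seed, stats::rnorm(nrow(pairs), 0, noise_sigma)))
  }
  data.frame(Q_d = pairs$Q_d, Q_c = pairs$Q_c, f_d = f)
}

#' Synthetic normalised-length observations
#'
#' Emulates a measured droplet-length dataset: evaluates the linear master
#' curve on a grid of flow-rate pairs and adds Gaussian noise,
#' `L/W_obs = law(Q_d/Q_c) + eps`, `eps ~ N(0, noise_sigma^2)`. Noise may
#' push individual observations below the intercept, as in real data.
#'
#' @param law A [length_law()].
#' @param pairs A [flow_pair()] grid.
#' @param noise_sigma Additive sigma; `0` reproduces the curve exactly.
#' @param seed Integer seed.
#' @return Data frame with columns `Q_d`, `Q_c`, `L_over_W`, ready for
#'   [fit_length_law()].
#' @export
synth_length_dataset <- function(law, pairs, noise_sigma, seed) {
  stopifnot(inherits(law, "length_law"))
  pairs <- as_flow_pair(pairs)
  .assert_nonneg(noise_sigma, "noise_sigma")
  l <- normalised_length(pairs, law)
  if (noise_sigma > 0) {
    l <- l + .with_seed(seed, stats::rnorm(nrow(pairs), 0, noise_sigma))
  }
  data.frame(Q_d = pairs$Q_d, Q_c = pairs$Q_c, L_over_W = l)
}

#' Write an arrival series as CSV
#'
#' Columns `t_s` (arrival instant, seconds) and `n_particles` (particles
#' deposited at that instant).
#'
#' @param series An [generate_arrivals()] result.
#' @param path File path.
#' @export
write_arrivals <- function(series, path) {
  stopifnot(inherits(series, "arrival_series"))
  utils::write.csv(
    data.frame(t_s = series$times, n_particles = series$particles_per_arrival),
    path, row.names = FALSE)
  invisible(path)
}

#' @export
print.arrival_series <- function(x, ...) {
  cat(sprintf(
    "Arrival series: %d arrivals (%d particles) over %.4g s (f_p = %.4g Hz, gap_cv = %.3g, doublet fraction %.3g, seed %d)\n",
    length(x$times), sum(x$particles_per_arrival), x$duration, x$f_p,
    x$gap_cv, x$aggregate_fraction, x$seed))
  invisible(x)
}

#' @export
print.droplet_counts <- function(x, ...) {
  cat(sprintf(
    "Droplet counts: %d droplets at f_d = %.4g Hz (phase %.4g s); mean occupancy %.4g\n",
    length(x$counts), x$f_d, x$phase, mean(x$counts)))
  invisible(x)
}
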