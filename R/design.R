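#' Local linear particle concentration
#'
#' phi_l = N d / L: the fraction of a channel observation window of length
#' `L_window` occupied by `N` particles of diameter `d`. The local
#' concentration, not the bulk volume fraction, sets the characteristic
#' frequency of an ordered train.
#'
#' @param N Number of particles counted in the window; non-negative integer.
#' @param d Particle diameter, metres.
#' @param L_window Window length, metres.
#' @return Dimensionless linear fraction in `[0, 1]`.
#' @examples
#' local_concentration(5, 20e-6, 1000e-6)   # 0.1
#' @export
local_concentration <- function(N, d, L_window) {
  .assert_scalar(N, "N"); .assert_nonneg(N, "N")
  if (N != floor(N)) stop("`N` must be an integer count", call. = FALSE)
  .assert_scalar(d, "d"); .assert_positive(d, "d")
  .assert_scalar(L_window, "L_window"); .assert_positive(L_window, "L_window")
  if (N * d > L_window) {
    stop("N * d exceeds the window length: particles cannot overlap",
         call. = FALSE)
  }
  N * d / L_window
}

#' Characteristic frequency of a particle train
#'
#' f_p = u phi_l / d: the rate at which equally spaced particles moving at
#' velocity `u` with linear concentration `phi_l` pass the encapsulation
#' area. Linear in `u` and `phi_l`, inverse in the diameter `d`.
#'
#' @param spec A [train_spec()], or a [particle_spec()] together with
#'   `phi_l`.
#' @param phi_l Local linear concentration; only used when `spec` is a
#'   [particle_spec()].
#' @return Arrival frequency, Hz.
#' @examples
#' p <- particle_spec(d = 20e-6, u = 0.01)
#' particle_frequency(p, phi_l = 0.1)   # 50 Hz
#' @export
particle_frequency <- function(spec, phi_l = NULL) {
  if (inherits(spec, "train_spec")) {
    p <- spec$particle
    phi_l <- spec$phi_l
  } else if (inherits(spec, "particle_spec")) {
    p <- spec
    if (is.null(phi_l)) stop("`phi_l` is required with a particle_spec",
                             call. = FALSE)
  } else {
    stop("`spec` must be a train_spec or particle_spec", call. = FALSE)
  }
  p$u * phi_l / p$d
}

#' Plug-flow estimate of particle velocity
#'
#' u = beta * Q_d / (W H), the mean dispersed-phase velocity scaled by a
#' shape factor `beta`. This is an approximation: particles travelling on
#' the channel centreline move faster than the cross-section mean, so a
#' calibrated `beta > 1` may be appropriate; the default `beta = 1` is the
#' plug-flow limit. Prefer a measured velocity when one is available.
#'
#' @param Q_d Dispersed-phase flow rate, uL/min.
#' @param geom A [geometry()].
#' @param beta Dimensionless shape factor, default 1.
#' @return Velocity estimate, m/s.
#' @export
plug_flow_velocity <- function(Q_d, geom, beta = 1) {
  .assert_positive(Q_d, "Q_d"); .assert_positive(beta, "beta")
  stopifnot(inherits(geom, "geometry"))
  beta * .uL_min_to_m3_s(Q_d) / (.um_to_m(geom$W_um) * .um_to_m(geom$H_um))
}

#' Continuous-phase flow rate that synchronises droplets to the train
#'
#' Solves the frequency-matching condition f_d = f_p for the oil flow rate:
#' setting the droplet-generation law A (Q_HA Q_oil)^B equal to the train
#' frequency u phi_l / d gives
#'
#'   Q_oil = (1 / Q_HA) * (u phi_l / (A d))^(1/B).
#'
#' Units follow the fitted law exactly: flow rates in uL/min, `d` in metres,
#' `u` in m/s. The returned flow rate carries an exact round-trip guarantee:
#' `droplet_frequency(flow_pair(Q_HA, Q_oil), law)` equals
#' `particle_frequency(spec)` up to floating-point error.
#'
#' @param Q_HA Dispersed-phase flow rate(s), uL/min.
#' @param spec A [train_spec()] (its `gap_cv` and `aggregate_fraction` are
#'   irrelevant here; only `u`, `d`, `phi_l` enter).
#' @param law A [frequency_law()].
#' @return Matched continuous-phase flow rate(s) Q_oil, uL/min.
#' @examples
#' tr <- train_spec(particle_spec(d = 20e-6, u = 0.01), phi_l = 0.1)
#' matched_oil_flow(8, tr)   # ~21.0 uL/min (f_p = 50 Hz)
#' @export
matched_oil_flow <- function(Q_HA, spec, law = frequency_law()) {
  .assert_positive(Q_HA, "Q_HA")
  stopifnot(inherits(spec, "train_spec"), inherits(law, "frequency_law"))
  f_p <- particle_frequency(spec)
  if (!is.finite(f_p) || f_p <= 0) {
    stop("particle frequency must be positive for frequency matching",
         call. = FALSE)
  }
  (f_p / law$A)^(1 / law$B) / Q_HA
}

#' Frequency-matched design table over a grid of dispersed flow rates
#'
#' Tabulates the frequency-matching solution for each candidate Q_HA:
#' the synchronising Q_oil, the common matched frequency f_d = f_p, and a
#' flag marking whether the solved Q_oil falls inside the experimentally
#' explored flow-rate window (default 1-10 uL/min). Out-of-range rows are
#' flagged, never clipped: the scaling law is an extrapolation there.
#'
#' @param Q_HA_grid Non-empty vector of dispersed-phase flow rates, uL/min.
#' @param spec A [train_spec()].
#' @param law A [frequency_law()].
#' @param explored_range Length-2 numeric, the flow-rate window within which
#'   the law was calibrated.
#' @return Data frame with columns `Q_HA_uL_min`, `Q_oil_uL_min`,
#'   `matched_frequency_Hz`, `in_explored_range`.
#' @export
design_table <- function(Q_HA_grid, spec, law = frequency_law(),
                         explored_range = c(1, 10)) {
  if (length(Q_HA_grid) == 0L) stop("`Q_HA_grid` must be non-empty",
                                    call. = FALSE)
  .assert_positive(Q_HA_grid, "Q_HA_grid")
  stopifnot(length(explored_range) == 2L, explored_range[1] < explored_range[2])
  q_oil <- matched_oil_flow(Q_HA_grid, spec, law)
  data.frame(
    Q_HA_uL_min = Q_HA_grid,
    Q_oil_uL_min = q_oil,
    matched_frequency_Hz = rep(particle_frequency(spec), length(Q_HA_grid)),
    in_explored_range = q_oil >= explored_range[1] & q_oil <= explored_range[2]
  )
}
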