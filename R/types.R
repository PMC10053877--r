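#' Channel geometry
#'
#' Cross-section of the rectangular microchannel at the T-junction. The
#' channel width `W` sets the length scale used to normalise droplet
#' lengths; `W * H` is the cross-sectional area used to convert volumetric
#' flow rates into mean velocities.
#'
#' @param W_um Channel width, micrometres. Must be positive.
#' @param H_um Channel height (depth), micrometres. Must be positive.
#' @return An object of class `"geometry"`.
#' @examples
#' geometry(100, 100)
#' @export
geometry <- function(W_um, H_um) {
  .assert_scalar(W_um, "W_um"); .assert_scalar(H_um, "H_um")
  .assert_positive(W_um, "W_um"); .assert_positive(H_um, "H_um")
  structure(list(W_um = W_um, H_um = H_um), class = "geometry")
}

#' Fluid properties of the two-phase system
#'
#' Bulk properties entering the capillary number and, as metadata, the
#' description of the dispersed viscoelastic phase. All fields are SI.
#'
#' @param mu_c Continuous-phase (oil) dynamic viscosity, Pa s.
#' @param gamma Interfacial tension between the phases, N/m.
#' @param lambda Longest relaxation time of the dispersed phase, seconds.
#'   Optional metadata; `NULL` when unknown.
#' @param dispersed_label Free-text description of the dispersed phase.
#' @return An object of class `"fluid_properties"`.
#' @examples
#' fluid_properties(mu_c = 0.029, gamma = 3.35e-3, lambda = 7.27e-3)
#' @export
fluid_properties <- function(mu_c, gamma, lambda = NULL,
                             dispersed_label = "dispersed phase") {
  .assert_scalar(mu_c, "mu_c"); .assert_positive(mu_c, "mu_c")
  .assert_scalar(gamma, "gamma"); .assert_positive(gamma, "gamma")
  if (!is.null(lambda)) {
    .assert_scalar(lambda, "lambda"); .assert_nonneg(lambda, "lambda")
  }
  structure(
    list(mu_c = mu_c, gamma = gamma, lambda = lambda,
         dispersed_label = as.character(dispersed_label)),
    class = "fluid_properties"
  )
}

#' Dispersed/continuous flow-rate pairs
#'
#' The pair (Q_d, Q_c) of volumetric flow rates is the independent variable
#' of every droplet-formation scaling law. Vectorised: `Q_d` and `Q_c` are
#' recycled to a common length.
#'
#' @param Q_d Dispersed-phase flow rate(s), microlitres per minute.
#' @param Q_c Continuous-phase (oil) flow rate(s), microlitres per minute.
#' @return A data frame of class `"flow_pair"` with columns `Q_d`, `Q_c`.
#' @examples
#' flow_pair(8, 8)
#' flow_pair(Q_d = c(1, 2, 4), Q_c = 10)
#' @export
flow_pair <- function(Q_d, Q_c) {
  .assert_positive(Q_d, "Q_d"); .assert_positive(Q_c, "Q_c")
  out <- data.frame(Q_d = Q_d, Q_c = Q_c)
  class(out) <- c("flow_pair", "data.frame")
  out
}

#' Linear master curve for normalised droplet length
#'
#' Parameters of the law L/W = intercept + slope * (Q_d / Q_c). The default
#' values (1, 2) are the Newtonian master curve on which the viscoelastic
#' droplet data collapse as well.
#'
#' @param intercept Dimensionless intercept (L/W at vanishing flow ratio).
#' @param slope Dimensionless slope in the flow-rate ratio; must be >= 0.
#' @param intercept_se,slope_se Optional standard errors (filled by
#'   [fit_length_law()]).
#' @return An object of class `"length_law"`.
#' @seealso [normalised_length()], [fit_length_law()]
#' @export
length_law <- function(intercept = 1, slope = 2,
                       intercept_se = NA_real_, slope_se = NA_real_) {
  .assert_scalar(intercept, "intercept"); .assert_scalar(slope, "slope")
  if (!is.numeric(slope) || is.na(slope) || slope < 0) {
    stop("`slope` must be non-negative", call. = FALSE)
  }
  structure(
    list(intercept = intercept, slope = slope,
         intercept_se = intercept_se, slope_se = slope_se),
    class = "length_law"
  )
}

#' Power law for droplet-generation frequency
#'
#' Parameters of the law f_d = A * (Q_d * Q_c)^B with flow rates in
#' microlitres per minute (the unit convention under which `A` carries its
#' value). Defaults are the fitted values for the hyaluronic-acid/mineral-oil
#' system: A = 1.64, B = 2/3.
#'
#' @param A Prefactor, Hz (uL/min)^(-2B); must be positive.
#' @param B Exponent, dimensionless; must lie in (0, 2).
#' @param A_se,B_se Optional standard errors (filled by
#'   [fit_frequency_law()]; `B_se` is `NA` when B was held fixed).
#' @return An object of class `"frequency_law"`.
#' @seealso [droplet_frequency()], [fit_frequency_law()], [matched_oil_flow()]
#' @export
frequency_law <- function(A = 1.64, B = 2 / 3,
                          A_se = NA_real_, B_se = NA_real_) {
  .assert_scalar(A, "A"); .assert_positive(A, "A")
  .assert_scalar(B, "B")
  if (!is.numeric(B) || is.na(B) || B <= 0 || B >= 2) {
    stop("exponent `B` must lie in (0, 2)", call. = FALSE)
  }
  structure(
    list(A = A, B = B, A_se = A_se, B_se = B_se),
    class = "frequency_law"
  )
}

#' Suspended-particle properties
#'
#' @param d Particle diameter, metres.
#' @param u Particle velocity along the channel, m/s.
#' @param phi Bulk particle concentration, volume fraction in `[0, 1)`.
#'   Metadata only; the train frequency depends on the *local* linear
#'   concentration, not on `phi`.
#' @return An object of class `"particle_spec"`.
#' @export
particle_spec <- function(d, u, phi = NA_real_) {
  .assert_scalar(d, "d"); .assert_positive(d, "d")
  .assert_scalar(u, "u"); .assert_positive(u, "u")
  if (!is.na(phi) && (phi < 0 || phi >= 1)) {
    stop("`phi` must be a volume fraction in [0, 1)", call. = FALSE)
  }
  structure(list(d = d, u = u, phi = phi), class = "particle_spec")
}

#' Particle-train specification
#'
#' Bundles the particle properties with the local linear concentration and
#' the two phenomenological parameters of the arrival process: the
#' coefficient of variation of inter-particle gaps (`gap_cv = 0` is a
#' perfectly ordered train, `gap_cv = 1` a fully stochastic Poisson stream)
#' and the probability that an arrival is an unbroken doublet.
#'
#' @param particle A [particle_spec()].
#' @param phi_l Local linear concentration, the occupied fraction N d / L of
#'   a channel window; must lie in (0, 1].
#' @param gap_cv Coefficient of variation of inter-particle gaps; >= 0.
#' @param aggregate_fraction Probability an arrival carries two particles.
#' @return An object of class `"train_spec"`.
#' @seealso [particle_frequency()], [generate_arrivals()]
#' @export
train_spec <- function(particle, phi_l, gap_cv = 0.25,
                       aggregate_fraction = 0.1) {
  stopifnot(inherits(particle, "particle_spec"))
  .assert_scalar(phi_l, "phi_l")
  if (!is.numeric(phi_l) || is.na(phi_l) || phi_l <= 0 || phi_l > 1) {
    stop("`phi_l` must lie in (0, 1]", call. = FALSE)
  }
  .assert_scalar(gap_cv, "gap_cv"); .assert_nonneg(gap_cv, "gap_cv")
  .assert_scalar(aggregate_fraction, "aggregate_fraction")
  if (aggregate_fraction < 0 || aggregate_fraction > 1) {
    stop("`aggregate_fraction` must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(particle = particle, phi_l = phi_l, gap_cv = gap_cv,
         aggregate_fraction = aggregate_fraction),
    class = "train_spec"
  )
}

#' @export
print.length_law <- function(x, ...) {
  cat(sprintf("Length master curve: L/W = %.4g + %.4g * (Q_d/Q_c)\n",
              x$intercept, x$slope))
  if (!is.na(x$slope_se)) {
    cat(sprintf("  standard errors: intercept %.3g, slope %.3g\n",
                x$intercept_se, x$slope_se))
  }
  invisible(x)
}

#' @export
print.frequency_law <- function(x, ...) {
  cat(sprintf("Frequency power law: f_d = %.4g * (Q_d*Q_c)^%.4g  [Hz; Q in uL/min]\n",
              x$A, x$B))
  if (!is.na(x$A_se)) {
    cat(sprintf("  standard errors: A %.3g%s\n", x$A_se,
                if (is.na(x$B_se)) " (B fixed)" else sprintf(", B %.3g", x$B_se)))
  }
  invisible(x)
}

#' @export
print.train_spec <- function(x, ...) {
  cat(sprintf(
    "Particle train: d = %.3g m, u = %.3g m/s, phi_l = %.3g (f_p = %.4g Hz)\n",
    x$particle$d, x$particle$u, x$phi_l, particle_frequency(x)))
  cat(sprintf("  gap_cv = %.3g, aggregate_fraction = %.3g\n",
              x$gap_cv, x$aggregate_fraction))
  invisible(x)
}
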