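#' Normalised droplet length from the linear master curve
#'
#' Evaluates L/W = intercept + slope * (Q_d / Q_c). On the default law the
#' droplet length grows linearly with the dispersed-to-continuous flow-rate
#' ratio, independent of the absolute flow rates: at equal flow rates the
#' droplet is three channel widths long.
#'
#' @param pair A [flow_pair()] (possibly many rows).
#' @param law A [length_law()]; defaults to the (1, 2) master curve.
#' @return Numeric vector of dimensionless droplet lengths L/W.
#' @examples
#' normalised_length(flow_pair(8, 8))          # 3
#' normalised_length(flow_pair(c(1, 5), 10))   # 1.2, 2
#' @export
normalised_length <- function(pair, law = length_law()) {
  pair <- as_flow_pair(pair)
  stopifnot(inherits(law, "length_law"))
  law$intercept + law$slope * pair$Q_d / pair$Q_c
}

#' Droplet-generation frequency from the power law
#'
#' Evaluates f_d = A * (Q_d * Q_c)^B with flow rates in microlitres per
#' minute. The law depends on the flow rates only through their product, so
#' it is symmetric under exchanging the two phases' flow rates.
#'
#' @param pair A [flow_pair()] with flow rates in uL/min.
#' @param law A [frequency_law()]; defaults to A = 1.64, B = 2/3.
#' @return Numeric vector of droplet frequencies, Hz.
#' @examples
#' droplet_frequency(flow_pair(8, 8))   # 1.64 * 64^(2/3) = 26.24 Hz
#' @export
droplet_frequency <- function(pair, law = frequency_law()) {
  pair <- as_flow_pair(pair)
  stopifnot(inherits(law, "frequency_law"))
  law$A * (pair$Q_d * pair$Q_c)^law$B
}

#' Mean continuous-phase velocity in the channel
#'
#' U_c = Q_c / (W H), with the flow rate converted from uL/min and the
#' cross-section from micrometres to SI before the ratio.
#'
#' @param Q_c Continuous-phase flow rate(s), uL/min.
#' @param geom A [geometry()].
#' @return Mean velocity, m/s.
#' @export
continuous_velocity <- function(Q_c, geom) {
  .assert_positive(Q_c, "Q_c")
  stopifnot(inherits(geom, "geometry"))
  .uL_min_to_m3_s(Q_c) / (.um_to_m(geom$W_um) * .um_to_m(geom$H_um))
}

#' Capillary number of the continuous phase
#'
#' Ca = mu_c U_c / gamma with U_c = Q_c / (W H): the ratio of viscous to
#' interfacial stresses that governs the droplet breakup regime. All unit
#' conversions to SI happen internally; `Q_c` stays in the uL/min convention
#' used for the flow-rate pairs.
#'
#' @inheritParams continuous_velocity
#' @param fluids A [fluid_properties()].
#' @return Dimensionless capillary number(s), with the mean velocity U_c
#'   (m/s) attached as attribute `"U_c"`.
#' @examples
#' g <- geometry(100, 100)
#' fl <- fluid_properties(mu_c = 0.029, gamma = 3.35e-3)
#' capillary_number(1, g, fl)    # ~0.0144
#' @export
capillary_number <- function(Q_c, geom, fluids) {
  stopifnot(inherits(fluids, "fluid_properties"))
  u_c <- continuous_velocity(Q_c, geom)
  ca <- fluids$mu_c * u_c / fluids$gamma
  attr(ca, "U_c") <- u_c
  ca
}

#' Fit the linear length master curve by ordinary least squares
#'
#' Regresses the observed normalised lengths L/W on the flow-rate ratio
#' Q_d/Q_c in linear space (additive measurement noise on the length is the
#' natural model for image-based droplet sizing).
#'
#' @param observations Data frame with columns `Q_d`, `Q_c`, `L_over_W`
#'   (e.g. from [read_length_observations()] or [synth_length_dataset()]).
#' @return A [length_law()] carrying the estimated intercept and slope,
#'   their standard errors, and attributes `"residuals"` (response scale)
#'   and `"n"`.
#' @examples
#' obs <- data.frame(Q_d = c(1, 2), Q_c = 4, L_over_W = c(1.5, 2))
#' fit_length_law(obs)   # recovers intercept 1, slope 2
#' @export
fit_length_law <- function(observations) {
  obs <- .check_length_obs(observations)
  ratio <- obs$Q_d / obs$Q_c
  if (length(unique(ratio)) < 2L) {
    stop("degenerate design: need at least 2 distinct flow-rate ratios",
         call. = FALSE)
  }
  fit <- stats::lm(L_over_W ~ ratio, data = data.frame(ratio = ratio,
                                                       L_over_W = obs$L_over_W))
  cf <- .lm_coefs(fit)
  law <- length_law(
    intercept = unname(cf["(Intercept)", "Estimate"]),
    slope = unname(cf["ratio", "Estimate"]),
    intercept_se = unname(cf["(Intercept)", "Std. Error"]),
    slope_se = unname(cf["ratio", "Std. Error"])
  )
  attr(law, "residuals") <- unname(stats::residuals(fit))
  attr(law, "n") <- nrow(obs)
  law
}

#' Fit the droplet-frequency power law in log space
#'
#' The power law f_d = A (Q_d Q_c)^B becomes linear after taking logs,
#' log f_d = log A + B log(Q_d Q_c), which matches the log-log collapse of
#' the frequency data and a multiplicative noise model. With `fixed_B`
#' supplied only the prefactor is estimated (the convention under which the
#' default A = 1.64 was obtained, with B held at 2/3); otherwise A and B are
#' fit jointly.
#'
#' @param observations Data frame with columns `Q_d`, `Q_c`, `f_d` (Hz,
#'   flow rates in uL/min), e.g. from [read_frequency_observations()] or
#'   [synth_frequency_dataset()].
#' @param fixed_B Optional exponent to hold fixed.
#' @return A [frequency_law()] with estimates and standard errors (`B_se`
#'   is `NA` when B was fixed; the standard error of A is propagated from
#'   log space, se(A) = A se(log A)). Attributes `"residuals"` (log scale)
#'   and `"n"` are attached.
#' @export
fit_frequency_law <- function(observations, fixed_B = NULL) {
  obs <- .check_frequency_obs(observations)
  log_prod <- log(obs$Q_d * obs$Q_c)
  log_f <- log(obs$f_d)
  if (is.null(fixed_B)) {
    if (length(unique(log_prod)) < 2L) {
      stop("degenerate design: need at least 2 distinct products Q_d*Q_c to fit B",
           call. = FALSE)
    }
    fit <- stats::lm(log_f ~ log_prod)
    cf <- .lm_coefs(fit)
    log_A <- unname(cf["(Intercept)", "Estimate"])
    A <- exp(log_A)
    law <- frequency_law(
      A = A, B = unname(cf["log_prod", "Estimate"]),
      A_se = A * unname(cf["(Intercept)", "Std. Error"]),
      B_se = unname(cf["log_prod", "Std. Error"])
    )
  } else {
    .assert_scalar(fixed_B, "fixed_B")
    resp <- log_f - fixed_B * log_prod
    fit <- stats::lm(resp ~ 1)
    cf <- .lm_coefs(fit)
    log_A <- unname(cf[1, "Estimate"])
    A <- exp(log_A)
    se_logA <- if (nrow(obs) > 1L) unname(cf[1, "Std. Error"]) else 0
    law <- frequency_law(A = A, B = fixed_B, A_se = A * se_logA,
                         B_se = NA_real_)
  }
  attr(law, "residuals") <- unname(stats::residuals(fit))
  attr(law, "n") <- nrow(obs)
  law
}

# ---- observation-table I/O (CSV, header required, decimal point) ----------

#' Read and write scaling-law observation tables
#'
#' Delimited-text interchange for the two observation tables. Length tables
#' carry columns `Q_d_uL_min, Q_c_uL_min, L_over_W`; frequency tables carry
#' `Q_d_uL_min, Q_c_uL_min, f_d_Hz`. A header row is required.
#'
#' @param path File path.
#' @return The readers return a data frame with columns `Q_d`, `Q_c` and
#'   `L_over_W` or `f_d`; the writers return `path` invisibly.
#' @name observation_io
NULL

#' @rdname observation_io
#' @export
read_length_observations <- function(path) {
  df <- utils::read.csv(path)
  .require_cols(df, c("Q_d_uL_min", "Q_c_uL_min", "L_over_W"), path)
  .check_length_obs(data.frame(Q_d = df$Q_d_uL_min, Q_c = df$Q_c_uL_min,
                               L_over_W = df$L_over_W))
}

#' @rdname observation_io
#' @export
read_frequency_observations <- function(path) {
  df <- utils::read.csv(path)
  .require_cols(df, c("Q_d_uL_min", "Q_c_uL_min", "f_d_Hz"), path)
  .check_frequency_obs(data.frame(Q_d = df$Q_d_uL_min, Q_c = df$Q_c_uL_min,
                                  f_d = df$f_d_Hz))
}

#' @rdname observation_io
#' @param observations Data frame as returned by the matching reader.
#' @export
write_length_observations <- function(observations, path) {
  obs <- .check_length_obs(observations)
  utils::write.csv(
    data.frame(Q_d_uL_min = obs$Q_d, Q_c_uL_min = obs$Q_c,
               L_over_W = obs$L_over_W),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname observation_io
#' @export
write_frequency_observations <- function(observations, path) {
  obs <- .check_frequency_obs(observations)
  utils::write.csv(
    data.frame(Q_d_uL_min = obs$Q_d, Q_c_uL_min = obs$Q_c, f_d_Hz = obs$f_d),
    path, row.names = FALSE)
  invisible(path)
}

# ---- internal validation ---------------------------------------------------

as_flow_pair <- function(pair) {
  if (inherits(pair, "flow_pair")) return(pair)
  if (is.data.frame(pair) && all(c("Q_d", "Q_c") %in% names(pair))) {
    return(flow_pair(pair$Q_d, pair$Q_c))
  }
  stop("`pair` must be a flow_pair (see `flow_pair()`)", call. = FALSE)
}

.require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("'%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

.check_length_obs <- function(observations) {
  stopifnot(is.data.frame(observations))
  .require_cols(observations, c("Q_d", "Q_c", "L_over_W"), "length observations")
  .assert_positive(observations$Q_d, "Q_d")
  .assert_positive(observations$Q_c, "Q_c")
  .assert_positive(observations$L_over_W, "L_over_W")
  observations
}

.check_frequency_obs <- function(observations) {
  stopifnot(is.data.frame(observations))
  .require_cols(observations, c("Q_d", "Q_c", "f_d"), "frequency observations")
  .assert_positive(observations$Q_d, "Q_d")
  .assert_positive(observations$Q_c, "Q_c")
  .assert_positive(observations$f_d, "f_d")
  observations
}

# summary.lm warns on noise-free synthetic data ("essentially perfect fit");
# a zero-residual fit is a legitimate input here, so that warning is muted
.lm_coefs <- function(fit) {
  withCallingHandlers(
    summary(fit)$coefficients,
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}
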