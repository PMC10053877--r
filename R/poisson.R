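#' Poisson occupancy probability
#'
#' Probability P(k, n) = k^n exp(-k) / n! of finding exactly `n` particles
#' in a droplet when particles arrive at random with mean occupancy `k`.
#' At k = 1 the single-particle probability is e^(-1), about 37%: the
#' Poisson ceiling on single encapsulation for stochastic loading.
#' Evaluated in log space (via [stats::dpois()]) so large `n` is stable.
#'
#' @param k Mean occupancy (particles per droplet); `k >= 0`.
#' @param n Occupancy; non-negative integer(s).
#' @return Probability vector, same length as `n`.
#' @examples
#' poisson_pmf(1, 1)      # 0.3679
#' poisson_pmf(1, 0:4)
#' @export
poisson_pmf <- function(k, n) {
  .assert_scalar(k, "k")
  if (!is.numeric(k) || is.na(k) || k < 0) {
    stop("mean occupancy `k` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) == 0L || anyNA(n) ||
      any(n < 0) || any(n != floor(n))) {
    stop("occupancy `n` must be non-negative integer(s)", call. = FALSE)
  }
  stats::dpois(as.integer(round(n)), lambda = k)
}

#' Occupancy histogram of particles per droplet
#'
#' Tabulates per-droplet particle counts into relative frequencies over the
#' full support 0..max(counts). Empty droplets (n = 0) are part of the
#' denominator: the Poisson baseline is a probability over all occupancies,
#' so relative frequencies must be, too. The mean occupancy k is the sample
#' mean, total particles / total droplets (the maximum-likelihood rate for
#' a Poisson model).
#'
#' @param counts Non-empty vector of non-negative integer per-droplet
#'   counts, or a [droplet_counts] object from [encapsulate()].
#' @return An object of class `"occupancy_histogram"`: a list with
#'   `frequencies` (named numeric, names "0", "1", ...), `n_droplets`, and
#'   mean occupancy `k`.
#' @examples
#' build_histogram(c(0, 1, 2, 1))
#' @export
build_histogram <- function(counts) {
  if (inherits(counts, "droplet_counts")) counts <- counts$counts
  if (length(counts) == 0L) stop("`counts` must be non-empty", call. = FALSE)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  counts <- as.integer(counts)
  support <- 0:max(counts)
  tab <- tabulate(counts + 1L, nbins = length(support))
  freq <- tab / length(counts)
  names(freq) <- as.character(support)
  structure(
    list(frequencies = freq, n_droplets = length(counts),
         k = sum(counts) / length(counts)),
    class = "occupancy_histogram"
  )
}

#' Compare an occupancy histogram to its Poisson baseline
#'
#' Evaluates the Poisson pmf at the histogram's own mean occupancy over the
#' observed support and reports the excess of single-particle droplets over
#' the stochastic value: `excess_at_1 = freq(1) - P(k, 1)`. A positive
#' excess means the loading beat the Poisson limit, the signature of an
#' ordered particle train synchronised to the droplet generator; zero (in
#' expectation) means fully stochastic loading.
#'
#' @param hist An [build_histogram()] result.
#' @return An object of class `"poisson_comparison"`: list with `histogram`,
#'   `baseline` (named probabilities on the same support) and `excess_at_1`.
#' @examples
#' compare_to_poisson(build_histogram(rep(1, 10)))   # excess ~0.632
#' @export
compare_to_poisson <- function(hist) {
  stopifnot(inherits(hist, "occupancy_histogram"))
  support <- as.integer(names(hist$frequencies))
  baseline <- poisson_pmf(hist$k, support)
  names(baseline) <- names(hist$frequencies)
  observed_1 <- if ("1" %in% names(hist$frequencies)) hist$frequencies[["1"]] else 0
  baseline_1 <- poisson_pmf(hist$k, 1L)
  structure(
    list(histogram = hist, baseline = baseline,
         excess_at_1 = observed_1 - baseline_1),
    class = "poisson_comparison"
  )
}

#' Chi-square goodness of fit of counts to a Poisson occupancy model
#'
#' Utility for validating simulated counts: pools bins with small expected
#' counts (tail-first, threshold 5) and runs a chi-square test against
#' Poisson(k) with k estimated from the sample (one df deducted).
#'
#' @param counts Per-droplet counts (vector or [droplet_counts]).
#' @return List with `statistic`, `df`, `p_value`, `k`.
#' @export
occupancy_poisson_gof <- function(counts) {
  hist <- build_histogram(counts)
  n <- hist$n_droplets
  support <- as.integer(names(hist$frequencies))
  observed <- hist$frequencies * n
  expected <- poisson_pmf(hist$k, support) * n
  # open the last bin to the full upper tail
  expected[length(expected)] <- n * (1 - stats::ppois(max(support) - 1L, hist$k))
  # pool from the tail until every expected count is >= 5
  while (length(expected) > 2L && expected[length(expected)] < 5) {
    m <- length(expected)
    expected[m - 1L] <- expected[m - 1L] + expected[m]
    observed[m - 1L] <- observed[m - 1L] + observed[m]
    expected <- expected[-m]; observed <- observed[-m]
  }
  stat <- sum((observed - expected)^2 / expected)
  df <- max(length(expected) - 2L, 1L)  # -1 constraint, -1 estimated k
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), k = hist$k)
}

# ---- count-table I/O -------------------------------------------------------

#' Read and write per-droplet count tables and histogram summaries
#'
#' Count tables are CSV with one row per droplet and a single column
#' `n_particles`. Histogram summaries are CSV with columns
#' `n, relative_frequency, poisson_baseline`.
#'
#' @param path File path.
#' @name count_io
NULL

#' @rdname count_io
#' @export
read_counts <- function(path) {
  df <- utils::read.csv(path)
  .require_cols(df, "n_particles", path)
  df$n_particles
}

#' @rdname count_io
#' @param counts Per-droplet counts (vector or [droplet_counts]).
#' @export
write_counts <- function(counts, path) {
  if (inherits(counts, "droplet_counts")) counts <- counts$counts
  utils::write.csv(data.frame(n_particles = as.integer(counts)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname count_io
#' @param comparison A [compare_to_poisson()] result.
#' @export
write_histogram <- function(comparison, path) {
  stopifnot(inherits(comparison, "poisson_comparison"))
  utils::write.csv(as.data.frame(comparison), path, row.names = FALSE)
  invisible(path)
}

#' @export
as.data.frame.poisson_comparison <- function(x, ...) {
  data.frame(
    n = as.integer(names(x$histogram$frequencies)),
    relative_frequency = unname(x$histogram$frequencies),
    poisson_baseline = unname(x$baseline)
  )
}

#' @export
print.occupancy_histogram <- function(x, ...) {
  cat(sprintf("Occupancy histogram: %d droplets, mean occupancy k = %.4g\n",
              x$n_droplets, x$k))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' @export
print.poisson_comparison <- function(x, ...) {
  print(x$histogram)
  cat(sprintf("Poisson baseline at k = %.4g; excess at n = 1: %+.4f\n",
              x$histogram$k, x$excess_at_1))
  invisible(x)
}
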