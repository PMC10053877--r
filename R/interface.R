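# Configuration loading and the command-line front end.
#
# One YAML config drives every stage; CLI flags override config keys
# (flag > file > package defaults). Unknown keys warn, missing required
# keys error by name, and every block is validated through the same
# constructors the R API uses.

.required_config_keys <- list(
  geometry = c("W_um", "H_um"),
  fluids = c("mu_c_Pa_s", "gamma_N_m"),
  particle = c("d_m", "u_m_s"),
  train = c("phi_l"),
  laws = character(0),
  simulation = c("duration_s", "seed")
)

.known_config_keys <- list(
  geometry = c("W_um", "H_um"),
  fluids = c("mu_c_Pa_s", "gamma_N_m", "lambda_s", "dispersed_label"),
  particle = c("d_m", "u_m_s", "phi"),
  train = c("phi_l", "gap_cv", "aggregate_fraction"),
  laws = c("frequency", "length"),
  simulation = c("duration_s", "seed", "f_d_Hz", "flow_pair", "phase_s"),
  output = c("dir")
)

#' Load and validate a run configuration
#'
#' Reads a YAML file describing the device geometry, fluid and particle
#' properties, the two fitted scaling laws, the particle-train parameters
#' and the simulation block, and validates every block through the same
#' constructors as the R API, so an invalid value fails on load with a
#' message naming the offending key. Unknown keys are reported as warnings;
#' missing required keys are errors. The droplet frequency may be given
#' directly (`simulation.f_d_Hz`) or as a flow-rate pair
#' (`simulation.flow_pair.Q_d` / `.Q_c`) evaluated through the frequency
#' law; the particle frequency is always derived from the train block.
#'
#' A commented example with the default hyaluronic-acid/mineral-oil system
#' ships at `system.file("extdata", "default_config.yaml", package =
#' "dropletrain")`.
#'
#' @param path Path to a YAML config file.
#' @return An object of class `"run_config"`: list with `geometry`,
#'   `fluids`, `particle`, `train` (a [train_spec()]), `laws` (list with
#'   `frequency`, `length`), `simulation` (list with `f_d`, `duration`,
#'   `seed`, `phase`) and `output_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' not found", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)

  unknown_sections <- setdiff(names(raw), names(.known_config_keys))
  if (length(unknown_sections)) {
    warning(sprintf("unknown config section(s) ignored: %s",
                    paste(unknown_sections, collapse = ", ")), call. = FALSE)
  }
  for (sec in names(.required_config_keys)) {
    if (is.null(raw[[sec]])) {
      stop(sprintf("config is missing required section '%s'", sec),
           call. = FALSE)
    }
    missing <- setdiff(.required_config_keys[[sec]], names(raw[[sec]]))
    if (length(missing)) {
      stop(sprintf("config section '%s' is missing required key(s): %s", sec,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    unknown <- setdiff(names(raw[[sec]]), .known_config_keys[[sec]])
    if (length(unknown)) {
      warning(sprintf("unknown key(s) in config section '%s' ignored: %s",
                      sec, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }

  wrap <- function(section, key, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("config key '%s.%s' is invalid: %s", section, key,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  geom <- wrap("geometry", "W_um/H_um",
               geometry(raw$geometry$W_um, raw$geometry$H_um))
  fluids <- wrap("fluids", "mu_c_Pa_s/gamma_N_m", fluid_properties(
    mu_c = raw$fluids$mu_c_Pa_s, gamma = raw$fluids$gamma_N_m,
    lambda = raw$fluids$lambda_s,
    dispersed_label = raw$fluids$dispersed_label %||% "dispersed phase"))
  particle <- wrap("particle", "d_m/u_m_s", particle_spec(
    d = raw$particle$d_m, u = raw$particle$u_m_s,
    phi = raw$particle$phi %||% NA_real_))
  train <- wrap("train", "phi_l", train_spec(
    particle, phi_l = raw$train$phi_l,
    gap_cv = raw$train$gap_cv %||% 0.25,
    aggregate_fraction = raw$train$aggregate_fraction %||% 0.1))

  freq_law <- wrap("laws", "frequency", frequency_law(
    A = raw$laws$frequency$A %||% 1.64,
    B = raw$laws$frequency$B %||% (2 / 3)))
  len_law <- wrap("laws", "length", length_law(
    intercept = raw$laws$length$intercept %||% 1,
    slope = raw$laws$length$slope %||% 2))

  sim <- raw$simulation
  f_d <- if (!is.null(sim$f_d_Hz)) {
    wrap("simulation", "f_d_Hz", { .assert_positive(sim$f_d_Hz, "f_d_Hz"); sim$f_d_Hz })
  } else if (!is.null(sim$flow_pair)) {
    wrap("simulation", "flow_pair", droplet_frequency(
      flow_pair(sim$flow_pair$Q_d, sim$flow_pair$Q_c), freq_law))
  } else {
    # default: synchronise droplets to the train
    particle_frequency(train)
  }
  duration <- wrap("simulation", "duration_s",
                   { .assert_positive(sim$duration_s, "duration_s"); sim$duration_s })
  seed <- wrap("simulation", "seed", {
    if (!is.numeric(sim$seed) || sim$seed != floor(sim$seed)) {
      stop("must be an integer")
    }
    as.integer(sim$seed)
  })

  structure(
    list(geometry = geom, fluids = fluids, particle = particle, train = train,
         laws = list(frequency = freq_law, length = len_law),
         simulation = list(f_d = f_d, duration = duration, seed = seed,
                           phase = sim$phase_s %||% "random"),
         output_dir = raw$output$dir %||% "."),
    class = "run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_config <- function(x, ...) {
  cat("Run configuration\n")
  cat(sprintf("  channel: W = %g um, H = %g um; oil viscosity %g Pa s, gamma = %g N/m\n",
              x$geometry$W_um, x$geometry$H_um, x$fluids$mu_c, x$fluids$gamma))
  print(x$train)
  cat(sprintf("  simulation: f_d = %.4g Hz, duration %g s, seed %d\n",
              x$simulation$f_d, x$simulation$duration, x$simulation$seed))
  invisible(x)
}

# ---- command line ----------------------------------------------------------

.cli_usage <- paste(
  "usage: dropletrain <command> [options]",
  "",
  "commands:",
  "  simulate         simulate a particle train, encapsulate it, write",
  "                   counts.csv and histogram.csv",
  "  fit-frequency    fit the droplet-frequency power law to a CSV table",
  "  fit-length       fit the droplet-length master curve to a CSV table",
  "  design           print the frequency-matched design table",
  "  poisson-compare  compare a counts CSV to its Poisson baseline",
  "",
  "options:",
  "  --config PATH        YAML run configuration (default: bundled example)",
  "  --seed INT           override the config seed",
  "  --out-dir DIR        output directory (default: config output.dir)",
  "  --observations PATH  observation CSV for the fit-* commands",
  "  --counts PATH        counts CSV for poisson-compare",
  "  --Q-HA LIST          comma-separated dispersed flow rates for design",
  "  --fixed-B VALUE      hold the frequency exponent fixed (default 2/3;",
  "                       pass 'free' to fit it)",
  sep = "\n")

.cli_parse <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      stop(sprintf("unexpected argument '%s'", a), call. = FALSE)
    }
    if (i == length(args)) stop(sprintf("flag '%s' needs a value", a),
                                call. = FALSE)
    opts[[substring(a, 3)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  opts
}

.cli_log <- function(...) message("[dropletrain] ", sprintf(...))

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `fit-frequency`, `fit-length`,
#' `design` and `poisson-compare` over the package API, writes CSV outputs
#' and logs the resolved parameters and seed to stderr so every output is
#' regenerable. A thin wrapper script suitable for `Rscript` ships at
#' `system.file("cli", "dropletrain", package = "dropletrain")`.
#'
#' @param args Character vector of command-line arguments (the subcommand
#'   first); defaults to the process arguments.
#' @return Exit status, invisibly: 0 on success, 1 on runtime error, 2 on
#'   usage error.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[[1]] %in% c("-h", "--help", "help")) {
    cat(.cli_usage, "\n")
    return(invisible(if (length(args) == 0L) 2L else 0L))
  }
  cmd <- args[[1]]
  opts <- tryCatch(.cli_parse(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts))
    cat(.cli_usage, "\n")
    return(invisible(2L))
  }
  status <- tryCatch({
    switch(
      cmd,
      "simulate" = .cli_simulate(opts),
      "fit-frequency" = .cli_fit_frequency(opts),
      "fit-length" = .cli_fit_length(opts),
      "design" = .cli_design(opts),
      "poisson-compare" = .cli_poisson_compare(opts),
      {
        message(sprintf("unknown command '%s'", cmd))
        cat(.cli_usage, "\n")
        return(invisible(2L))
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cli_config <- function(opts) {
  path <- opts$config %||%
    system.file("extdata", "default_config.yaml", package = "dropletrain")
  cfg <- load_config(path)
  if (!is.null(opts$seed)) {
    cfg$simulation$seed <- as.integer(opts$seed)
  }
  if (!is.null(opts[["out-dir"]])) cfg$output_dir <- opts[["out-dir"]]
  cfg
}

.cli_simulate <- function(opts) {
  cfg <- .cli_config(opts)
  f_p <- particle_frequency(cfg$train)
  .cli_log("simulate: f_p = %.4g Hz, f_d = %.4g Hz, gap_cv = %.3g, doublets %.3g, duration %g s, seed %d",
           f_p, cfg$simulation$f_d, cfg$train$gap_cv,
           cfg$train$aggregate_fraction, cfg$simulation$duration,
           cfg$simulation$seed)
  series <- generate_arrivals(
    f_p = f_p, gap_cv = cfg$train$gap_cv, duration = cfg$simulation$duration,
    aggregate_fraction = cfg$train$aggregate_fraction,
    seed = cfg$simulation$seed)
  counts <- encapsulate(series, f_d = cfg$simulation$f_d,
                        phase = cfg$simulation$phase,
                        seed = cfg$simulation$seed + 1L)
  cmp <- compare_to_poisson(build_histogram(counts))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  counts_path <- file.path(cfg$output_dir, "counts.csv")
  hist_path <- file.path(cfg$output_dir, "histogram.csv")
  write_counts(counts, counts_path)
  write_histogram(cmp, hist_path)
  .cli_log("wrote %s (%d droplets) and %s; excess over Poisson at n=1: %+.4f",
           counts_path, length(counts$counts), hist_path, cmp$excess_at_1)
}

.cli_fit_frequency <- function(opts) {
  if (is.null(opts$observations)) stop("--observations is required")
  obs <- read_frequency_observations(opts$observations)
  fixed_B <- opts[["fixed-B"]] %||% "0.6666666666666666"
  law <- if (identical(fixed_B, "free")) {
    fit_frequency_law(obs)
  } else {
    fit_frequency_law(obs, fixed_B = as.numeric(fixed_B))
  }
  .cli_log("fit-frequency: %d observations", attr(law, "n"))
  print(law)
}

.cli_fit_length <- function(opts) {
  if (is.null(opts$observations)) stop("--observations is required")
  obs <- read_length_observations(opts$observations)
  law <- fit_length_law(obs)
  .cli_log("fit-length: %d observations", attr(law, "n"))
  print(law)
}

.cli_design <- function(opts) {
  cfg <- .cli_config(opts)
  grid <- if (!is.null(opts[["Q-HA"]])) {
    as.numeric(strsplit(opts[["Q-HA"]], ",")[[1]])
  } else {
    c(1, 2, 4, 6, 8, 10)
  }
  tab <- design_table(grid, cfg$train, cfg$laws$frequency)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(cfg$output_dir, "design_table.csv")
  utils::write.csv(tab, out, row.names = FALSE)
  .cli_log("design: matched frequency %.4g Hz; wrote %s",
           tab$matched_frequency_Hz[1], out)
  print(tab, row.names = FALSE)
}

.cli_poisson_compare <- function(opts) {
  if (is.null(opts$counts)) stop("--counts is required")
  counts <- read_counts(opts$counts)
  cmp <- compare_to_poisson(build_histogram(counts))
  out_dir <- opts[["out-dir"]] %||% dirname(opts$counts)
  out <- file.path(out_dir, "histogram.csv")
  write_histogram(cmp, out)
  .cli_log("poisson-compare: %d droplets, k = %.4g, excess at n=1 %+.4f; wrote %s",
           cmp$histogram$n_droplets, cmp$histogram$k, cmp$excess_at_1, out)
  print(cmp)
}
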