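test_that("arrival generation spans perfect trains to Poisson streams", {
  # degenerate gaps: a perfect 50 Hz train
  s0 <- generate_arrivals(f_p = 50, gap_cv = 0, duration = 2,
                          aggregate_fraction = 0, seed = 1)
  expect_equal(diff(s0$times), rep(0.02, length(s0$times) - 1))
  expect_true(all(s0$times > 0 & s0$times < 2))
  expect_true(all(s0$particles_per_arrival == 1L))

  # exponential gaps: mean gap within 3 standard errors of 1/f_p
  s1 <- generate_arrivals(f_p = 50, gap_cv = 1, duration = 100,
                          aggregate_fraction = 0, seed = 2)
  gaps <- diff(s1$times)
  se <- 0.02 / sqrt(length(gaps))  # exponential: sd = mean
  expect_lt(abs(mean(gaps) - 0.02), 3 * se)
  expect_true(all(diff(s1$times) > 0))

  # intermediate ordering: gamma gaps with the requested dispersion
  s2 <- generate_arrivals(f_p = 50, gap_cv = 0.25, duration = 200,
                          aggregate_fraction = 0, seed = 3)
  g2 <- diff(s2$times)
  expect_equal(stats::sd(g2) / mean(g2), 0.25, tolerance = 0.05)

  # every arrival is a doublet at aggregate_fraction 1
  s3 <- generate_arrivals(50, gap_cv = 0.5, duration = 5,
                          aggregate_fraction = 1, seed = 4)
  expect_true(all(s3$particles_per_arrival == 2L))

  expect_error(generate_arrivals(-1, 0, 1, seed = 1), "f_p")
  expect_error(generate_arrivals(50, -0.1, 1, seed = 1), "gap_cv")
  expect_error(generate_arrivals(50, 0, 1, 0), "seed")
})

test_that("generation is seed-reproducible and leaves the caller's RNG alone", {
  a <- generate_arrivals(50, 1, 10, 0.1, seed = 99)
  b <- generate_arrivals(50, 1, 10, 0.1, seed = 99)
  expect_identical(a$times, b$times)
  expect_identical(a$particles_per_arrival, b$particles_per_arrival)

  set.seed(7); x1 <- runif(1)
  set.seed(7); invisible(generate_arrivals(50, 1, 1, seed = 5)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("encapsulation assigns arrivals to periodic droplets and conserves particles", {
  # perfect train at matched frequency: every droplet holds exactly one
  s <- generate_arrivals(50, gap_cv = 0, duration = 20,
                         aggregate_fraction = 0, seed = 1)
  dc <- encapsulate(s, f_d = 50, phase = 0.007)
  expect_true(all(dc$counts == 1L))
  expect_equal(length(dc$counts), floor((20 - 0.007) * 50))

  # empty series: all droplets empty
  none <- generate_arrivals(f_p = 0.001, gap_cv = 0, duration = 1,
                            aggregate_fraction = 0, seed = 1)
  expect_length(none$times, 0)
  expect_true(all(encapsulate(none, f_d = 10, phase = 0)$counts == 0L))

  # exact particle conservation inside the covered span
  s2 <- generate_arrivals(40, gap_cv = 0.7, duration = 30,
                          aggregate_fraction = 0.2, seed = 8)
  dc2 <- encapsulate(s2, f_d = 55, phase = "random", seed = 9)
  span_end <- dc2$phase + length(dc2$counts) * dc2$droplet_period
  inside <- s2$times >= dc2$phase & s2$times < span_end
  expect_identical(sum(dc2$counts), sum(s2$particles_per_arrival[inside]))

  expect_error(encapsulate(s, f_d = 50, phase = 0.03), "phase")
  expect_error(encapsulate(s, f_d = 50, phase = "random"), "seed")
})

test_that("fully stochastic arrivals reproduce Poisson occupancy at several loadings", {
  f_d <- 50
  for (k in c(0.5, 1, 2)) {
    s <- generate_arrivals(f_p = k * f_d, gap_cv = 1, duration = 20000 / f_d,
                           aggregate_fraction = 0, seed = 300 + k * 10)
    dc <- encapsulate(s, f_d = f_d, phase = "random", seed = 400 + k * 10)
    gof <- occupancy_poisson_gof(dc)
    expect_gt(gof$p_value, 0.01)
    expect_equal(gof$k, k, tolerance = 0.05)
  }
})

test_that("mean occupancy converges to f_p (1 + aggregate_fraction) / f_d", {
  f_p <- 50; f_d <- 40; af <- 0.1
  s <- generate_arrivals(f_p, gap_cv = 0.5, duration = 500,
                         aggregate_fraction = af, seed = 21)
  dc <- encapsulate(s, f_d = f_d, phase = "random", seed = 22)
  expected <- f_p * (1 + af) / f_d
  se <- stats::sd(dc$counts) / sqrt(length(dc$counts))
  expect_lt(abs(mean(dc$counts) - expected), 3 * se)
})

test_that("single-encapsulation efficiency degrades monotonically with gap dispersion", {
  eff <- vapply(c(0, 0.25, 0.5, 1), single_fraction, numeric(1))
  expect_true(all(diff(eff) <= 0))
  expect_equal(eff[1], 1, tolerance = 1e-3)       # perfect train
  expect_equal(eff[4], exp(-1), tolerance = 0.02) # Poisson limit
})

test_that("synthetic scaling datasets reproduce the laws at zero noise", {
  pairs <- grid_pairs(36, seed = 61)
  law_f <- frequency_law(1.64, 2 / 3)
  exact_f <- synth_frequency_dataset(law_f, pairs, noise_sigma = 0, seed = 1)
  expect_equal(exact_f$f_d, droplet_frequency(pairs, law_f), tolerance = 1e-15)
  expect_equal(nrow(exact_f), 36)

  law_l <- length_law(1, 2)
  exact_l <- synth_length_dataset(law_l, pairs, noise_sigma = 0, seed = 1)
  expect_equal(exact_l$L_over_W, normalised_length(pairs, law_l),
               tolerance = 1e-15)

  # a single-ratio grid is rejected downstream by the fitter
  degen <- synth_length_dataset(law_l, flow_pair(c(2, 4), c(4, 8)),
                                noise_sigma = 0.05, seed = 2)
  expect_error(fit_length_law(degen), "degenerate")

  # identical seeds give identical noise
  n1 <- synth_frequency_dataset(law_f, pairs, 0.05, seed = 9)
  n2 <- synth_frequency_dataset(law_f, pairs, 0.05, seed = 9)
  expect_identical(n1, n2)
})

test_that("arrival series dump to CSV with one row per arrival", {
  tmp <- withr::local_tempdir()
  s <- generate_arrivals(50, 0.25, 1, 0.1, seed = 77)
  path <- file.path(tmp, "arrivals.csv")
  write_arrivals(s, path)
  back <- utils::read.csv(path)
  expect_named(back, c("t_s", "n_particles"))
  expect_equal(back$t_s, s$times, tolerance = 1e-12)
  expect_equal(back$n_particles, s$particles_per_arrival)
})
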