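test_that("normalised length follows the linear master curve", {
  law <- length_law(1, 2)
  cases <- data.frame(
    Q_d = c(1e-9, 8, 5),
    Q_c = c(1, 8, 10),
    expected = c(1, 3, 2)  # intercept-only limit; ratio 1; ratio 0.5
  )
  expect_equal(normalised_length(flow_pair(cases$Q_d, cases$Q_c), law),
               cases$expected, tolerance = 1e-6)

  # strictly increasing in Q_d, strictly decreasing in Q_c
  qs <- c(1, 2, 4, 6, 8, 10)
  expect_true(all(diff(normalised_length(flow_pair(qs, 5), law)) > 0))
  expect_true(all(diff(normalised_length(flow_pair(5, qs), law)) < 0))

  expect_error(flow_pair(-1, 2), "Q_d")
  expect_error(flow_pair(1, 0), "Q_c")
})

test_that("droplet frequency follows the product power law and is symmetric", {
  expect_equal(droplet_frequency(flow_pair(2, 3), frequency_law(A = 1, B = 1)), 6)
  expect_equal(droplet_frequency(flow_pair(1, 1), frequency_law(1.64, 2 / 3)), 1.64)
  # 1.64 * 64^(2/3) = 1.64 * 16
  expect_equal(droplet_frequency(flow_pair(8, 8), frequency_law(1.64, 2 / 3)),
               26.24, tolerance = 1e-12)

  pairs <- grid_pairs(50, seed = 7)
  law <- frequency_law(1.64, 2 / 3)
  expect_equal(droplet_frequency(pairs, law),
               droplet_frequency(flow_pair(pairs$Q_c, pairs$Q_d), law))
  qs <- c(1, 2, 4, 6, 8, 10)
  expect_true(all(diff(droplet_frequency(flow_pair(qs, 3), law)) > 0))
  expect_true(all(diff(droplet_frequency(flow_pair(3, qs), law)) > 0))
})

test_that("capillary number matches a direct SI computation and scales dimensionally", {
  geom <- default_geom()
  fluids <- default_fluids()
  # independent unit-by-unit oracle: Q in m^3/s over the SI cross-section
  ca_oracle <- function(q_uL_min, mu, gamma, w_um, h_um) {
    u_c <- (q_uL_min * 1e-9 / 60) / ((w_um * 1e-6) * (h_um * 1e-6))
    mu * u_c / gamma
  }
  expect_equal(capillary_number(1, geom, fluids),
               ca_oracle(1, 0.029, 3.35e-3, 100, 100),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(as.numeric(capillary_number(1, geom, fluids)), 0.0144,
               tolerance = 1e-2)
  expect_equal(attr(capillary_number(1, geom, fluids), "U_c"), 1 / 600,
               tolerance = 1e-12)

  # linear in Q_c and mu_c; inverse in gamma, W, H
  ca1 <- as.numeric(capillary_number(1, geom, fluids))
  expect_equal(as.numeric(capillary_number(10, geom, fluids)), 10 * ca1)
  expect_equal(as.numeric(capillary_number(1, geom,
                                           fluid_properties(2 * 0.029, 3.35e-3))),
               2 * ca1)
  expect_equal(as.numeric(capillary_number(1, geom,
                                           fluid_properties(0.029, 2 * 3.35e-3))),
               ca1 / 2)
  expect_equal(as.numeric(capillary_number(1, geometry(200, 100), fluids)),
               ca1 / 2)
  expect_equal(as.numeric(capillary_number(1, geometry(100, 200), fluids)),
               ca1 / 2)
  expect_error(fluid_properties(0.029, 0), "gamma")
})

test_that("length-law fit recovers generating parameters", {
  # two points: hand-solved 2x2 system (slope 0.5/0.25 = 2, intercept 1)
  two <- data.frame(Q_d = c(0.25, 0.5), Q_c = 1, L_over_W = c(1.5, 2.0))
  fit2 <- fit_length_law(two)
  expect_equal(fit2$slope, 2, tolerance = 1e-12)
  expect_equal(fit2$intercept, 1, tolerance = 1e-12)

  # exact recovery for arbitrary positive parameters on noise-free data
  params <- dropletrain:::.with_seed(31, data.frame(
    intercept = runif(5, 0.5, 3), slope = runif(5, 0.1, 5)))
  for (i in seq_len(nrow(params))) {
    law <- length_law(params$intercept[i], params$slope[i])
    obs <- synth_length_dataset(law, ratio_pairs(20), noise_sigma = 0, seed = 1)
    fit <- fit_length_law(obs)
    expect_equal(fit$slope, law$slope, tolerance = 1e-9)
    expect_equal(fit$intercept, law$intercept, tolerance = 1e-9)
  }

  # noisy recovery within 3 standard errors
  obs <- synth_length_dataset(length_law(1, 2), ratio_pairs(60),
                              noise_sigma = 0.05, seed = 11)
  fit <- fit_length_law(obs)
  expect_lt(abs(fit$slope - 2), 3 * fit$slope_se)
  expect_lt(abs(fit$intercept - 1), 3 * fit$intercept_se)
  expect_length(attr(fit, "residuals"), 60)

  # degenerate design: a single distinct ratio
  one_ratio <- data.frame(Q_d = c(2, 4), Q_c = c(4, 8), L_over_W = c(2, 2.1))
  expect_error(fit_length_law(one_ratio), "degenerate")
})

test_that("frequency-law fit recovers parameters in log space, fixed or free B", {
  pairs <- grid_pairs(40, seed = 5)
  for (p in list(c(1.64, 2 / 3), c(0.5, 1.2), c(8, 0.25))) {
    law <- frequency_law(p[1], p[2])
    obs <- synth_frequency_dataset(law, pairs, noise_sigma = 0, seed = 1)
    free <- fit_frequency_law(obs)
    expect_equal(free$A, p[1], tolerance = 1e-9)
    expect_equal(free$B, p[2], tolerance = 1e-9)
    fixed <- fit_frequency_law(obs, fixed_B = p[2])
    expect_equal(fixed$A, p[1], tolerance = 1e-9)
    expect_true(is.na(fixed$B_se))
  }

  # noisy recovery of the prefactor with the exponent held at 2/3
  obs <- synth_frequency_dataset(frequency_law(1.64, 2 / 3),
                                 grid_pairs(100, seed = 23),
                                 noise_sigma = 0.05, seed = 29)
  fit <- fit_frequency_law(obs, fixed_B = 2 / 3)
  expect_lt(abs(fit$A - 1.64), 3 * fit$A_se)

  expect_error(fit_frequency_law(data.frame(Q_d = 1, Q_c = 1, f_d = -2)), "f_d")
  same_product <- data.frame(Q_d = c(2, 4), Q_c = c(4, 2), f_d = c(5, 5.1))
  expect_error(fit_frequency_law(same_product), "degenerate")
})

test_that("observation tables round-trip through CSV", {
  tmp <- withr::local_tempdir()
  lobs <- synth_length_dataset(length_law(), ratio_pairs(10), 0.05, seed = 3)
  fpath <- file.path(tmp, "lengths.csv")
  write_length_observations(lobs, fpath)
  expect_equal(read_length_observations(fpath), lobs, tolerance = 1e-12)

  fobs <- synth_frequency_dataset(frequency_law(), grid_pairs(10, seed = 4),
                                  0.05, seed = 5)
  fpath2 <- file.path(tmp, "freqs.csv")
  write_frequency_observations(fobs, fpath2)
  expect_equal(read_frequency_observations(fpath2), fobs, tolerance = 1e-12)

  bad <- file.path(tmp, "bad.csv")
  utils::write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_length_observations(bad), "missing required column")
})
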