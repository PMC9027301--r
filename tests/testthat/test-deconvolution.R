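test_that("series-RC extraction inverts its construction and flags non-capacitive records", {
  got <- extract_series_rc(100 - 1i / (2 * pi * 4000 * 1e-8), 4000)
  expect_equal(got$resistance_ohm, 100)
  expect_equal(got$capacitance_f, 1e-8)
  expect_true(got$capacitance_valid)

  res_only <- extract_series_rc(250 + 0i, 4000)
  expect_false(res_only$capacitance_valid)
  expect_true(is.na(res_only$capacitance_f))

  set.seed(7)
  n <- 1000
  R <- runif(n, 1, 1e4); C <- 10^runif(n, -9, -6); f <- 10^runif(n, 2, 5)
  z <- complex(real = R, imaginary = -1 / (2 * pi * f * C))
  rt <- extract_series_rc(z, f)
  expect_equal(rt$resistance_ohm, R)
  expect_equal(rt$capacitance_f, C)
})

test_that("electrode parameters are recovered from a clean cell-free reference", {
  truth <- electrode_parameters(cpe_magnitude_Q = 8e-6, cpe_exponent_n = 0.92,
                                solution_resistance_Rsol = 220)
  ref <- spectrum_tbl(well_impedance(default_grid, truth))
  fit <- fit_electrode_parameters(ref)
  expect_equal(fit$cpe_magnitude_Q, truth$cpe_magnitude_Q, tolerance = 1e-4)
  expect_equal(fit$cpe_exponent_n, truth$cpe_exponent_n, tolerance = 1e-4)
  expect_equal(fit$solution_resistance_Rsol, truth$solution_resistance_Rsol,
               tolerance = 1e-4)
})

test_that("noiseless spectra return the generating barrier parameters", {
  el <- electrode_parameters()
  for (p in list(c(4, 8, 1.5), c(0.5, 8, 1.5), c(15, 3, 0.8))) {
    sp <- spectrum_tbl(well_impedance(default_grid, el,
                                      barrier_parameters(p[1], p[2], p[3])))
    fit <- fit_barrier_parameters(sp, electrode = el)
    expect_true(fit$converged)
    expect_equal(unname(fit$raw), p, tolerance = 1e-3)
    expect_true(fit$barrier$alpha_modelable && fit$barrier$cm_modelable)
  }
})

test_that("a cell-free spectrum is reported as the degenerate Rb = 0 case", {
  el <- electrode_parameters()
  ref <- spectrum_tbl(well_impedance(default_grid, el))
  fit <- fit_barrier_parameters(ref, electrode = el)
  expect_equal(fit$barrier$Rb, 0)
  expect_false(fit$barrier$alpha_modelable)
  expect_false(fit$barrier$cm_modelable)
})

test_that("the objective is invariant to overall impedance scaling", {
  el <- electrode_parameters()
  z <- well_impedance(default_grid, el, barrier_parameters(4, 8, 1.5))
  set.seed(11)
  z <- z * (1 + complex(real = rnorm(9), imaginary = rnorm(9)) * 0.007)
  f1 <- fit_barrier_parameters(spectrum_tbl(z), electrode = el)
  # a well whose every impedance is 10x larger: area /10, series R x10
  el10 <- electrode_parameters(cpe_magnitude_Q = el$cpe_magnitude_Q,
                               cpe_exponent_n = el$cpe_exponent_n,
                               solution_resistance_Rsol = 10 * el$solution_resistance_Rsol,
                               electrode_area_A = el$electrode_area_A / 10)
  f2 <- fit_barrier_parameters(spectrum_tbl(z * 10), electrode = el10)
  expect_equal(f1$residual_norm, f2$residual_norm, tolerance = 1e-8)
  expect_equal(f1$raw, f2$raw, tolerance = 1e-6)
})

test_that("fits refuse fewer than four usable frequencies", {
  el <- electrode_parameters()
  sp <- spectrum_tbl(well_impedance(default_grid, el, confluent_barrier()))
  expect_error(fit_barrier_parameters(sp[1:3, ], electrode = el), "4 usable")
})

test_that("an all-zero signal yields failed timepoints rather than aborting", {
  rec <- tidyr::expand_grid(time_h = c(0, 1), well = "w1", group = "g",
                            frequency_hz = default_grid) |>
    dplyr::mutate(z_real_ohm = 0, z_imag_ohm = 0)
  out <- deconvolve_timecourse(rec, electrode = electrode_parameters())
  expect_true(all(!out$converged))
  expect_true(all(is.na(out$rb)))
  expect_true(all(!out$alpha_modelable & !out$cm_modelable))
})

test_that("timecourse deconvolution tracks a noiseless synthetic well", {
  cfg <- tiny_config(noise_fraction = 0)
  exp <- simulate_experiment(cfg, seed = 3)
  sub <- dplyr::filter(exp$impedance, well %in% c("d0_w1", "cf_w1", "cf_w2"))
  dec <- deconvolve_timecourse(sub)
  post <- dplyr::filter(dec, time_h >= 0)
  truth <- dplyr::filter(exp$ground_truth, well == "d0_w1", time_h >= 0)
  expect_equal(post$rb, truth$rb, tolerance = 1e-3)
  expect_equal(post$alpha, truth$alpha, tolerance = 1e-3)
  expect_equal(post$cm, truth$cm, tolerance = 1e-3)
  expect_true(all(post$alpha_modelable))
})

test_that("whenever reported Rb is zero both modelability flags are false", {
  cfg <- tiny_config()
  exp <- simulate_experiment(cfg, seed = 5)
  dec <- deconvolve_timecourse(exp$impedance)
  zero <- dplyr::filter(dec, !is.na(rb), rb == 0)
  expect_gt(nrow(zero), 0)
  expect_true(all(!zero$alpha_modelable))
  expect_true(all(!zero$cm_modelable))
})

test_that("tidy and glance summarise a barrier fit", {
  el <- electrode_parameters()
  fit <- fit_barrier_parameters(
    spectrum_tbl(well_impedance(default_grid, el, confluent_barrier())),
    electrode = el)
  td <- tidy(fit)
  expect_equal(td$term, c("Rb", "alpha", "Cm"))
  expect_equal(td$estimate, c(3, 12, 1.5), tolerance = 1e-3)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n_frequencies_used, 9L)
})
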