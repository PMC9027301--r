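test_that("CPE interface reduces to a capacitor at n = 1 and a resistor as n -> 0", {
  f <- c(250, 4000, 64000)
  cap <- electrode_parameters(cpe_magnitude_Q = 1e-6, cpe_exponent_n = 1)
  expect_equal(cpe_interface_impedance(f, cap), 1 / (2i * pi * f * 1e-6))

  res <- electrode_parameters(cpe_magnitude_Q = 0.01, cpe_exponent_n = 1e-9)
  z <- cpe_interface_impedance(f, res)
  expect_equal(Re(z), rep(100, 3), tolerance = 1e-6)
  expect_equal(Im(z), rep(0, 3), tolerance = 1e-4)
})

test_that("CPE value matches arbitrary-precision evaluation of the same formula", {
  # frozen from a 50-digit evaluation of 1/(Q (i 2 pi f)^n), Q=2e-5, n=0.9, f=4000
  el <- electrode_parameters(cpe_magnitude_Q = 2e-5, cpe_exponent_n = 0.9)
  z <- cpe_interface_impedance(4000, el)
  expect_equal(Re(z), 0.85720870361792169, tolerance = 1e-14)
  expect_equal(Im(z), -5.4122027508602832, tolerance = 1e-14)
  expect_true(all(Re(z) >= 0) && all(Im(z) <= 0))
})

test_that("membrane impedance is purely capacitive with 1/f scaling", {
  z1 <- membrane_impedance(4000, Cm = 1)
  expect_equal(Re(z1), 0)
  expect_equal(abs(z1), 2 / (2 * pi * 4000 * 1e-6))
  expect_equal(abs(membrane_impedance(8000, Cm = 1)), abs(z1) / 2)
  # infinite capacitance is a short
  expect_lt(abs(membrane_impedance(4000, Cm = 1e9)), 1e-6)
})

test_that("domain errors are raised for non-physical inputs", {
  expect_error(cpe_interface_impedance(0, electrode_parameters()), "> 0")
  expect_error(membrane_impedance(4000, Cm = 0), "> 0")
  expect_error(membrane_impedance(-1, Cm = 1), "> 0")
  expect_error(bessel_ratio(0), "nonzero")
  expect_error(electrode_parameters(cpe_exponent_n = 1.5), "0, 1")
  expect_error(barrier_parameters(-1, 8, 1.5), ">= 0")
})

test_that("bessel ratio has the correct small- and large-argument limits", {
  for (x in c(1e-6, 1e-6 * (1 + 1i) / sqrt(2), 1e-5i + 1e-5)) {
    expect_equal(x * bessel_ratio(x), 2 + 0i, tolerance = 1e-10)
  }
  for (x in c(1e5, 1e5 * (1 + 1i) / sqrt(2), 1e6)) {
    expect_equal(bessel_ratio(x), 1 + 0i, tolerance = 1e-4)
  }
  # frozen 50-digit series value of I0(1)/I1(1)
  expect_equal(bessel_ratio(1), 2.2401937238700897411 + 0i, tolerance = 1e-14)
})

test_that("bessel ratio agrees with the arbitrary-precision oracle to 1e-10", {
  oracle <- utils::read.csv(test_path("bessel-ratio-oracle.csv"))
  x <- complex(real = oracle$x_re, imaginary = oracle$x_im)
  expected <- complex(real = oracle$ratio_re, imaginary = oracle$ratio_im)
  got <- bessel_ratio(x)
  rel <- abs(got - expected) / abs(expected)
  expect_lt(max(rel), 1e-10)
})

test_that("cell-covered impedance collapses to the cell-free interface at Rb = alpha = 0", {
  el <- electrode_parameters()
  bar <- barrier_parameters(Rb = 0, alpha = 0, Cm = 1.5)
  expect_equal(cell_covered_impedance(default_grid, el, bar),
               cpe_interface_impedance(default_grid, el))
  # and the degenerate barrier forces the modelability flags off
  expect_false(bar$alpha_modelable)
  expect_false(bar$cm_modelable)
})

test_that("infinite paracellular resistance forces all current transcellular", {
  el <- electrode_parameters()
  bar <- barrier_parameters(Rb = 1e9, alpha = 8, Cm = 1.5)
  zc <- cell_covered_impedance(default_grid, el, bar)
  series <- cpe_interface_impedance(default_grid, el) +
    membrane_impedance(default_grid, 1.5)
  expect_lt(max(abs(zc - series) / abs(series)), 1e-6)
})

test_that("cell-covered impedance matches an independent high-precision transcription", {
  # frozen from a 50-digit mpmath transcription of the same current-spreading
  # formula at Rb=4, alpha=8, Cm=1.5, f=4000, Q=4e-6, n=0.9
  el <- electrode_parameters()
  zc <- cell_covered_impedance(4000, el, barrier_parameters(4, 8, 1.5))
  expect_equal(Re(zc), 14.988157912395621, tolerance = 1e-12)
  expect_equal(Im(zc), -30.412198538946581, tolerance = 1e-12)
})

test_that("well impedance maps specific impedance through area and series resistance", {
  el <- electrode_parameters(solution_resistance_Rsol = 0)
  expect_equal(well_impedance(default_grid, el),
               cpe_interface_impedance(default_grid, el) / el$electrode_area_A)
  bar0 <- barrier_parameters(0, 0, 1.5)
  expect_equal(well_impedance(default_grid, el, bar0),
               well_impedance(default_grid, el))
})

test_that("cells never lower the well impedance magnitude and Rb effect is monotone", {
  el <- electrode_parameters()
  zf <- well_impedance(default_grid, el)
  for (rb in c(0, 0.5, 2, 6, 50)) {
    for (al in c(0, 2, 8, 20)) {
      zc <- well_impedance(default_grid, el, barrier_parameters(rb, al, 1.5))
      expect_true(all(abs(zc) >= abs(zf) * (1 - 1e-12)))
    }
  }
  mags <- vapply(c(0, 0.5, 1, 2, 4, 8, 16, 64), function(rb)
    abs(cell_covered_impedance(4000, el, barrier_parameters(rb, 8, 1.5))),
    numeric(1))
  expect_true(all(diff(mags) >= 0))
})
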