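test_that("identical groups give unit ratio spectra", {
  el <- electrode_parameters()
  z <- well_impedance(default_grid, el, confluent_barrier())
  a <- records_at(z, "cells", "w1")
  b <- records_at(z, "free", "cf1")
  for (q in c("impedance_magnitude", "resistance", "capacitance")) {
    sp <- ratio_spectrum(a, b, q)
    expect_equal(sp$ratio, rep(1, 9))
  }
})

test_that("confluent-monolayer capacitance ratios fall below one at high frequency", {
  fx <- forward_spectra()
  sp <- ratio_spectrum(records_at(complex(real = fx$cell$z_real_ohm,
                                          imaginary = fx$cell$z_imag_ohm),
                                  "cells", "w1"),
                       records_at(complex(real = fx$free$z_real_ohm,
                                          imaginary = fx$free$z_imag_ohm),
                                  "free", "cf1"),
                       "capacitance")
  high <- sp$ratio[sp$frequency_hz >= 16000]
  expect_true(all(high < 1))
})

test_that("frequency selection honours the extremum, low-frequency ties and permutation invariance", {
  spec <- tibble::tibble(frequency_hz = default_grid,
                         ratio = seq(1, 2, length.out = 9))
  expect_equal(select_frequency(spec, "maximize"), 64000)
  expect_equal(select_frequency(spec, "minimize"), 250)
  tie <- tibble::tibble(frequency_hz = c(250, 4000, 16000),
                        ratio = c(1, 2, 2))
  expect_equal(select_frequency(tie, "maximize"), 4000)
  shuffled <- tie[c(3, 1, 2), ]
  expect_equal(select_frequency(shuffled, "maximize"), 4000)
})

test_that("normalisation pins the treatment timepoint at 1 (0 on log scale) and is idempotent", {
  tr <- tibble::tibble(time_h = 0:5, value = c(4, 5, 6, 5, 3, 2))
  n1 <- normalize_trace(tr)
  expect_equal(n1$value[1], 1)
  expect_equal(normalize_trace(tr, log_scale = TRUE)$value[1], 0)
  expect_equal(normalize_trace(n1), n1)
  # constant trace normalises to all ones
  expect_equal(normalize_trace(tibble::tibble(time_h = 0:3, value = rep(7, 4)))$value,
               rep(1, 4))
  expect_error(normalize_trace(tibble::tibble(time_h = 0:1, value = c(0, 1))),
               "zero")
  expect_error(normalize_trace(tibble::tibble(time_h = 1:2, value = c(1, 2))),
               "time grid")
})

test_that("grouped normalisation is applied per trace", {
  tr <- tidyr::expand_grid(well = c("a", "b"), time_h = 0:2) |>
    dplyr::mutate(value = ifelse(well == "a", 2, 8) * (time_h + 1))
  out <- tr |> dplyr::group_by(well) |> normalize_trace() |> dplyr::ungroup()
  expect_equal(out$value, rep(c(1, 2, 3), 2))
})

test_that("trapezoid AUC is exact on constants and linear ramps and additive over windows", {
  const <- tibble::tibble(time_h = seq(0, 25, by = 0.5), value = 1)
  expect_equal(area_under_curve(const)$auc, 25)
  ramp <- tibble::tibble(time_h = c(0, 0.3, 1), value = c(0, 0.3, 1))
  expect_equal(area_under_curve(ramp, t_start = 0, t_end = 1)$auc, 0.5)
  # additivity at an off-grid split, to machine precision
  set.seed(2)
  tr <- tibble::tibble(time_h = sort(runif(40, 0, 25)), value = rnorm(40))
  whole <- area_under_curve(tr, t_start = tr$time_h[1], t_end = 25 * 0.9)$auc
  left <- area_under_curve(tr, t_start = tr$time_h[1], t_end = 13.37)$auc
  right <- area_under_curve(tr, t_start = 13.37, t_end = 25 * 0.9)$auc
  expect_equal(left + right, whole, tolerance = 1e-12)
  expect_error(area_under_curve(const, t_start = -1, t_end = 10), "support")
})

test_that("the confluency gate is strict at 20 nF and requires a sustained dwell", {
  never <- tibble::tibble(time_h = 0:10, capacitance_f = rep(30e-9, 11))
  expect_true(is.na(confluency_gate(never)))
  # a step exactly onto the threshold does not qualify
  at <- tibble::tibble(time_h = 0:10,
                       capacitance_f = c(rep(30e-9, 5), rep(20e-9, 6)))
  expect_true(is.na(confluency_gate(at)))
  below <- tibble::tibble(time_h = 0:10,
                          capacitance_f = c(rep(30e-9, 5), rep(19e-9, 6)))
  expect_equal(confluency_gate(below), 5)
  # a transient dip shorter than the dwell is ignored
  blip <- tibble::tibble(time_h = seq(0, 10, by = 0.25),
                         capacitance_f = 30e-9)
  blip$capacitance_f[blip$time_h >= 2 & blip$time_h < 2.5] <- 15e-9
  blip$capacitance_f[blip$time_h >= 6] <- 15e-9
  expect_equal(confluency_gate(blip), 6)
})

test_that("star annotation uses the four inclusive thresholds", {
  expect_equal(p_stars(c(1e-4, 1e-3, 0.01, 0.05)),
               c("****", "***", "**", "*"))
  expect_equal(p_stars(c(1.0001e-4, 1.0001e-3, 0.010001, 0.050001)),
               c("***", "**", "*", "ns"))
  expect_equal(p_stars(c(0.5, 1)), c("ns", "ns"))
})

test_that("ANOVA matches a hand-computed textbook fixture and exposes Tukey contrasts", {
  # 3 groups, n = 5 each, computed by the standard sum-of-squares formulas
  g1 <- c(6, 8, 4, 5, 3); g2 <- c(8, 12, 9, 11, 6); g3 <- c(13, 9, 11, 8, 7)
  dat <- tibble::tibble(value = c(g1, g2, g3),
                        group = rep(c("a", "b", "c"), each = 5))
  grand <- mean(dat$value)
  ss_between <- 5 * sum((tapply(dat$value, dat$group, mean) - grand)^2)
  ss_within <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  f_hand <- (ss_between / 2) / (ss_within / 12)
  cmp <- compare_groups(dat, design = "endpoint")
  expect_equal(glance(cmp)$statistic, f_hand, tolerance = 1e-12)
  td <- tidy(cmp)
  expect_equal(nrow(td), 3)
  expect_true(all(td$p_adj >= 0 & td$p_adj <= 1))
})

test_that("identical groups compare as no difference and two groups get a t-test", {
  same <- tibble::tibble(value = rep(5, 12), group = rep(c("a", "b", "c"), 4))
  cmp <- compare_groups(same)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$stars, "ns")
  expect_true(all(tidy(cmp)$stars == "ns"))

  set.seed(9)
  two <- tibble::tibble(value = c(rnorm(6), rnorm(6, 5)),
                        group = rep(c("a", "b"), each = 6))
  cmp2 <- compare_groups(two)
  expect_false(is.null(cmp2$t_test))
  expect_lt(cmp2$t_test$p_value, 0.001)
  expect_error(compare_groups(tibble::tibble(value = 1:3, group = "a")),
               "2 groups")
})

test_that("plateau timing finds the first arrival at the trailing-window level", {
  tr <- tibble::tibble(time_h = seq(0, 25, by = 0.5),
                       value = pmax(exp(-seq(0, 25, by = 0.5)), 0.4))
  # decays to 0.4 by t = -log(0.4) ~ 0.92; within 1% slightly earlier
  expect_lt(abs(time_to_plateau(tr) - 1), 0.6)
  flat <- tibble::tibble(time_h = 0:10, value = rep(2, 11))
  expect_equal(time_to_plateau(flat), 0)
})
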