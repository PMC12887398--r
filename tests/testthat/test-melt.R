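# Two-state melt model, derivative and fit Tm, dose-dependent amplitudes.

test_that("van't Hoff unfolded fraction: midpoint, sharp limit, hand values", {
  expect_equal(unfolded_fraction(71.5, 71.5, 50), 0.5, tolerance = 1e-12)
  # frozen hand evaluations of the logistic in 1/T at Tm +/- 10 C,
  # dH = 50 kcal/mol
  expect_equal(unfolded_fraction(61.5, 71.5, 50), 0.1014226911,
               tolerance = 1e-8)
  expect_equal(unfolded_fraction(81.5, 71.5, 50), 0.8868029105,
               tolerance = 1e-8)
  # dH -> infinity approaches a step at Tm
  expect_lt(unfolded_fraction(70.5, 71.5, 5000), 1e-3)
  expect_gt(unfolded_fraction(72.5, 71.5, 5000), 1 - 1e-3)
})

test_that("derivative Tm finds the true midpoint on noiseless curves", {
  for (tm in c(55, 71.5, 80)) {
    cu <- gen_melt(melt_truth(tm = tm), seq(25, 95, 1), noise_spec(0, 1))
    d <- derivative_tm(cu)
    expect_false(d$no_transition)
    expect_equal(d$tm, tm, tolerance = 1)  # within one grid step
  }
})

test_that("monotone signals are reported as having no transition", {
  temps <- seq(25, 95, 1)
  lin <- melt_curve(temps, 500 - 2 * temps)
  d <- derivative_tm(lin)
  expect_true(d$no_transition)
  expect_true(is.na(d$tm))
  # quench-dominated scan of a fully remodeled probe, with read noise
  qt <- melt_truth(quench_slope = 0.004)
  cu <- gen_melt(qt, temps, noise_spec(1, 4), amplitude_scale = 0)
  expect_true(derivative_tm(cu)$no_transition)
})

test_that("the derivative extremum location is amplitude-invariant", {
  temps <- seq(25, 95, 1)
  mt <- melt_truth()
  full <- derivative_tm(gen_melt(mt, temps, noise_spec(0, 1)))
  scaled <- derivative_tm(gen_melt(mt, temps, noise_spec(0, 1),
                                   amplitude_scale = 0.35))
  expect_equal(full$tm, scaled$tm, tolerance = 0.2)
})

test_that("fit-based and derivative-based Tm agree on noiseless curves", {
  temps <- seq(25, 95, 1)
  for (tm in c(60, 71.5)) {
    cu <- gen_melt(melt_truth(tm = tm, quench_slope = 0.001), temps,
                   noise_spec(0, 1))
    f <- fit_melt(cu)
    expect_true(f$converged)
    expect_equal(f$tm, tm, tolerance = 0.05)
    expect_equal(f$tm, f$tm_derivative, tolerance = 1)
    expect_equal(f$dh_vh, 50, tolerance = 0.05)
  }
})

test_that("Tm recovery is unbiased over noisy replicates", {
  temps <- seq(25, 95, 1)
  mt <- melt_truth()
  amp <- 207  # unfolded-minus-folded baseline gap at Tm for the defaults
  tms <- vapply(1:100, function(i)
    derivative_tm(gen_melt(mt, temps, noise_spec(0.02 * amp, i)))$tm,
    numeric(1))
  expect_lt(abs(median(tms, na.rm = TRUE) - 71.5), 3.5)
})

test_that("fitted amplitudes are invariant to the baseline slopes", {
  temps <- seq(25, 95, 1)
  a <- fit_melt(gen_melt(melt_truth(), temps, noise_spec(0, 1)))
  steep <- melt_truth(baseline_folded = c(100, 0.8),
                      baseline_unfolded = c(300, 0.9))
  b <- fit_melt(gen_melt(steep, temps, noise_spec(0, 1)))
  expect_equal(a$amplitude, b$amplitude, tolerance = 0.02)
})

test_that("transition amplitudes track the free-hairpin fraction 1 - fb", {
  temps <- seq(25, 95, 1)
  mt <- melt_truth(quench_slope = 0.001)
  kd <- 23.7; probe <- 40
  doses <- c(0, 10, 20, 40, 80)
  scales <- 1 - fraction_bound(doses, probe, kd)
  curves <- lapply(seq_along(doses), function(i)
    gen_melt(mt, temps, noise_spec(0, 1), amplitude_scale = scales[i]))
  out <- amplitude_vs_dose(curves, doses, kd, probe)
  expect_equal(out$table$rel_amplitude[1], 1)
  expect_lt(out$rms, 0.02)

  # dose far above Kd: amplitude nearly gone (the no-transition regime)
  tight <- 1  # nM
  sat_scales <- 1 - fraction_bound(doses, probe, tight)
  sat_curves <- lapply(seq_along(doses), function(i)
    gen_melt(mt, temps, noise_spec(0, 1), amplitude_scale = sat_scales[i]))
  sat <- amplitude_vs_dose(sat_curves, doses, tight, probe)
  expect_lt(sat$table$rel_amplitude[doses == 80], 0.05)
  # mismatched grids are rejected
  bad <- c(curves[-1], list(gen_melt(mt, seq(20, 90, 1), noise_spec(0, 1))))
  expect_error(amplitude_vs_dose(bad, doses, kd, probe), "share")
})

test_that("degenerate melt inputs are rejected", {
  expect_error(melt_curve(numeric(0), numeric(0)), "empty")
  expect_error(melt_curve(c(25, 25, 26), c(1, 2, 3)), "strictly increasing")
  expect_error(derivative_tm(melt_curve(25:32, rnorm(8)), smooth_window = 5),
               "at least")
  expect_error(melt_truth(dh_vh = -5), "positive")
})
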