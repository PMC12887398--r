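# Seeded generators: determinism, exact model placement at sd = 0, and the
# structural contrast between the closed and open hairpin builds.

test_that("generators are pure functions of (arguments, seed)", {
  truth <- binding_truth(23.7, 40, 0.079, 0.055)
  g <- titrant_grid(23.7)
  a <- gen_titration(truth, g, noise_spec(0.002, 7))
  b <- gen_titration(truth, g, noise_spec(0.002, 7))
  c <- gen_titration(truth, g, noise_spec(0.002, 8))
  expect_identical(a$observables, b$observables)
  expect_false(identical(a$observables, c$observables))

  mt <- melt_truth()
  m1 <- gen_melt(mt, seq(25, 95, 1), noise_spec(2, 3))
  m2 <- gen_melt(mt, seq(25, 95, 1), noise_spec(2, 3))
  expect_identical(m1$signal, m2$signal)

  t1 <- gen_shift_tables(shift_perturbation_spec(), gen_apo_shift_table(),
                         noise_spec(0.002, 5))
  t2 <- gen_shift_tables(shift_perturbation_spec(), gen_apo_shift_table(),
                         noise_spec(0.002, 5))
  expect_identical(t1[[3]]$dH_ppm, t2[[3]]$dH_ppm)
})

test_that("sd = 0 titrations lie exactly on the depletion model curve", {
  truth <- binding_truth(23.7, 40, 0.079, 0.055)
  g <- titrant_grid(23.7)
  s <- gen_titration(truth, g, noise_spec(0, 1))
  expect_equal(s$observables, predict_observable(truth, g), tolerance = 1e-15)
  # zero-titrant endpoint is the free-probe observable, 0.079 for the
  # folded hairpin probe
  expect_identical(s$observables[1], 0.079)
  one <- gen_titration(truth, 0, noise_spec(0, 1))
  expect_identical(one$observables, 0.079)
})

test_that("titrations at titrant >> Kd saturate within 1% of the range", {
  truth <- binding_truth(23.7, 40, 0.079, 0.055)
  s <- gen_titration(truth, c(0, 23.7 * 1000), noise_spec(0, 1))
  expect_lt(abs(s$observables[2] - 0.055), 0.01 * abs(0.079 - 0.055))
})

test_that("Pt = Lt = Kd point sits at the closed-form bound fraction", {
  truth <- binding_truth(40, 40, 0.1, 0.2)
  s <- gen_titration(truth, 40, noise_spec(0, 1))
  expect_equal(s$observables, 0.1 + (3 - sqrt(5)) / 2 * 0.1,
               tolerance = 1e-9)
})

test_that("melt generator: midpoint, quench-dominated regime, amplitude scaling", {
  mt <- melt_truth(tm = 71.5, dh_vh = 50)
  expect_equal(unfolded_fraction(71.5, 71.5, 50), 0.5, tolerance = 1e-12)

  # saturated-probe regime: no transition amplitude, positive quench ->
  # monotonically decreasing signal
  qt <- melt_truth(quench_slope = 0.004)
  cu <- gen_melt(qt, seq(25, 95, 1), noise_spec(0, 1), amplitude_scale = 0)
  expect_true(all(diff(cu$signal) < 0))

  # amplitude scaling round-trips through the melt fit
  full <- gen_melt(mt, seq(25, 95, 1), noise_spec(0, 1))
  half <- gen_melt(mt, seq(25, 95, 1), noise_spec(0, 1),
                   amplitude_scale = 0.5)
  af <- fit_melt(full)$amplitude
  ah <- fit_melt(half)$amplitude
  expect_equal(ah / af, 0.5, tolerance = 1e-3)
})

test_that("shift generator saturates to the bound shifts and nulls cleanly", {
  apo <- gen_apo_shift_table()
  spec <- shift_perturbation_spec(ratios = c(1, 1e5), kd = 1e-6)
  tabs <- gen_shift_tables(spec, apo, noise_spec(0, 1))
  sat <- tabs[[3]]
  i <- match(spec$perturbed_residues, apo$residue_id)
  expect_equal(sat$dH_ppm[i], apo$dH_ppm[i] + spec$dh_bound, tolerance = 1e-4)
  expect_equal(sat$dN_ppm[i], apo$dN_ppm[i] + spec$dn_bound, tolerance = 1e-4)

  null <- shift_perturbation_spec(dh_bound = rep(0, 5), dn_bound = rep(0, 5))
  ntabs <- gen_shift_tables(null, apo, noise_spec(0, 1))
  for (t in ntabs[-1]) expect_equal(t$dH_ppm, apo$dH_ppm, tolerance = 1e-15)

  bad <- shift_perturbation_spec(perturbed_residues = c(84, 999),
                                 dh_bound = c(0.1, 0.1),
                                 dn_bound = c(1, 1))
  expect_error(gen_shift_tables(bad, apo, noise_spec(0, 1)), "absent")
})

test_that("closed and open conformers have the designed structural contrast", {
  closed <- gen_hairpin_conformer("closed")
  open <- gen_hairpin_conformer("open")
  expect_error(gen_hairpin_conformer("half-open"))

  # stem contacts: paired base centroids sit at 3 A in the closed build
  expect_equal(base_pair_distances(closed), rep(3, 4), tolerance = 1e-12)
  # terminal groups separate by > 15 A in the open build
  expect_true(all(base_pair_distances(open) > 15))

  cn_c <- coordination_number(closed)
  cn_o <- coordination_number(open)
  expect_gte(cn_c / cn_o, 10)

  expect_gt(kabsch_rmsd(open, closed), 5)
  expect_equal(kabsch_rmsd(closed, closed), 0, tolerance = 1e-12)
})
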