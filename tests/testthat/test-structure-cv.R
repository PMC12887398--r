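# Kabsch RMSD, switching function, coordination number, base-pair
# distances, and their rigid-motion invariance.

test_that("Kabsch RMSD: identity and rigid-motion invariance", {
  closed <- gen_hairpin_conformer("closed")
  expect_equal(kabsch_rmsd(closed, closed), 0, tolerance = 1e-12)
  for (seed in 1:5) {
    moved <- transform_conformer(closed, random_rotation(seed),
                                 c(5, -3, 11) * seed)
    expect_lt(kabsch_rmsd(moved, closed), 1e-8)
  }
})

test_that("Kabsch RMSD matches the Euler-grid oracle on a 3-atom toy", {
  set.seed(9)
  P <- matrix(rnorm(9, sd = 2), 3)
  Q <- matrix(rnorm(9, sd = 2), 3)
  mk <- function(m) conformer(data.frame(
    atom = "P", resid = 1:3, element = "P", x = m[, 1], y = m[, 2],
    z = m[, 3]))
  got <- kabsch_rmsd(mk(P), mk(Q), selection = "P")
  expect_equal(got, rmsd_grid_oracle(P, Q), tolerance = 1e-3)
})

test_that("mismatched selections are rejected", {
  closed <- gen_hairpin_conformer("closed")
  clipped <- closed
  clipped$atoms <- clipped$atoms[-1, ]
  expect_error(kabsch_rmsd(clipped, closed), "one-to-one")
})

test_that("switching function limits and closed-form values", {
  expect_equal(switching_value(0, d0 = 0, r0 = 3), 1)
  expect_equal(switching_value(2, d0 = 2, r0 = 3), 1)  # contact limit r = d0
  # removable singularity at r = d0 + r0: L'Hopital limit 1/2
  expect_equal(switching_value(3, d0 = 0, r0 = 3), 0.5, tolerance = 1e-14)
  expect_equal(switching_value(5, d0 = 2, r0 = 3), 0.5, tolerance = 1e-14)
  # direct evaluation 63/4095 = 1/65 at twice the cutoff
  expect_equal(switching_value(6, d0 = 0, r0 = 3), 1 / 65,
               tolerance = 1e-14)
  expect_error(switching_value(1, r0 = -1), "positive")
})

test_that("switching function is continuous and strictly decreasing", {
  r <- seq(0.01, 12, by = 0.001)
  v <- switching_value(r, d0 = 0, r0 = 3)
  expect_true(all(diff(v) < 0))
  # dense sampling across the x = 1 point
  near <- switching_value(3 + seq(-1e-6, 1e-6, length.out = 401), 0, 3)
  expect_lt(max(abs(diff(near))), 1e-6)
  # general-exponent branch agrees with the simplified 6/12 form
  expect_equal(switching_value(4.4, 0.5, 3, n = 6, m = 12),
               1 / (1 + ((4.4 - 0.5) / 3)^6), tolerance = 1e-12)
})

test_that("coordination number equals the double-loop oracle exactly", {
  for (state in c("closed", "open")) {
    conf <- gen_hairpin_conformer(state)
    expect_equal(coordination_number(conf), cn_loop(conf), tolerance = 1e-12)
    expect_equal(coordination_number(conf, atom_names = "BC"),
                 cn_loop(conf, atom_names = "BC"), tolerance = 1e-12)
  }
})

test_that("coordination number: two-atom contact, additivity, group checks", {
  two <- conformer(data.frame(atom = "BC", resid = c(1, 15),
                              element = "C", x = c(0, 3), y = 0, z = 0))
  expect_equal(coordination_number(two, 1, 15, d0 = 3, r0 = 3), 1)

  closed <- gen_hairpin_conformer("closed")
  whole <- coordination_number(closed, 1:4, 12:15)
  parts <- coordination_number(closed, 1:4, 12:13) +
    coordination_number(closed, 1:4, 14:15)
  expect_equal(whole, parts, tolerance = 1e-12)

  expect_error(coordination_number(closed, 1:4, 4:8), "disjoint")
  expect_error(coordination_number(closed, integer(0), 12:15), "nonempty")
})

test_that("all observables are invariant under global rigid motion", {
  closed <- gen_hairpin_conformer("closed")
  moved <- transform_conformer(closed, random_rotation(4), c(-20, 7, 3))
  expect_equal(coordination_number(moved), coordination_number(closed),
               tolerance = 1e-10)
  expect_equal(base_pair_distances(moved), base_pair_distances(closed),
               tolerance = 1e-10)
})

test_that("base-pair distances: construction, ordering, equivariance", {
  closed <- gen_hairpin_conformer("closed")
  open <- gen_hairpin_conformer("open")
  expect_equal(base_pair_distances(closed), rep(3, 4), tolerance = 1e-12)
  expect_true(all(base_pair_distances(open) > base_pair_distances(closed)))
  p <- default_pairing()
  perm <- p[c(3, 1, 4, 2), ]
  expect_equal(base_pair_distances(closed, perm),
               base_pair_distances(closed)[c(3, 1, 4, 2)])
  expect_error(base_pair_distances(closed, cbind(1, 16)), "1..15")
})

test_that("kabsch agrees with an independent library superposition", {
  closed <- gen_hairpin_conformer("closed")
  open <- gen_hairpin_conformer("open")
  sel <- closed$atoms$atom %in% rna_backbone_atoms()
  ord <- order(closed$atoms$resid[sel], closed$atoms$atom[sel])
  fix <- as.vector(t(as.matrix(closed$atoms[sel, c("x", "y", "z")][ord, ])))
  mob <- as.vector(t(as.matrix(open$atoms[sel, c("x", "y", "z")][ord, ])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fix, mob))
  ref <- sqrt(mean(colSums(matrix((fitted - fix)^2, nrow = 3))))
  expect_equal(kabsch_rmsd(open, closed), ref, tolerance = 1e-6)
})

test_that("cv_series evaluates both collective variables per frame", {
  closed <- gen_hairpin_conformer("closed")
  open <- gen_hairpin_conformer("open")
  cv <- compute_cv_series(list(closed, open), closed)
  expect_equal(cv$rmsd[1], 0, tolerance = 1e-12)
  expect_gt(cv$rmsd[2], 5)
  expect_gt(cv$cn[1] / cv$cn[2], 10)
})
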