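# FES reconstruction, basin detection, and free-energy gaps.

# analytic two-well surface built directly as an fes object
make_double_well_fes <- function(depth1 = 5, depth2 = 8,
                                 c1 = c(2, 20), c2 = c(8, 80),
                                 n = c(101, 101)) {
  cv1 <- seq(0, 10, length.out = n[1])
  cv2 <- seq(0, 100, length.out = n[2])
  F <- outer(cv1, cv2, function(x, y)
    -depth1 * exp(-((x - c1[1])^2 / 2 + (y - c1[2])^2 / 200)) -
      depth2 * exp(-((x - c2[1])^2 / 2 + (y - c2[2])^2 / 200)))
  structure(list(cv1 = cv1, cv2 = cv2, F_kcal = F - min(F), gamma = 15),
            class = "fes_grid_2d")
}

test_that("sum_hills reproduces a single Gaussian analytically", {
  h <- hills_log(0.2, 1.5, 40, 0.5, 10, 0.8, 15)
  g <- list(cv1 = seq(-1, 4, length.out = 41),
            cv2 = seq(0, 80, length.out = 41))
  V <- sum_hills(h, g)
  truth <- outer(g$cv1, g$cv2, function(x, y)
    0.8 * exp(-(x - 1.5)^2 / (2 * 0.25) - (y - 40)^2 / (2 * 100)))
  expect_equal(unclass(V), truth, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("sum_hills: empty log, linearity over concatenated logs, oracle", {
  g <- list(cv1 = seq(0, 10, length.out = 31),
            cv2 = seq(0, 100, length.out = 31))
  empty <- hills_log(numeric(0), numeric(0), numeric(0), numeric(0),
                     numeric(0), numeric(0), numeric(0))
  expect_true(all(sum_hills(empty, g) == 0))

  pot <- hairpin_landscape()
  run <- run_wt_metadynamics(pot, n_steps = 3e4, seed = 2)
  h <- run$hills
  h1 <- h[1:100, ]; h2 <- h[101:nrow(h), ]
  class(h1) <- class(h2) <- class(h)
  expect_equal(sum_hills(h, g), sum_hills(h1, g) + sum_hills(h2, g),
               tolerance = 1e-12, ignore_attr = TRUE)

  # node-wise agreement with the direct per-point bias sum
  pts <- as.matrix(expand.grid(g$cv1[c(3, 17, 29)], g$cv2[c(5, 16, 30)]))
  V <- sum_hills(h, g)
  for (i in seq_len(nrow(pts))) {
    a <- which(g$cv1 == pts[i, 1]); b <- which(g$cv2 == pts[i, 2])
    expect_equal(V[a, b], evaluate_bias(pts[i, ], h), tolerance = 1e-10)
  }
})

test_that("a too-coarse grid records a resolution warning", {
  h <- hills_log(0.2, 5, 50, 0.5, 10, 1, 15)
  coarse <- list(cv1 = seq(0, 10, length.out = 5),
                 cv2 = seq(0, 100, length.out = 5))
  expect_false(is.null(attr(sum_hills(h, coarse), "coarse_warning")))
  fine <- list(cv1 = seq(0, 10, length.out = 101),
               cv2 = seq(0, 100, length.out = 101))
  expect_null(attr(sum_hills(h, fine), "coarse_warning"))
})

test_that("bias_to_fes: constant bias, single-hill depth, gamma limits", {
  g <- list(cv1 = seq(0, 1, length.out = 11),
            cv2 = seq(0, 1, length.out = 11))
  const <- matrix(7, 11, 11)
  f <- bias_to_fes(const, gamma = 15, cv1 = g$cv1, cv2 = g$cv2)
  expect_true(all(f$F_kcal == 0))

  # single hill of height h: well-tempered depth (gamma/(gamma-1)) h,
  # in kcal, relative to the far field
  h <- 0.9
  hl <- hills_log(0.2, 0.5, 0.5, 0.05, 0.05, h, 15)
  wide <- list(cv1 = seq(-3, 4, length.out = 141),
               cv2 = seq(-3, 4, length.out = 141))
  fes <- bias_to_fes(sum_hills(hl, wide), gamma = 15)
  depth <- max(fes$F_kcal) - min(fes$F_kcal)
  expect_equal(depth, (15 / 14) * h / 4.184, tolerance = 1e-6)

  # gamma -> Inf: standard metadynamics, F = -V after shift
  fi <- bias_to_fes(sum_hills(hl, wide), gamma = Inf)
  expect_equal(max(fi$F_kcal), h / 4.184, tolerance = 1e-6)
  expect_error(bias_to_fes(const, gamma = 1), "exceed 1")
})

test_that("FES shape is invariant to a constant added to the bias", {
  h <- hills_log(0.2, 5, 50, 1, 10, 1, 15)
  g <- list(cv1 = seq(0, 10, length.out = 51),
            cv2 = seq(0, 100, length.out = 51))
  V <- sum_hills(h, g)
  f1 <- bias_to_fes(V, 15)
  f2 <- bias_to_fes(V + 42, 15, cv1 = g$cv1, cv2 = g$cv2)
  expect_equal(f1$F_kcal, f2$F_kcal, tolerance = 1e-10)
})

test_that("basin detection on constructed surfaces", {
  fes <- make_double_well_fes()
  b <- find_basins(fes, min_barrier = 1)
  expect_length(b, 2)
  # minima at the constructed centers within one grid step
  locs <- sapply(b, function(x) c(x$cv1, x$cv2))
  expect_equal(sort(locs[1, ]), c(2, 8), tolerance = 0.11)
  expect_equal(sort(locs[2, ]), c(20, 80), tolerance = 1.1)

  # one paraboloid -> one basin
  cv <- seq(-5, 5, length.out = 61)
  para <- structure(list(cv1 = cv, cv2 = cv,
                         F_kcal = outer(cv^2, cv^2, "+") / 5, gamma = 15),
                    class = "fes_grid_2d")
  expect_length(find_basins(para, 1), 1)

  # merge threshold above the separating saddle collapses to one basin
  merged <- find_basins(fes, min_barrier = 20)
  expect_length(merged, 1)

  # monotone surface: no interior minimum
  tilt <- structure(list(cv1 = cv, cv2 = cv,
                         F_kcal = outer(cv, cv, function(x, y) x + 2 * y + 20),
                         gamma = 15),
                    class = "fes_grid_2d")
  expect_length(find_basins(tilt, 1), 0)
})

test_that("basin gaps: symmetric wells cancel, constructed gaps recover", {
  sym <- make_double_well_fes(depth1 = 6, depth2 = 6)
  bs <- find_basins(sym, 1)
  expect_equal(basin_delta_g(sym, bs)$delta_g, 0, tolerance = 1e-9)

  gap <- make_double_well_fes(depth1 = 5, depth2 = 8)
  bg <- find_basins(gap, 1)
  rep <- basin_delta_g(gap, bg)
  # hairpin convention: low-rmsd minimum minus high-rmsd minimum
  expect_equal(rep$delta_g, 3, tolerance = 0.05)
  expect_gt(rep$barrier, 0)
  # both conventions are reported
  expect_true(is.finite(rep$delta_g_integral))
  alt <- basin_delta_g(gap, bg, convention = "integral")
  expect_equal(alt$delta_g, alt$delta_g_integral)
})

test_that("end-to-end gap recovery across constructed landscapes", {
  # the sampled two-well landscape hands its constructed gap back through
  # sampling + reconstruction + basin analysis
  for (dg in c(2, 5, 9.86, 12, 15)) {
    pot <- hairpin_landscape(delta_g_kcal = dg)
    run <- run_wt_metadynamics(pot, n_steps = 1e6, seed = 40 + round(dg))
    grid <- list(cv1 = seq(pot$box[1], pot$box[2], length.out = 200),
                 cv2 = seq(pot$box[3], pot$box[4], length.out = 200))
    fes <- fes_from_hills(run$hills, grid = grid, tail_average = 10)
    b <- find_basins(fes)
    expect_gte(length(b), 2)
    got <- basin_delta_g(fes, b)$delta_g
    expect_lt(abs(got - dg), max(0.5, 0.07 * dg))
  }
})

test_that("the half-history diagnostic is small for a converged run", {
  pot <- hairpin_landscape()
  run <- run_wt_metadynamics(pot, n_steps = 1e6, seed = 1)
  grid <- list(cv1 = seq(pot$box[1], pot$box[2], length.out = 200),
               cv2 = seq(pot$box[3], pot$box[4], length.out = 200))
  cv <- fes_convergence(run$hills, grid = grid, tail_average = 10)
  expect_lt(cv$diag, 0.5)
  expect_equal(cv$delta_g_full, 9.86, tolerance = 0.1)
})
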