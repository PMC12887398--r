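# Well-tempered hill tempering, bias evaluation, and the Langevin sampler.

test_that("tempered hill heights: first hill, e-folding, saturation limit", {
  p <- metad_params()  # w0 = 1 kJ/mol, gamma = 15, 300 K
  expect_equal(wt_hill_height(0, p), 1)
  kb_dt <- 0.008314462618 * 14 * 300
  expect_equal(wt_hill_height(kb_dt, p), exp(-1), tolerance = 1e-12)
  v <- wt_hill_height(c(0, 10, 50, 200, 1000), p)
  expect_true(all(diff(v) < 0) && all(v > 0))
  expect_lt(wt_hill_height(1e4, p), 1e-100)
  expect_error(metad_params(bias_factor = 1), "exceed 1")
  expect_error(wt_hill_height(-1, p), "nonnegative")
})

test_that("evaluate_bias: empty log, single hill, linearity", {
  empty <- hills_log(numeric(0), numeric(0), numeric(0), numeric(0),
                     numeric(0), numeric(0), numeric(0))
  expect_equal(evaluate_bias(c(1, 2), empty), 0)
  one <- hills_log(0.2, 1.5, 40, 0.5, 10, 0.8, 15)
  expect_equal(evaluate_bias(c(1.5, 40), one), 0.8)
  two <- hills_log(c(0.2, 0.4), rep(1.5, 2), rep(40, 2), rep(0.5, 2),
                   rep(10, 2), rep(0.8, 2), rep(15, 2))
  grid <- as.matrix(expand.grid(seq(0, 3, 0.5), seq(20, 60, 10)))
  expect_equal(evaluate_bias(grid, two), 2 * evaluate_bias(grid, one),
               tolerance = 1e-14)
})

test_that("two runs with identical seeds produce identical hills logs", {
  pot <- hairpin_landscape()
  a <- run_wt_metadynamics(pot, n_steps = 2e4, seed = 5)
  b <- run_wt_metadynamics(pot, n_steps = 2e4, seed = 5)
  expect_identical(a$hills, b$hills)
  expect_identical(a$trace, b$trace)
  c <- run_wt_metadynamics(pot, n_steps = 2e4, seed = 6)
  expect_false(identical(a$hills$cv1, c$hills$cv1))
})

test_that("deposited heights never exceed w0 and replay from the log", {
  pot <- hairpin_landscape()
  p <- metad_params()
  run <- run_wt_metadynamics(pot, p, n_steps = 2e4, seed = 3)
  h <- run$hills
  expect_true(all(h$height <= p$w0 + 1e-15))
  expect_equal(h$height[1], p$w0)  # first hill lands on zero bias
  # each height re-derives from the bias of the preceding hills
  for (k in seq_len(nrow(h))) {
    prev <- h[seq_len(k - 1), ]
    class(prev) <- class(h)
    v <- evaluate_bias(c(h$cv1[k], h$cv2[k]), prev)
    expect_equal(h$height[k], wt_hill_height(v, p), tolerance = 1e-10)
  }
})

test_that("a very large bias factor reproduces standard metadynamics", {
  # kB (gamma - 1) T must dwarf the accumulated bias (tens of kJ/mol here)
  # for the heights to stay within 1e-6 of w0
  pot <- hairpin_landscape()
  p <- metad_params(bias_factor = 1e9)
  run <- run_wt_metadynamics(pot, p, n_steps = 2e4, seed = 3)
  expect_true(all(abs(run$hills$height - p$w0) < 1e-6 * p$w0))
})

test_that("zero temperature with no bias descends the potential monotonically", {
  pot <- hairpin_landscape()
  p <- metad_params(temperature = 1e-12)
  st <- langevin_settings(trace_stride = 10L,
                         x0 = c(3.5, 80))  # off-minimum start
  run <- run_wt_metadynamics(pot, p, n_steps = 1e4, seed = 1,
                             settings = st, deposit = FALSE)
  expect_equal(nrow(run$hills), 0L)
  expect_true(all(diff(run$trace$energy_kJ) <= 1e-9))
})

test_that("leaving the domain box by over 10 widths aborts with a diagnostic", {
  pot <- hairpin_landscape()
  st <- langevin_settings(x0 = c(40, 500))  # far outside the box
  expect_warning(run <- run_wt_metadynamics(pot, n_steps = 100, seed = 1,
                                            settings = st),
                 "domain box")
  expect_true(run$diverged)
})

test_that("a flat landscape is sampled uniformly", {
  pot <- toy_potential("flat", box = c(0, 10, 0, 100))
  st <- langevin_settings(trace_stride = 2000L)
  run <- run_wt_metadynamics(pot, metad_params(), n_steps = 3e6, seed = 12,
                             settings = st)
  tr <- run$trace[-(1:(nrow(run$trace) / 2)), ]  # drop the burn-in half
  inside <- tr$cv1 > 0.5 & tr$cv1 < 9.5 & tr$cv2 > 5 & tr$cv2 < 95
  tr <- tr[inside, ]
  bx <- cut(tr$cv1, breaks = seq(0.5, 9.5, length.out = 4))
  by <- cut(tr$cv2, breaks = seq(5, 95, length.out = 4))
  counts <- table(bx, by)
  n <- sum(counts)
  p <- 1 / 9
  band <- 4 * sqrt(n * p * (1 - p))
  expect_true(all(abs(counts - n * p) <= band))
})

test_that("chunked runs resume hills, position and RNG stream seamlessly", {
  pot <- hairpin_landscape()
  p <- metad_params()
  set.seed(77)
  st <- langevin_settings()
  r1 <- run_wt_metadynamics(pot, p, n_steps = 1e4, seed = NULL,
                            settings = st)
  st$x0 <- r1$x_final
  r2 <- run_wt_metadynamics(pot, p, n_steps = 1e4, seed = NULL,
                            settings = st, hills0 = r1$hills,
                            t0 = 1e4 * p$dt_ps)
  joint <- rbind(r1$hills, r2$hills)
  expect_true(all(diff(joint$time) > 0))
  # resumed tempering still replays against the combined log
  k <- nrow(r1$hills) + 1L
  prev <- joint[seq_len(k - 1), ]
  class(prev) <- class(r1$hills)
  v <- evaluate_bias(c(joint$cv1[k], joint$cv2[k]), prev)
  expect_equal(joint$height[k], wt_hill_height(v, p), tolerance = 1e-10)
})
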