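# Well-tempered metadynamics on a 2D collective-variable space.
#
# The biasing protocol follows the standard well-tempered scheme: Gaussian
# hills of initial height w0 are deposited every `pace` steps, tempered as
#   w = w0 * exp(-V(s) / (kB * (gamma - 1) * T))
# where V(s) is the accumulated bias at the deposition point and gamma the
# bias factor. The microscopic sampler is overdamped Langevin dynamics on
# toy analytic potentials standing in for the all-atom system: the biasing
# mathematics is independent of the microscopic engine.

#' Well-tempered metadynamics parameters
#'
#' Defaults mirror a typical hairpin-opening protocol: 1.0 kJ/mol hills
#' every 0.2 ps (100 steps at a 2 fs-equivalent timestep), widths 0.5
#' Angstrom on the RMSD axis and 10 on the dimensionless coordination
#' number, bias factor 15, 300 K.
#'
#' @param w0 initial hill height, kJ/mol (> 0).
#' @param pace steps between hill depositions.
#' @param widths Gaussian widths `(sigma_cv1 [Angstrom], sigma_cv2)`.
#' @param bias_factor well-tempered bias factor gamma (> 1).
#' @param temperature K.
#' @param dt_ps bookkeeping timestep, ps per sampler step (maps `pace`
#'   steps to the deposition stride; default 0.002 ps = 2 fs).
#' @return object of class `metad_params`.
#' @export
metad_params <- function(w0 = 1.0, pace = 100L, widths = c(0.5, 10),
                         bias_factor = 15, temperature = 300,
                         dt_ps = 0.002) {
  if (w0 <= 0) stop("`w0` must be positive")
  if (bias_factor <= 1) stop("`bias_factor` must exceed 1")
  if (any(widths <= 0)) stop("`widths` must be positive")
  if (pace < 1) stop("`pace` must be a positive integer")
  structure(list(w0 = w0, pace = as.integer(pace), widths = widths,
                 bias_factor = bias_factor, temperature = temperature,
                 dt_ps = dt_ps),
            class = "metad_params")
}

#' Tempered hill height
#'
#' `w = w0 * exp(-V / (kB * (gamma - 1) * T))`: the first hill has height
#' `w0` exactly; heights decay monotonically toward zero as the local bias
#' accumulates.
#'
#' @param bias_at_center accumulated bias at the deposition point, kJ/mol
#'   (>= 0).
#' @param params a [metad_params()].
#' @return hill height, kJ/mol.
#' @export
wt_hill_height <- function(bias_at_center, params) {
  stopifnot(inherits(params, "metad_params"))
  if (any(bias_at_center < 0)) stop("`bias_at_center` must be nonnegative")
  kb_dt <- .kB_kJ * (params$bias_factor - 1) * params$temperature
  params$w0 * exp(-bias_at_center / kb_dt)
}

#' Construct a hills log
#'
#' @param time deposition times (ps), strictly increasing.
#' @param cv1,cv2 hill centers.
#' @param sigma_cv1,sigma_cv2 hill widths.
#' @param height hill heights, kJ/mol (> 0).
#' @param biasf bias factor.
#' @return data.frame of class `hills_log`.
#' @export
hills_log <- function(time, cv1, cv2, sigma_cv1, sigma_cv2, height, biasf) {
  if (length(time) && any(diff(time) <= 0))
    stop("hill times must be strictly increasing")
  if (any(height <= 0)) stop("hill heights must be positive")
  out <- data.frame(time = time, cv1 = cv1, cv2 = cv2,
                    sigma_cv1 = sigma_cv1, sigma_cv2 = sigma_cv2,
                    height = height, biasf = biasf)
  class(out) <- c("hills_log", "data.frame")
  out
}

.empty_hills <- function(biasf = 15)
  hills_log(numeric(0), numeric(0), numeric(0), numeric(0), numeric(0),
            numeric(0), numeric(0))

#' Evaluate the deposited bias
#'
#' `V(s) = sum_k h_k exp(-d1^2 / 2 s1^2 - d2^2 / 2 s2^2)` over the hills
#' log; an empty log gives 0.
#'
#' @param points length-2 vector `(cv1, cv2)` or an n x 2 matrix.
#' @param hills a [hills_log()].
#' @return bias value(s), kJ/mol.
#' @export
evaluate_bias <- function(points, hills) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (nrow(hills) == 0L) return(rep(0, nrow(points)))
  apply(points, 1L, function(p) {
    sum(hills$height * exp(-0.5 * ((p[1] - hills$cv1) / hills$sigma_cv1)^2
                           - 0.5 * ((p[2] - hills$cv2) / hills$sigma_cv2)^2))
  })
}

#' Toy collective-variable-space potential
#'
#' Analytic potentials on the `(rmsd, cn)` plane used as desk-scale
#' stand-ins for the all-atom landscape. All kinds carry quartic confining
#' walls outside the domain box.
#'
#' @param kind `"double_well"` (two Gaussian wells), `"harmonic"`, or
#'   `"flat"`.
#' @param params numeric parameter vector: double_well
#'   `(A1, c1x, c1y, w1x, w1y, A2, c2x, c2y, w2x, w2y)` (depths in kJ/mol,
#'   Gaussian wells subtracted from zero); harmonic `(k1, c1, k2, c2)`;
#'   flat ignores it.
#' @param box domain `(lo1, hi1, lo2, hi2)`.
#' @param wall_k wall strength, kJ/mol.
#' @param wall_scale per-dimension wall softness; default 5% of the box.
#' @param start suggested starting point for samplers.
#' @return object of class `toy_potential`.
#' @export
toy_potential <- function(kind = c("double_well", "harmonic", "flat"),
                          params = numeric(0),
                          box = c(-2, 12, -40, 110),
                          wall_k = 10,
                          wall_scale = NULL,
                          start = NULL) {
  kind <- match.arg(kind)
  if (is.null(wall_scale))
    wall_scale <- 0.05 * c(box[2] - box[1], box[4] - box[3])
  if (is.null(start))
    start <- switch(kind,
                    double_well = c(params[2], params[3]),
                    harmonic = c(params[2], params[4]),
                    flat = c(mean(box[1:2]), mean(box[3:4])))
  structure(list(kind = kind, params = as.numeric(params), box = box,
                 wall_k = wall_k, wall_scale = wall_scale, start = start),
            class = "toy_potential")
}

#' Default two-basin hairpin landscape
#'
#' Two Gaussian wells on `(rmsd, cn)`: a hairpin basin at low RMSD / high
#' coordination number and a stem-open basin at high RMSD / low
#' coordination number, with a configurable free-energy gap (open below
#' hairpin for positive `delta_g_kcal`). Well widths (1.0 Angstrom, 15)
#' are chosen to be resolvable by the default hill widths (0.5, 10).
#'
#' @param delta_g_kcal depth difference open minus hairpin, kcal/mol.
#' @param depth_hairpin_kJ depth of the hairpin well, kJ/mol.
#' @param center_hairpin,center_open well centers `(rmsd, cn)`.
#' @param widths Gaussian well widths `(rmsd, cn)`.
#' @return a [toy_potential()] of kind `"double_well"`, starting in the
#'   hairpin basin.
#' @export
hairpin_landscape <- function(delta_g_kcal = 9.86, depth_hairpin_kJ = 20,
                              center_hairpin = c(1.0, 60),
                              center_open = c(8.0, 5),
                              widths = c(1.0, 15)) {
  a1 <- depth_hairpin_kJ
  a2 <- depth_hairpin_kJ + delta_g_kcal * .kJ_per_kcal
  toy_potential("double_well",
                params = c(a1, center_hairpin, widths, a2, center_open,
                           widths),
                box = c(-2, 12, -40, 110),
                start = center_hairpin)
}

#' Evaluate a toy potential
#'
#' @param potential a [toy_potential()].
#' @param points length-2 vector or n x 2 matrix.
#' @return potential energy value(s), kJ/mol (walls included).
#' @export
potential_energy <- function(potential, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  p <- potential$params
  U <- numeric(nrow(points))
  x <- points[, 1]; y <- points[, 2]
  if (potential$kind == "harmonic") {
    U <- 0.5 * p[1] * (x - p[2])^2 + 0.5 * p[3] * (y - p[4])^2
  } else if (potential$kind == "double_well") {
    for (w in 0:1) {
      A <- p[5 * w + 1]; cx <- p[5 * w + 2]; cy <- p[5 * w + 3]
      wx <- p[5 * w + 4]; wy <- p[5 * w + 5]
      U <- U - A * exp(-0.5 * (((x - cx) / wx)^2 + ((y - cy) / wy)^2))
    }
  }
  b <- potential$box; ws <- potential$wall_scale; k <- potential$wall_k
  U <- U + k * pmax(0, (b[1] - x) / ws[1])^4 + k * pmax(0, (x - b[2]) / ws[1])^4
  U + k * pmax(0, (b[3] - y) / ws[2])^4 + k * pmax(0, (y - b[4]) / ws[2])^4
}

#' Overdamped Langevin sampler settings
#'
#' @param mobility per-CV mobility (units of CV^2 per kJ/mol per step);
#'   the noise amplitude per step is `sqrt(2 * mobility * kB * T)`.
#' @param trace_stride steps between saved trace points.
#' @param x0 starting point; `NULL` = the potential's suggested start.
#' @return list of class `langevin_settings`.
#' @export
langevin_settings <- function(mobility = c(0.002, 0.8), trace_stride = 50L,
                              x0 = NULL) {
  if (any(mobility <= 0)) stop("`mobility` must be positive")
  structure(list(mobility = mobility, trace_stride = as.integer(trace_stride),
                 x0 = x0),
            class = "langevin_settings")
}

#' Run well-tempered metadynamics on a toy potential
#'
#' Overdamped Langevin updates on `(cv1, cv2)` under the potential plus the
#' accumulated bias; a hill is deposited every `pace` steps at the current
#' point with the tempered height of [wt_hill_height()]. Bit-reproducible
#' for a given seed. Pass `pace > n_steps` (or `deposit = FALSE`) for an
#' unbiased run; `temperature = 0` in `params` gives deterministic
#' gradient descent.
#'
#' @param potential a [toy_potential()].
#' @param params a [metad_params()].
#' @param n_steps number of sampler steps.
#' @param seed integer seed (`NULL` = use the current RNG state, e.g. to
#'   continue a stream across chunks).
#' @param settings a [langevin_settings()].
#' @param hills0 optional [hills_log()] to resume from (its bias is active
#'   from step one and its heights enter the tempering sums).
#' @param t0 time offset, ps.
#' @param deposit set `FALSE` to run without depositing hills.
#' @return list of class `metad_run`: `hills` ([hills_log()] of the new
#'   hills), `trace` data.frame `(time, cv1, cv2, energy_kJ)`, `diverged`,
#'   `x_final`, `params`, `potential`.
#' @export
run_wt_metadynamics <- function(potential, params = metad_params(),
                                n_steps = 2e5, seed = 1,
                                settings = langevin_settings(),
                                hills0 = NULL, t0 = 0, deposit = TRUE) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(params, "metad_params"),
            inherits(settings, "langevin_settings"))
  if (!is.null(seed)) set.seed(seed)
  x0 <- if (is.null(settings$x0)) potential$start else settings$x0
  box <- potential$box
  sg <- params$widths
  pad <- 5 * sg
  glo <- c(box[1] - pad[1], box[3] - pad[2])
  ghi <- c(box[2] + pad[1], box[4] + pad[2])
  gn <- pmax(31L, as.integer(ceiling((ghi - glo) / (sg / 5))) + 1L)
  h0 <- if (is.null(hills0)) matrix(0, 0, 7) else as.matrix(hills0)
  pot_kind <- match(potential$kind, c("flat", "harmonic", "double_well")) - 1L
  kT <- .kB_kJ * params$temperature
  kb_dt <- .kB_kJ * (params$bias_factor - 1) * params$temperature
  res <- metad_run_cpp(pot_kind, potential$params, box, potential$wall_k,
                       potential$wall_scale, x0, as.integer(n_steps),
                       settings$mobility, kT, if (deposit) params$w0 else 0,
                       params$pace, sg, params$bias_factor, kb_dt,
                       params$dt_ps, t0, h0, settings$trace_stride,
                       glo, ghi, gn)
  if (res$diverged)
    warning("trajectory left the domain box by more than 10 hill widths; ",
            "run aborted at the divergence point")
  hm <- res$hills[seq_len(res$n_hills), , drop = FALSE]
  hl <- hills_log(hm[, 1], hm[, 2], hm[, 3], hm[, 4], hm[, 5], hm[, 6],
                  hm[, 7])
  tm <- res$trace[seq_len(res$n_trace), , drop = FALSE]
  trace <- data.frame(time = tm[, 1], cv1 = tm[, 2], cv2 = tm[, 3],
                      energy_kJ = tm[, 4])
  structure(list(hills = hl, trace = trace, diverged = res$diverged,
                 x_final = res$x_final, params = params,
                 potential = potential),
            class = "metad_run")
}

#' @export
print.metad_run <- function(x, ...) {
  cat(sprintf("<metad_run> %d hills, %d trace points%s\n", nrow(x$hills),
              nrow(x$trace), if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' Run metadynamics in chunks until the free-energy estimate stabilizes
#'
#' Repeats [run_wt_metadynamics()] in chunks (resuming hills, position and
#' RNG stream) and after each chunk compares the basin free-energy gap
#' computed from the full deposition history against the history truncated
#' at half time ([fes_convergence()]). Stops when the two agree within
#' `tol_kcal` or `max_chunks` is reached.
#'
#' @inheritParams run_wt_metadynamics
#' @param chunk_steps sampler steps per chunk.
#' @param max_chunks chunk cap.
#' @param tol_kcal convergence tolerance on the half-vs-full gap, kcal/mol.
#' @param tail_average FES checkpoint-averaging depth (see [sum_hills()]).
#' @return list: `hills` (full log), `runs` (per-chunk `metad_run`s),
#'   `converged`, `history` data.frame of per-chunk diagnostics, `grid`
#'   (the box-restricted grid used for the diagnostics, suitable for the
#'   final [fes_from_hills()] call).
#' @export
metad_until_converged <- function(potential, params = metad_params(),
                                  settings = langevin_settings(),
                                  seed = 1, chunk_steps = 1e6,
                                  max_chunks = 6, tol_kcal = 0.3,
                                  tail_average = 10) {
  set.seed(seed)
  # basin analysis restricted to the potential's domain box: the soft-wall
  # shelves outside it accumulate bias at long times and would otherwise
  # masquerade as minima
  grid <- list(cv1 = seq(potential$box[1], potential$box[2],
                         length.out = 200),
               cv2 = seq(potential$box[3], potential$box[4],
                         length.out = 200))
  hills <- NULL
  x0 <- NULL
  t0 <- 0
  runs <- list()
  hist <- data.frame(chunk = integer(0), n_hills = integer(0),
                     delta_g_full = numeric(0), diag_kcal = numeric(0))
  converged <- FALSE
  for (ch in seq_len(max_chunks)) {
    st <- settings
    st$x0 <- x0
    run <- run_wt_metadynamics(potential, params, n_steps = chunk_steps,
                               seed = NULL, settings = st, hills0 = hills,
                               t0 = t0)
    runs[[ch]] <- run
    hills <- if (is.null(hills)) run$hills else
      hills_log(c(hills$time, run$hills$time), c(hills$cv1, run$hills$cv1),
                c(hills$cv2, run$hills$cv2),
                c(hills$sigma_cv1, run$hills$sigma_cv1),
                c(hills$sigma_cv2, run$hills$sigma_cv2),
                c(hills$height, run$hills$height),
                c(hills$biasf, run$hills$biasf))
    x0 <- run$x_final
    t0 <- t0 + chunk_steps * params$dt_ps
    cv <- tryCatch(
      fes_convergence(hills, gamma = params$bias_factor, grid = grid,
                      tail_average = tail_average),
      error = function(e) list(delta_g_full = NA_real_, diag = NA_real_))
    hist <- rbind(hist, data.frame(chunk = ch, n_hills = nrow(hills),
                                   delta_g_full = cv$delta_g_full,
                                   diag_kcal = cv$diag))
    if (is.finite(cv$diag) && cv$diag < tol_kcal && ch >= 2) {
      converged <- TRUE
      break
    }
  }
  list(hills = hills, runs = runs, converged = converged, history = hist,
       grid = grid)
}
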