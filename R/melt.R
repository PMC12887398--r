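# Two-state thermal denaturation of a FRET-labeled hairpin.
#
# The probe fluoresces weakly while folded (quencher close to the
# fluorophore) and strongly once melted. Signal model:
#   S(T) = [(1 - a*fu) * B_f(T) + a*fu * B_u(T)] * (1 - q * (T - Tmin))
# with fu the two-state van't Hoff unfolded fraction, linear baselines
# B(T) = intercept + slope * T (T in deg C), `a` an amplitude scale used to
# emulate protein doses that deplete the folded population, and `q` a
# thermal-quenching slope of the fluorophore (fractional loss per deg C).

#' Ground truth of a two-state melt
#'
#' @param tm melting temperature, deg C.
#' @param dh_vh van't Hoff enthalpy, kcal/mol (> 0).
#' @param baseline_folded,baseline_unfolded `(intercept, slope per deg C)`
#'   of the folded / unfolded fluorescence baselines.
#' @param quench_slope fractional fluorescence loss per deg C (>= 0).
#' @return object of class `melt_truth`.
#' @export
melt_truth <- function(tm = 71.5, dh_vh = 50,
                       baseline_folded = c(100, 0.1),
                       baseline_unfolded = c(300, 0.2),
                       quench_slope = 0) {
  if (dh_vh <= 0) stop("`dh_vh` must be positive")
  if (quench_slope < 0) stop("`quench_slope` must be nonnegative")
  structure(list(tm = tm, dh_vh = dh_vh,
                 baseline_folded = baseline_folded,
                 baseline_unfolded = baseline_unfolded,
                 quench_slope = quench_slope),
            class = "melt_truth")
}

#' Two-state van't Hoff unfolded fraction
#'
#' `fu(T) = 1 / (1 + exp[(dH/R) (1/T - 1/Tm)])` with temperatures in
#' kelvin; `fu(Tm) = 1/2` exactly.
#'
#' @param temp_c temperature(s), deg C.
#' @param tm melting temperature, deg C.
#' @param dh_vh van't Hoff enthalpy, kcal/mol.
#' @return unfolded fraction(s) in `(0, 1)`.
#' @export
unfolded_fraction <- function(temp_c, tm, dh_vh) {
  tk <- temp_c + 273.15
  tmk <- tm + 273.15
  1 / (1 + exp((dh_vh / .R_kcal) * (1 / tk - 1 / tmk)))
}

#' Evaluate the melt signal model
#'
#' @param temp_c temperature grid, deg C.
#' @param truth a [melt_truth()].
#' @param amplitude_scale factor in `[0, 1]` multiplying the transition
#'   amplitude (1 = full folded population at low T).
#' @param t_min reference temperature for the quench term; defaults to
#'   `min(temp_c)`.
#' @return fluorescence signal, same length as `temp_c`.
#' @export
melt_model <- function(temp_c, truth, amplitude_scale = 1,
                       t_min = min(temp_c)) {
  stopifnot(inherits(truth, "melt_truth"))
  fu <- unfolded_fraction(temp_c, truth$tm, truth$dh_vh)
  bf <- truth$baseline_folded[1] + truth$baseline_folded[2] * temp_c
  bu <- truth$baseline_unfolded[1] + truth$baseline_unfolded[2] * temp_c
  core <- bf + amplitude_scale * fu * (bu - bf)
  core * (1 - truth$quench_slope * (temp_c - t_min))
}

#' Construct a melt curve
#'
#' @param temps temperatures, deg C, strictly increasing.
#' @param signal fluorescence, same length.
#' @param condition free-text condition label (e.g. protein dose).
#' @return object of class `melt_curve`.
#' @export
melt_curve <- function(temps, signal, condition = "") {
  if (length(temps) != length(signal))
    stop("temperature and signal vectors must have equal length")
  if (length(temps) == 0L) stop("empty temperature grid")
  if (any(diff(temps) <= 0)) stop("temperatures must be strictly increasing")
  structure(list(temps = as.numeric(temps), signal = as.numeric(signal),
                 condition = condition),
            class = "melt_curve")
}

#' Melting temperature from the smoothed first derivative
#'
#' Smooths the curve with a moving quadratic (Savitzky-Golay) filter, takes
#' the central-difference derivative, and reports the temperature of the
#' derivative extremum in the scan interior (sub-grid position from a
#' parabolic vertex through the three points around the peak). A curve with
#' no interior, prominent derivative extremum -- e.g. a monotone
#' quench-dominated scan of a fully remodeled probe -- is reported as
#' having no transition rather than a spurious Tm.
#'
#' @param curve a [melt_curve()].
#' @param smooth_window odd Savitzky-Golay window length (default 5).
#' @return list: `tm` (deg C or `NA`), `no_transition` flag, `derivative`
#'   data.frame `(temp_c, dsignal_dT)`, `direction` (+1 rising signal,
#'   -1 falling).
#' @export
derivative_tm <- function(curve, smooth_window = 5) {
  stopifnot(inherits(curve, "melt_curve"))
  w <- as.integer(smooth_window)
  if (w < 3L || w %% 2L == 0L) stop("`smooth_window` must be odd and >= 3")
  n <- length(curve$temps)
  if (n < 2L * w + 3L) stop("need at least 2*smooth_window + 3 points")
  sm <- signal::sgolayfilt(curve$signal, p = 2, n = w)
  d <- numeric(n)
  d[2:(n - 1)] <- (sm[3:n] - sm[1:(n - 2)]) / (curve$temps[3:n] - curve$temps[1:(n - 2)])
  d[1] <- d[2]; d[n] <- d[n - 1]
  interior <- (w + 1L):(n - w)
  di <- d[interior]
  i_loc <- which.max(abs(di))
  i_star <- interior[i_loc]
  peak <- abs(di[i_loc])
  edge_mag <- max(abs(di[1L]), abs(di[length(di)]))
  prominence <- if (peak > 0) (peak - edge_mag) / peak else 0
  no_transition <- i_loc <= 1L || i_loc >= length(di) || prominence <= 0.2
  tm <- NA_real_
  if (!no_transition) {
    # parabolic vertex through the three samples around the extremum
    t3 <- curve$temps[(i_star - 1L):(i_star + 1L)]
    y3 <- abs(d[(i_star - 1L):(i_star + 1L)])
    denom <- (y3[1] - 2 * y3[2] + y3[3])
    tm <- if (denom < 0) {
      t3[2] + 0.5 * (t3[3] - t3[1]) / 2 * (y3[1] - y3[3]) / denom
    } else t3[2]
    if (abs(tm - t3[2]) > (t3[3] - t3[1])) tm <- t3[2]
  }
  list(tm = tm, no_transition = no_transition,
       derivative = data.frame(temp_c = curve$temps, dsignal_dT = d),
       direction = if (no_transition) 0 else sign(d[i_star]))
}

#' Fit the two-state melt model
#'
#' Nonlinear least squares over `(Tm, dH, baselines, quench)` of the model
#' in [melt_model()] (with a free amplitude carried by the fitted
#' baselines). Initialization is deterministic: baselines from the first
#' and last fifth of the scan, Tm from [derivative_tm()] (falling back to
#' the scan midpoint), dH at 50 kcal/mol.
#'
#' @param curve a [melt_curve()].
#' @param fit_quench include a thermal-quench slope parameter (default TRUE).
#' @param smooth_window passed to [derivative_tm()] for the Tm start value.
#' @return object of class `melt_fit`: `tm`, `tm_se`, `dh_vh`, `amplitude`
#'   (unfolded-minus-folded baseline gap at Tm, signal units), `baselines`,
#'   `quench_slope`, `tm_derivative`, `residual_rms`, `converged`.
#' @export
fit_melt <- function(curve, fit_quench = TRUE, smooth_window = 5) {
  stopifnot(inherits(curve, "melt_curve"))
  temps <- curve$temps
  y <- curve$signal
  t_min <- min(temps)
  dtm <- derivative_tm(curve, smooth_window)
  n <- length(temps)
  k <- max(3L, n %/% 5L)
  lo <- stats::lm(y[1:k] ~ temps[1:k])$coefficients
  hi <- stats::lm(y[(n - k + 1):n] ~ temps[(n - k + 1):n])$coefficients
  tm0 <- if (!is.na(dtm$tm)) dtm$tm else mean(range(temps))
  start <- list(tm = tm0, dh = 50, af = unname(lo[1]), bf = unname(lo[2]),
                au = unname(hi[1]), bu = unname(hi[2]))
  form <- y ~ (af + bf * temps +
                 unfolded_fraction(temps, tm, dh) *
                 ((au + bu * temps) - (af + bf * temps))) *
              (1 - q * (temps - t_min))
  if (fit_quench) start$q <- 0 else q <- 0
  dat <- data.frame(temps = temps, y = y)
  lower <- c(tm = min(temps), dh = 1, af = -Inf, bf = -Inf, au = -Inf,
             bu = -Inf)
  upper <- c(tm = max(temps), dh = 1000, af = Inf, bf = Inf, au = Inf,
             bu = Inf)
  if (fit_quench) { lower <- c(lower, q = -0.05); upper <- c(upper, q = 0.05) }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = dat, start = start, lower = lower,
                      upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(tm = NA_real_, tm_se = NA_real_, dh_vh = NA_real_,
                          amplitude = NA_real_, baselines = NULL,
                          quench_slope = NA_real_, tm_derivative = dtm$tm,
                          residual_rms = NA_real_, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "melt_fit"))
  }
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  amp <- (cf[["au"]] + cf[["bu"]] * cf[["tm"]]) -
         (cf[["af"]] + cf[["bf"]] * cf[["tm"]])
  res <- stats::residuals(fit)
  conv <- cf[["tm"]] > min(temps) + 0.5 && cf[["tm"]] < max(temps) - 0.5
  structure(list(
    tm = cf[["tm"]], tm_se = unname(se["tm"]), dh_vh = cf[["dh"]],
    amplitude = abs(amp), amplitude_signed = amp,
    baselines = list(folded = c(cf[["af"]], cf[["bf"]]),
                     unfolded = c(cf[["au"]], cf[["bu"]])),
    quench_slope = if (fit_quench) cf[["q"]] else 0,
    tm_derivative = dtm$tm, residual_rms = sqrt(mean(res^2)),
    converged = conv, message = if (conv) "ok" else "Tm at scan boundary"),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> converged=%s\n", x$converged))
  if (isTRUE(x$converged))
    cat(sprintf("  Tm = %.2f +/- %.2g degC (derivative: %.2f), dH = %.1f kcal/mol, amplitude = %.3g\n",
                x$tm, x$tm_se, x$tm_derivative, x$dh_vh, x$amplitude))
  invisible(x)
}

#' Transition amplitude versus protein dose
#'
#' Fits each melt curve, normalizes the transition amplitudes to the
#' zero-dose curve, and compares them with the free-hairpin fraction
#' `1 - fb(dose)` predicted by the depletion isotherm. A probe saturated
#' with binder has (near) zero amplitude: the hairpin population is gone
#' before heating starts.
#'
#' @param curves list of [melt_curve()]s on a shared temperature grid.
#' @param doses numeric binder doses (nM), same length, including 0.
#' @param kd,probe_total binding parameters (nM) for the prediction.
#' @param smooth_window passed to [fit_melt()].
#' @return list: `table` data.frame `(dose, amplitude, rel_amplitude,
#'   predicted)`, `rms` agreement between `rel_amplitude` and `predicted`.
#' @export
amplitude_vs_dose <- function(curves, doses, kd, probe_total,
                              smooth_window = 5) {
  if (length(curves) != length(doses)) stop("one dose per curve required")
  if (!any(doses == 0)) stop("a zero-dose reference curve is required")
  grids <- lapply(curves, `[[`, "temps")
  if (!all(vapply(grids, function(g) identical(g, grids[[1]]), logical(1))))
    stop("melt curves must share one temperature grid")
  amps <- vapply(curves, function(cu) {
    f <- fit_melt(cu, smooth_window = smooth_window)
    if (is.na(f$amplitude)) 0 else f$amplitude
  }, numeric(1))
  ref <- amps[which(doses == 0)[1]]
  rel <- amps / ref
  pred <- 1 - fraction_bound(doses, probe_total, kd)
  tab <- data.frame(dose = doses, amplitude = amps, rel_amplitude = rel,
                    predicted = pred)
  list(table = tab, rms = sqrt(mean((rel - pred)^2)))
}
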