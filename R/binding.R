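# Single-site equilibrium binding with ligand depletion.
#
# In all titration experiments the labeled probe (RNA or DNA, tens of nM) is
# held fixed while protein is titrated. Because the probe concentration is
# comparable to Kd, the free-protein approximation fails and the bound
# fraction must come from the exact 1:1 mass balance:
#   P_free * L_free / Kd = C,  P = P_free + C,  L = L_free + C
# whose physical root gives fb = C / L.

#' Fraction of probe bound under ligand depletion
#'
#' Exact single-site 1:1 bound fraction of a probe at total concentration
#' `probe_total` titrated with a binder at total concentration
#' `protein_total`. Uses the numerically stable (multiply-conjugate) form of
#' the quadratic mass-balance root,
#' `fb = 2P / (P + L + Kd + sqrt((P + L + Kd)^2 - 4 P L))`,
#' which avoids catastrophic cancellation when `P >> L` and degrades
#' gracefully to the hyperbolic limit `P / (P + Kd)` as `L -> 0`.
#'
#' @param protein_total titrant (binder) total concentration(s); any
#'   concentration unit, consistent with `probe_total` and `kd`. Vectorized.
#' @param probe_total labeled probe total concentration (scalar).
#' @param kd dissociation constant, same unit.
#' @return bound fraction(s) in `[0, 1]`.
#' @examples
#' fraction_bound(40, 40, 40)   # (3 - sqrt(5)) / 2
#' fraction_bound(23.7, 1e-9, 23.7)  # ~ 0.5, hyperbolic limit
#' @export
fraction_bound <- function(protein_total, probe_total, kd) {
  if (length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("`kd` must be a single positive number")
  if (length(probe_total) != 1L || probe_total < 0)
    stop("`probe_total` must be a single nonnegative number")
  if (any(protein_total < 0)) stop("`protein_total` must be nonnegative")
  s <- protein_total + probe_total + kd
  disc <- s^2 - 4 * protein_total * probe_total
  disc[disc < 0] <- 0  # guard roundoff
  fb <- 2 * protein_total / (s + sqrt(disc))
  pmin(pmax(fb, 0), 1)
}

#' Ground-truth parameters of a binding titration
#'
#' @param kd dissociation constant (nM by convention in this package).
#' @param probe_total probe concentration (nM).
#' @param obs_free observable of the unbound probe (e.g. anisotropy 0.079
#'   for a folded hairpin probe).
#' @param obs_bound observable of the saturated complex; may be above or
#'   below `obs_free` (anisotropy drops when the hairpin is remodeled,
#'   FRET-probe intensity rises when the ends separate).
#' @param obs_kind `"anisotropy"` or `"fret_intensity"`.
#' @return object of class `binding_truth`.
#' @export
binding_truth <- function(kd, probe_total, obs_free, obs_bound,
                          obs_kind = c("anisotropy", "fret_intensity")) {
  obs_kind <- match.arg(obs_kind)
  if (kd <= 0) stop("`kd` must be positive")
  if (probe_total <= 0) stop("`probe_total` must be positive")
  if (obs_free == obs_bound) stop("`obs_free` and `obs_bound` must differ")
  structure(list(kd = kd, probe_total = probe_total, obs_free = obs_free,
                 obs_bound = obs_bound, obs_kind = obs_kind),
            class = "binding_truth")
}

#' Predict the titration observable from ground truth
#'
#' Population-weighted linear mix
#' `obs_free + fb * (obs_bound - obs_free)` with `fb` from
#' [fraction_bound()].
#'
#' @param truth a [binding_truth()].
#' @param titrant_concs titrant concentrations (nM), nonnegative.
#' @return numeric vector of predicted observables.
#' @export
predict_observable <- function(truth, titrant_concs) {
  stopifnot(inherits(truth, "binding_truth"))
  fb <- fraction_bound(titrant_concs, truth$probe_total, truth$kd)
  truth$obs_free + fb * (truth$obs_bound - truth$obs_free)
}

#' Construct a titration series
#'
#' @param titrant_concs titrant concentrations (nM), sorted nondecreasing.
#' @param observables measured observable, same length.
#' @param probe_total probe concentration (nM).
#' @param obs_kind observable label.
#' @param truth optional [binding_truth()] provenance (recorded by the
#'   synthetic generator).
#' @return object of class `titration_series`.
#' @export
titration_series <- function(titrant_concs, observables, probe_total,
                             obs_kind = "anisotropy", truth = NULL) {
  if (length(titrant_concs) != length(observables))
    stop("concentration and observable vectors must have equal length")
  if (any(titrant_concs < 0)) stop("titrant concentrations must be nonnegative")
  if (is.unsorted(titrant_concs)) stop("titrant concentrations must be sorted")
  if (probe_total <= 0) stop("`probe_total` must be positive")
  structure(list(titrant_concs = as.numeric(titrant_concs),
                 observables = as.numeric(observables),
                 probe_total = probe_total, obs_kind = obs_kind,
                 truth = truth),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration_series> %d points, probe %g nM, %s\n",
              length(x$titrant_concs), x$probe_total, x$obs_kind))
  invisible(x)
}

# deterministic initialization: endpoints from first/last observation,
# Kd from the titrant concentration nearest half signal change; a second
# start at the geometric mean of the nonzero grid rescues noisy series
# whose half-signal point collapses onto the grid edge
.fit_kd_start <- function(series) {
  obs <- series$observables
  conc <- series$titrant_concs
  f0 <- obs[1L]
  f1 <- obs[length(obs)]
  half <- (f0 + f1) / 2
  i <- which.min(abs(obs - half))
  kd0 <- conc[i]
  pos <- conc[conc > 0]
  fallback <- exp(mean(log(pos)))
  if (kd0 <= 0) kd0 <- fallback
  list(starts = c(kd0, fallback), f0 = f0, f1 = f1)
}

#' Fit a dissociation constant to a titration series
#'
#' Nonlinear least squares of the single-site model over
#' `(Kd, obs_free, obs_bound)`. The default `"depletion"` model uses the
#' exact mass-balance isotherm [fraction_bound()]; a Hill model
#' (`obs = f0 + (f1 - f0) * c^n / (c^n + ec50^n)`) is provided for
#' comparison with plate-reader-software style logistic fits. Standard
#' errors are asymptotic (from the fit covariance); set `n_boot > 0` for a
#' residual-resampling bootstrap on Kd instead.
#'
#' Degenerate series (no signal change) and fits whose Kd collapses onto
#' the positivity bound are flagged via `converged = FALSE` and a message,
#' never silently returned.
#'
#' @param series a [titration_series()] with at least 5 points.
#' @param model `"depletion"` (default) or `"hill"`.
#' @param n_boot bootstrap replicates for the Kd standard error (0 = use
#'   asymptotic errors).
#' @param boot_seed seed for the bootstrap resampling.
#' @return object of class `binding_fit`: `kd`, `kd_se`, `obs_free(_se)`,
#'   `obs_bound(_se)`, `residual_rms`, `converged`, `message`, `model`.
#' @export
fit_kd <- function(series, model = c("depletion", "hill"), n_boot = 0,
                   boot_seed = 1) {
  stopifnot(inherits(series, "titration_series"))
  model <- match.arg(model)
  if (length(series$titrant_concs) < 5L)
    stop("need at least 5 titration points")
  obs <- series$observables
  conc <- series$titrant_concs
  lt <- series$probe_total

  fail <- function(msg) {
    structure(list(kd = NA_real_, kd_se = NA_real_, obs_free = NA_real_,
                   obs_free_se = NA_real_, obs_bound = NA_real_,
                   obs_bound_se = NA_real_, residual_rms = NA_real_,
                   converged = FALSE, message = msg, model = model),
              class = "binding_fit")
  }
  if (diff(range(obs)) == 0) return(fail("non-identifiable: constant observable"))

  st <- .fit_kd_start(series)
  dat <- data.frame(conc = conc, obs = obs)
  fit <- NULL
  for (kd0 in st$starts) {
    fit <- tryCatch({
      if (model == "depletion") {
        minpack.lm::nlsLM(
          obs ~ f0 + (f1 - f0) * fraction_bound(conc, lt, kd),
          data = dat, start = list(kd = kd0, f0 = st$f0, f1 = st$f1),
          lower = c(kd = 1e-9, f0 = -Inf, f1 = -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          obs ~ f0 + (f1 - f0) * conc^n / (conc^n + ec50^n),
          data = dat,
          start = list(ec50 = kd0, n = 1, f0 = st$f0, f1 = st$f1),
          lower = c(ec50 = 1e-9, n = 0.1, f0 = -Inf, f1 = -Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) e)
    if (!inherits(fit, "error")) break
  }
  if (inherits(fit, "error")) return(fail(paste("fit failed:", conditionMessage(fit))))

  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
  names(se) <- names(cf)
  kd_name <- if (model == "depletion") "kd" else "ec50"
  kd_hat <- unname(cf[kd_name])
  res <- stats::residuals(fit)
  out <- structure(list(
    kd = kd_hat, kd_se = unname(se[kd_name]),
    obs_free = unname(cf["f0"]), obs_free_se = unname(se["f0"]),
    obs_bound = unname(cf["f1"]), obs_bound_se = unname(se["f1"]),
    residual_rms = sqrt(mean(res^2)),
    converged = TRUE, message = "ok", model = model),
    class = "binding_fit")
  if (model == "hill") out$hill_n <- unname(cf["n"])

  if (kd_hat <= 2e-9) {
    out$converged <- FALSE
    out$message <- "kd collapsed onto the positivity bound"
  }
  dyn <- abs(out$obs_bound - out$obs_free)
  if (is.finite(dyn) && dyn < 3 * out$residual_rms) {
    out$converged <- FALSE
    out$message <- "non-identifiable: signal change indistinguishable from noise"
  }
  if (out$converged && n_boot > 0) {
    set.seed(boot_seed)
    fitted_v <- stats::fitted(fit)
    kds <- vapply(seq_len(n_boot), function(b) {
      ob <- fitted_v + sample(res, replace = TRUE)
      bs <- tryCatch(fit_kd(titration_series(conc, ob, lt, series$obs_kind),
                            model = model),
                     error = function(e) NULL)
      if (is.null(bs) || !bs$converged) NA_real_ else bs$kd
    }, numeric(1))
    out$kd_se <- stats::sd(kds, na.rm = TRUE)
    out$n_boot <- n_boot
  }
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> model=%s converged=%s\n", x$model, x$converged))
  if (isTRUE(x$converged)) {
    cat(sprintf("  Kd = %.4g +/- %.3g\n", x$kd, x$kd_se))
    cat(sprintf("  obs_free = %.4g, obs_bound = %.4g, residual rms = %.3g\n",
                x$obs_free, x$obs_bound, x$residual_rms))
  } else cat("  ", x$message, "\n")
  invisible(x)
}

#' @export
plot.titration_series <- function(x, fit = NULL, ...) {
  graphics::plot(x$titrant_concs, x$observables, log = "x",
                 xlab = "titrant (nM)", ylab = x$obs_kind, ...)
  if (!is.null(fit) && isTRUE(fit$converged)) {
    cg <- exp(seq(log(max(min(x$titrant_concs[x$titrant_concs > 0]), 1e-3)),
                  log(max(x$titrant_concs)), length.out = 200))
    tr <- binding_truth(fit$kd, x$probe_total, fit$obs_free, fit$obs_bound,
                        x$obs_kind)
    graphics::lines(cg, predict_observable(tr, cg), col = 2)
  }
  invisible(x)
}
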