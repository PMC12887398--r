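# Seeded generators for every pipeline input. Each generator is a pure
# function of (arguments, seed): identical calls give identical output, and
# sd = 0 output lies exactly on the corresponding model curve.

#' Gaussian read-noise specification
#'
#' @param sd noise standard deviation in observable units (>= 0).
#' @param seed integer RNG seed.
#' @param kind only `"gaussian"` is implemented.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(sd = 0, seed = 1, kind = "gaussian") {
  if (!identical(kind, "gaussian")) stop("unknown noise kind: ", kind)
  if (sd < 0) stop("`sd` must be nonnegative")
  structure(list(kind = kind, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

.with_noise <- function(values, noise, scale = 1) {
  if (noise$sd == 0) return(values)
  set.seed(noise$seed)
  values + rnorm(length(values), sd = noise$sd * scale)
}

#' Generate a synthetic binding titration
#'
#' Observable = `obs_free + fb * (obs_bound - obs_free) + eps`, with `fb`
#' from the ligand-depletion isotherm [fraction_bound()] and Gaussian read
#' noise `eps`.
#'
#' @param truth a [binding_truth()].
#' @param titrant_concs nonnegative, sorted titrant concentrations (nM).
#' @param noise a [noise_spec()]; `sd` in observable units.
#' @return [titration_series()] carrying `truth` as provenance.
#' @export
gen_titration <- function(truth, titrant_concs, noise = noise_spec()) {
  stopifnot(inherits(truth, "binding_truth"), inherits(noise, "noise_spec"))
  if (any(titrant_concs < 0)) stop("titrant concentrations must be nonnegative")
  if (is.unsorted(titrant_concs)) stop("titrant concentrations must be sorted")
  pred <- predict_observable(truth, titrant_concs)
  obs <- .with_noise(pred, noise)
  titration_series(titrant_concs, obs, truth$probe_total, truth$obs_kind,
                   truth = truth)
}

#' Log-spaced titrant grid spanning a transition
#'
#' @param kd center of the transition (nM).
#' @param lo,hi span as multiples of `kd` (default 0.01-10x).
#' @param n number of nonzero points.
#' @param include_zero prepend a zero-titrant point.
#' @return sorted concentration vector (nM).
#' @export
titrant_grid <- function(kd, lo = 0.01, hi = 10, n = 12,
                         include_zero = TRUE) {
  g <- exp(seq(log(lo * kd), log(hi * kd), length.out = n))
  if (include_zero) c(0, g) else g
}

#' Generate a synthetic melt curve
#'
#' Signal from [melt_model()] plus Gaussian noise. `amplitude_scale < 1`
#' emulates partial pre-melting depletion of the folded population by a
#' bound protein; with `amplitude_scale = 0` and a positive quench slope
#' the signal decreases monotonically with temperature, the
#' fully-remodeled regime.
#'
#' @param truth a [melt_truth()].
#' @param temps sorted ascending temperature grid (deg C), nonempty.
#' @param noise a [noise_spec()]; `sd` in signal units.
#' @param amplitude_scale transition amplitude factor in `[0, 1]`.
#' @param condition curve label.
#' @return a [melt_curve()].
#' @export
gen_melt <- function(truth, temps, noise = noise_spec(),
                     amplitude_scale = 1, condition = "") {
  stopifnot(inherits(truth, "melt_truth"), inherits(noise, "noise_spec"))
  if (length(temps) == 0L) stop("empty temperature grid")
  if (any(diff(temps) <= 0)) stop("temperatures must be strictly increasing")
  sig <- melt_model(temps, truth, amplitude_scale = amplitude_scale)
  melt_curve(temps, .with_noise(sig, noise), condition = condition)
}

#' Perturbation specification for synthetic NMR titrations
#'
#' @param perturbed_residues residue ids whose bound-state shifts move.
#' @param dh_bound,dn_bound ppm offsets (bound minus apo) per perturbed
#'   residue, same length as `perturbed_residues`.
#' @param ratios strictly increasing RNA:protein molar ratios.
#' @param protein_total protein concentration, uM.
#' @param kd dissociation constant, uM.
#' @return object of class `shift_perturbation_spec`.
#' @export
shift_perturbation_spec <- function(
    perturbed_residues = c(84L, 85L, 86L, 100L, 101L),
    dh_bound = c(0.12, 0.18, 0.15, 0.10, 0.14),
    dn_bound = c(0.8, 1.2, -0.9, 0.7, 1.0),
    ratios = c(0.6, 1.2, 1.9, 2.5, 3.8, 5.0, 10.1),
    protein_total = 68, kd = 1) {
  if (length(dh_bound) != length(perturbed_residues) ||
      length(dn_bound) != length(perturbed_residues))
    stop("one (dH, dN) offset pair per perturbed residue required")
  if (is.unsorted(ratios, strictly = TRUE))
    stop("ratios must be strictly increasing")
  if (kd <= 0 || protein_total <= 0) stop("kd and protein_total must be positive")
  structure(list(perturbed_residues = as.integer(perturbed_residues),
                 dh_bound = dh_bound, dn_bound = dn_bound, ratios = ratios,
                 protein_total = protein_total, kd = kd),
            class = "shift_perturbation_spec")
}

#' Synthetic apo amide shift table
#'
#' Seeded random-coil-like amide shifts (dH ~ N(8.3, 0.45), dN ~ N(118,
#' 4.5)) over a residue set; residues 84-86 and 100-101 carry their
#' biological identities (T, Y, I, N, A) when present, other names are
#' drawn at random.
#'
#' @param residues residue ids (a couple of prolines are dropped by the
#'   default to mimic unassignable positions).
#' @param seed integer seed.
#' @return apo [shift_table()].
#' @export
gen_apo_shift_table <- function(residues = setdiff(1:120, c(38L, 58L)),
                                seed = 42) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "Q",
          "R", "S", "T", "V", "W", "Y")
  nm <- sample(aa, length(residues), replace = TRUE)
  known <- c(`84` = "T", `85` = "Y", `86` = "I", `100` = "N", `101` = "A")
  hit <- match(as.integer(names(known)), residues)
  nm[hit[!is.na(hit)]] <- known[!is.na(hit)]
  shift_table(residues, nm,
              rnorm(length(residues), 8.3, 0.45),
              rnorm(length(residues), 118, 4.5), state = "apo")
}

#' Generate fast-exchange-averaged titration shift tables
#'
#' At each RNA:protein ratio the observed shift is the population average
#' `(1 - fb) * delta_apo + fb * delta_bound`, with the bound protein
#' fraction `fb` from the depletion mass balance at that ratio's RNA
#' concentration (RNA total = ratio x protein total). Gaussian noise of
#' `sd` ppm is added on the proton axis and `6 * sd` on nitrogen
#' (dispersion-scaled).
#'
#' @param spec a [shift_perturbation_spec()]; all perturbed residues must
#'   be present in `apo`.
#' @param apo apo [shift_table()].
#' @param noise a [noise_spec()].
#' @return list of [shift_table()]s: the apo table followed by one table
#'   per ratio (state = ratio label).
#' @export
gen_shift_tables <- function(spec, apo, noise = noise_spec()) {
  stopifnot(inherits(spec, "shift_perturbation_spec"),
            inherits(apo, "shift_table"))
  if (!all(spec$perturbed_residues %in% apo$residue_id))
    stop("perturbed residue absent from the apo table")
  dh_off <- dn_off <- numeric(nrow(apo))
  i <- match(spec$perturbed_residues, apo$residue_id)
  dh_off[i] <- spec$dh_bound
  dn_off[i] <- spec$dn_bound
  if (noise$sd > 0) set.seed(noise$seed)
  out <- vector("list", length(spec$ratios) + 1L)
  out[[1L]] <- apo
  for (k in seq_along(spec$ratios)) {
    rna_total <- spec$ratios[k] * spec$protein_total
    fb <- fraction_bound(rna_total, spec$protein_total, spec$kd)
    dh <- apo$dH_ppm + fb * dh_off
    dn <- apo$dN_ppm + fb * dn_off
    if (noise$sd > 0) {
      dh <- dh + rnorm(length(dh), sd = noise$sd)
      dn <- dn + rnorm(length(dn), sd = 6 * noise$sd)
    }
    out[[k + 1L]] <- shift_table(apo$residue_id, apo$residue_name, dh, dn,
                                 state = format(spec$ratios[k]))
  }
  out
}

#' Geometry parameters of the parametric hairpin builder
#'
#' @param rise stem rise per base pair, Angstrom.
#' @param strand_x half-separation of the backbone strands, Angstrom.
#' @param pair_half half-distance between paired base centroids (3 Angstrom
#'   pair contact by default), Angstrom.
#' @param loop_radius radius of the 7-residue loop arc, Angstrom.
#' @param open_step per-residue extension step of the open-state arm,
#'   Angstrom.
#' @param open_lift vertical offset of the open-state arm, Angstrom.
#' @return list of class `hairpin_geometry`.
#' @export
hairpin_geometry <- function(rise = 4.0, strand_x = 6.0, pair_half = 1.5,
                             loop_radius = 6.0, open_step = 3.5,
                             open_lift = 2.0) {
  structure(list(rise = rise, strand_x = strand_x, pair_half = pair_half,
                 loop_radius = loop_radius, open_step = open_step,
                 open_lift = open_lift),
            class = "hairpin_geometry")
}

#' 15-mer hairpin sequence
#' @return character vector of the 15 bases (5' to 3').
#' @export
rna15_sequence <- function() strsplit("ACGGAAAGACCCCGU", "")[[1]]

# fixed local backbone-atom offsets (Angstrom) around each residue
.bb_offsets <- function() {
  m <- rbind(P    = c(0.0,  0.0, 0.0),
             `O5'` = c(0.8,  0.3, 0.5),
             `C5'` = c(1.4, -0.2, 0.9),
             `C4'` = c(0.9,  0.7, 1.2),
             `C3'` = c(0.2,  1.1, 0.6),
             `O3'` = c(-0.5, 0.8, 1.0))
  colnames(m) <- c("x", "y", "z")
  m
}

#' Deterministic parametric hairpin conformer
#'
#' Builds an idealized 15-residue conformer in one of two states. In the
#' `"closed"` (hairpin) state residues 1-4 pair with 15-12: the paired
#' base-centroid pseudo-atoms sit exactly `2 * pair_half` = 3 Angstrom
#' apart, and residues 5-11 form a loop arc. In the `"open"` (stem-open)
#' state the strand beyond the loop entry is extended away, separating the
#' terminal groups by well over 15 Angstrom. The geometry is parametric,
#' not force-field derived: it exists to give the collective-variable
#' operators controllable contact/separation structure.
#'
#' @param state `"closed"` or `"open"`.
#' @param geometry a [hairpin_geometry()].
#' @return a [conformer()].
#' @export
gen_hairpin_conformer <- function(state = c("closed", "open"),
                                  geometry = hairpin_geometry()) {
  state <- match.arg(state)
  g <- geometry
  seqs <- rna15_sequence()
  off <- .bb_offsets()
  ref <- matrix(NA_real_, 15, 3)
  bc <- matrix(NA_real_, 15, 3)
  mirror <- rep(1, 15)  # x-mirroring of backbone offsets for strand B

  # strand A (residues 1-4), shared by both states
  for (i in 1:4) {
    ref[i, ] <- c(-g$strand_x, g$rise * (i - 1), 0)
    bc[i, ] <- c(-g$pair_half, g$rise * (i - 1), 0)
  }
  y_top <- g$rise * 3
  if (state == "closed") {
    for (r in 12:15) {         # strand B, paired with 16-r
      i <- 16 - r
      ref[r, ] <- c(g$strand_x, g$rise * (i - 1), 0)
      bc[r, ] <- c(g$pair_half, g$rise * (i - 1), 0)
      mirror[r] <- -1
    }
    for (r in 5:11) {          # loop arc over the stem top
      th <- pi - pi * (r - 4) / 8
      p <- c(g$loop_radius * cos(th), y_top + g$loop_radius * sin(th), 0)
      ref[r, ] <- p
      ctr <- c(0, y_top, 0)
      bc[r, ] <- ctr + (p - ctr) * (g$loop_radius - g$pair_half) / g$loop_radius
    }
  } else {
    for (r in 5:15) {          # extended arm leaving the stem top
      ref[r, ] <- c(-g$strand_x + g$open_step * (r - 4),
                    y_top + g$open_lift, 0)
      bc[r, ] <- ref[r, ] + c(0, -g$pair_half, 0)
    }
  }

  rows <- vector("list", 15)
  for (r in 1:15) {
    bb <- sweep(off, 2, c(mirror[r], 1, 1), `*`)
    xyz <- rbind(sweep(bb, 2, ref[r, ], `+`), BC = bc[r, ])
    rows[[r]] <- data.frame(atom = rownames(xyz), resid = r,
                            element = c("P", "O", "C", "C", "C", "O", "C"),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            base = seqs[r], stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  conformer(atoms, label = paste0("rna15_", state))
}
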