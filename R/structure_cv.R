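# Structural observables of the 15-mer hairpin: Kabsch superposition RMSD,
# switching-function coordination numbers between the stem-end base groups,
# and per-base-pair interstrand distances.

#' Construct a conformer
#'
#' Named-atom 3D coordinates of the 15-nt RNA. The minimal atom dictionary
#' used by the generators is the six backbone atoms (P, O5', C5', C4',
#' C3', O3') plus one base-centroid pseudo-atom `BC` per residue.
#'
#' @param atoms data.frame with columns `atom` (name), `resid` (1-based
#'   residue index in 1..15), `element`, `x`, `y`, `z` (Angstrom).
#' @param label free-text label.
#' @return object of class `conformer`.
#' @export
conformer <- function(atoms, label = "") {
  need <- c("atom", "resid", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) stop("atoms must have columns ",
                                         paste(need, collapse = ", "))
  if (any(atoms$resid < 1 | atoms$resid > 15))
    stop("residue indices must be in 1..15")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  structure(list(atoms = atoms, label = label), class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> '%s': %d atoms, %d residues\n", x$label,
              nrow(x$atoms), length(unique(x$atoms$resid))))
  invisible(x)
}

#' Default RNA backbone atom names
#' @return character vector of backbone atom names used for RMSD.
#' @export
rna_backbone_atoms <- function() c("P", "O5'", "C5'", "C4'", "C3'", "O3'")

# coordinate matrix for a selection, keyed and ordered by (resid, atom)
.sel_coords <- function(conf, atom_names = NULL, resids = NULL) {
  a <- conf$atoms
  if (!is.null(atom_names)) a <- a[a$atom %in% atom_names, , drop = FALSE]
  if (!is.null(resids)) a <- a[a$resid %in% resids, , drop = FALSE]
  a <- a[order(a$resid, a$atom), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- paste(a$resid, a$atom, sep = ":")
  m
}

#' Optimal rigid superposition (Kabsch)
#'
#' Least-squares rotation + translation (proper rotation only; the SVD
#' reflection branch is corrected) of `mobile` onto `reference` over the
#' atom selection, matched one-to-one by `(residue, atom name)`.
#'
#' @param mobile,reference [conformer()]s.
#' @param selection atom names to superpose (default backbone).
#' @return list: `rmsd` (Angstrom), `rotation` 3x3, `translation` length-3
#'   (maps centered mobile onto reference frame).
#' @export
kabsch_superpose <- function(mobile, reference,
                             selection = rna_backbone_atoms()) {
  P <- .sel_coords(mobile, selection)
  Q <- .sel_coords(reference, selection)
  if (nrow(P) == 0L) stop("empty atom selection")
  if (nrow(P) != nrow(Q) || !identical(rownames(P), rownames(Q)))
    stop("selections do not match one-to-one by (residue, atom)")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  Pr <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((Pr - Qc)^2)))
  list(rmsd = rmsd, rotation = R, translation = cq - as.vector(R %*% cp))
}

#' Superposition RMSD between two conformers
#'
#' @inheritParams kabsch_superpose
#' @return RMSD in Angstrom after optimal rigid superposition.
#' @export
kabsch_rmsd <- function(mobile, reference, selection = rna_backbone_atoms()) {
  kabsch_superpose(mobile, reference, selection)$rmsd
}

#' Rational switching function
#'
#' Smooth 0-1 contact indicator
#' `s(r) = [1 - x^n] / [1 - x^m]`, `x = (r - d0) / r0`, with the analytic
#' value `n/m` at the removable singularity `x = 1` and `s = 1` for
#' `r <= d0`. For the default exponents `(n, m) = (6, 12)` the exact
#' simplification `1 / (1 + x^6)` is used. Default `r0 = 3` Angstrom,
#' `d0 = 0`.
#'
#' @param r distance(s), Angstrom.
#' @param d0 contact offset, Angstrom (default 0).
#' @param r0 cutoff distance, Angstrom (> 0; default 3).
#' @param n,m rational exponents (default 6 and 12).
#' @return switching value(s) in `(0, 1]`.
#' @export
switching_value <- function(r, d0 = 0, r0 = 3.0, n = 6, m = 12) {
  if (r0 <= 0) stop("`r0` must be positive")
  x <- (r - d0) / r0
  out <- numeric(length(x))
  low <- x <= 0
  out[low] <- 1
  xx <- x[!low]
  if (m == 2 * n) {
    out[!low] <- 1 / (1 + xx^n)
  } else {
    v <- (1 - xx^n) / (1 - xx^m)
    sing <- abs(xx^m - 1) < 1e-10
    v[sing] <- n / m
    out[!low] <- v
  }
  out
}

#' Coordination number between two residue groups
#'
#' `CN_total = sum_{i in A} sum_{j in B} s(r_ij)` over all cross-group
#' atom pairs of the configured selection, with the switching function of
#' [switching_value()]. Default groups are the stem ends, residues 1-4
#' versus 12-15, over all atoms in the dictionary.
#'
#' @param conf a [conformer()].
#' @param group_a,group_b disjoint, nonempty residue index sets.
#' @param d0,r0 switching parameters (Angstrom).
#' @param atom_names optional atom-name restriction (e.g. `"BC"` for a
#'   base-only selection); `NULL` = all atoms.
#' @return dimensionless coordination number.
#' @export
coordination_number <- function(conf, group_a = 1:4, group_b = 12:15,
                                d0 = 0, r0 = 3.0, atom_names = NULL) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("groups must be nonempty")
  if (length(intersect(group_a, group_b)) > 0L)
    stop("groups must be disjoint")
  A <- .sel_coords(conf, atom_names, group_a)
  B <- .sel_coords(conf, atom_names, group_b)
  if (nrow(A) == 0L || nrow(B) == 0L) stop("empty atom selection")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d2[d2 < 0] <- 0
  sum(switching_value(sqrt(d2), d0 = d0, r0 = r0))
}

#' Default stem base pairing of the 15-mer
#' @return 4x2 matrix of paired residue indices (1,15),(2,14),(3,13),(4,12).
#' @export
default_pairing <- function() cbind(1:4, 15:12)

#' Interstrand base-pair distances
#'
#' Distance between the base-centroid pseudo-atoms of each paired residue.
#'
#' @param conf a [conformer()].
#' @param pairing two-column matrix of residue index pairs (default the
#'   stem pairing of [default_pairing()]).
#' @param atom atom name used as the per-base reference point.
#' @return numeric vector of distances (Angstrom), one per pair, in the
#'   order of `pairing`.
#' @export
base_pair_distances <- function(conf, pairing = default_pairing(),
                                atom = "BC") {
  pairing <- as.matrix(pairing)
  if (any(pairing < 1 | pairing > 15)) stop("pair indices must be in 1..15")
  a <- conf$atoms[conf$atoms$atom == atom, , drop = FALSE]
  idx <- match(pairing, a$resid)
  if (anyNA(idx)) stop("missing reference atom for some paired residue")
  p1 <- as.matrix(a[match(pairing[, 1], a$resid), c("x", "y", "z")])
  p2 <- as.matrix(a[match(pairing[, 2], a$resid), c("x", "y", "z")])
  unname(sqrt(rowSums((p1 - p2)^2)))
}

#' Apply a rigid motion to a conformer
#'
#' @param conf a [conformer()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector (Angstrom).
#' @return transformed [conformer()].
#' @export
transform_conformer <- function(conf, rotation = diag(3),
                                translation = c(0, 0, 0)) {
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")])
  xyz <- xyz %*% t(rotation) + matrix(translation, nrow(xyz), 3, byrow = TRUE)
  out <- conf
  out$atoms[, c("x", "y", "z")] <- xyz
  out
}

#' Collective-variable series over a toy trajectory
#'
#' Evaluates the two hairpin collective variables -- backbone RMSD from a
#' reference conformer and the stem coordination number -- on a list of
#' conformers (frames).
#'
#' @param frames list of [conformer()]s.
#' @param reference reference [conformer()] for the RMSD.
#' @param selection RMSD atom selection.
#' @param group_a,group_b,d0,r0,atom_names coordination-number settings.
#' @return data.frame of class `cv_series`: `frame`, `rmsd`, `cn`.
#' @export
compute_cv_series <- function(frames, reference,
                              selection = rna_backbone_atoms(),
                              group_a = 1:4, group_b = 12:15,
                              d0 = 0, r0 = 3.0, atom_names = NULL) {
  rmsd <- vapply(frames, kabsch_rmsd, numeric(1), reference = reference,
                 selection = selection)
  cn <- vapply(frames, coordination_number, numeric(1), group_a = group_a,
               group_b = group_b, d0 = d0, r0 = r0, atom_names = atom_names)
  out <- data.frame(frame = seq_along(frames), rmsd = rmsd, cn = cn)
  class(out) <- c("cv_series", "data.frame")
  out
}
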