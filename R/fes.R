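# Free-energy-surface reconstruction from a hills log, basin detection and
# basin-to-basin free-energy differences.
#
# Well-tempered estimator: F(s) = -(gamma / (gamma - 1)) * V(s), with V the
# accumulated bias; F is reported in kcal/mol, min-shifted to zero.

#' Grid specification spanning a hills log
#'
#' Regular grid covering the deposited hill centers padded by
#' `pad_sigmas` hill widths per dimension.
#'
#' @param hills a [hills_log()].
#' @param n nodes per dimension (default 200 x 200).
#' @param pad_sigmas padding in hill widths (default 5).
#' @return list `(cv1, cv2)` of axis node vectors.
#' @export
fes_grid <- function(hills, n = c(200L, 200L), pad_sigmas = 5) {
  if (nrow(hills) == 0L) stop("empty hills log")
  s1 <- max(hills$sigma_cv1); s2 <- max(hills$sigma_cv2)
  list(cv1 = seq(min(hills$cv1) - pad_sigmas * s1,
                 max(hills$cv1) + pad_sigmas * s1, length.out = n[1]),
       cv2 = seq(min(hills$cv2) - pad_sigmas * s2,
                 max(hills$cv2) + pad_sigmas * s2, length.out = n[2]))
}

#' Sum deposited hills onto a grid
#'
#' Evaluates the accumulated Gaussian bias on a regular grid. Linear in
#' the log: summing two logs equals summing their grids. Optional
#' `weights` rescale each hill's contribution -- used by the checkpoint
#' (tail) averaging of [fes_from_hills()], where hill `k`'s weight is the
#' fraction of checkpoints at which it had already been deposited. A grid
#' coarser than half the smallest hill width records a resolution warning
#' in the `"coarse_warning"` attribute.
#'
#' @param hills a [hills_log()].
#' @param grid list `(cv1, cv2)` of axis nodes (default [fes_grid()]).
#' @param weights optional per-hill weights in `[0, 1]`.
#' @param chunk hills per BLAS block.
#' @return matrix `length(cv1) x length(cv2)` of bias values (kJ/mol) with
#'   attributes `cv1`, `cv2`.
#' @export
sum_hills <- function(hills, grid = fes_grid(hills), weights = NULL,
                      chunk = 4096L) {
  g1 <- grid$cv1; g2 <- grid$cv2
  V <- matrix(0, length(g1), length(g2))
  if (nrow(hills) > 0L) {
    if (min(diff(g1)) > min(hills$sigma_cv1) / 2 ||
        min(diff(g2)) > min(hills$sigma_cv2) / 2)
      attr(V, "coarse_warning") <-
        "grid spacing exceeds half the smallest hill width"
    h <- hills$height
    if (!is.null(weights)) h <- h * weights
    idx <- split(seq_len(nrow(hills)),
                 ceiling(seq_len(nrow(hills)) / chunk))
    for (ii in idx) {
      E1 <- exp(-0.5 * (outer(g1, hills$cv1[ii], "-") /
                          rep(hills$sigma_cv1[ii], each = length(g1)))^2)
      E2 <- exp(-0.5 * (outer(g2, hills$cv2[ii], "-") /
                          rep(hills$sigma_cv2[ii], each = length(g2)))^2)
      V <- V + sweep(E1, 2, h[ii], `*`) %*% t(E2)
    }
  }
  attr(V, "cv1") <- g1
  attr(V, "cv2") <- g2
  V
}

#' Convert a bias grid to a free-energy surface
#'
#' `F(s) = -(gamma / (gamma - 1)) * V(s)`, converted from kJ/mol to
#' kcal/mol and shifted so the grid minimum is zero. In the
#' `gamma -> Inf` limit this is the standard-metadynamics `F = -V`.
#'
#' @param bias bias grid from [sum_hills()] (kJ/mol) with `cv1`/`cv2`
#'   attributes, or a plain matrix plus explicit axes.
#' @param gamma bias factor (> 1; `Inf` allowed).
#' @param cv1,cv2 axis nodes (defaults taken from `bias` attributes).
#' @return object of class `fes_grid_2d`: `cv1`, `cv2`, `F_kcal` matrix,
#'   `gamma`.
#' @export
bias_to_fes <- function(bias, gamma, cv1 = attr(bias, "cv1"),
                        cv2 = attr(bias, "cv2")) {
  if (!(gamma > 1)) stop("`gamma` must exceed 1")
  fac <- if (is.infinite(gamma)) 1 else gamma / (gamma - 1)
  F_kcal <- -fac * bias / .kJ_per_kcal
  F_kcal <- F_kcal - min(F_kcal)
  structure(list(cv1 = cv1, cv2 = cv2, F_kcal = unclass(F_kcal),
                 gamma = gamma),
            class = "fes_grid_2d")
}

#' @export
print.fes_grid_2d <- function(x, ...) {
  cat(sprintf("<fes_grid_2d> %d x %d nodes, cv1 [%.3g, %.3g], cv2 [%.3g, %.3g], max F %.3g kcal/mol\n",
              length(x$cv1), length(x$cv2), min(x$cv1), max(x$cv1),
              min(x$cv2), max(x$cv2), max(x$F_kcal)))
  invisible(x)
}

#' @export
plot.fes_grid_2d <- function(x, levels = pretty(range(x$F_kcal), 12), ...) {
  graphics::image(x$cv1, x$cv2, x$F_kcal, xlab = "rmsd (A)", ylab = "cn",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::contour(x$cv1, x$cv2, x$F_kcal, levels = levels, add = TRUE,
                    col = "white")
  invisible(x)
}

#' Reconstruct the free-energy surface from a hills log
#'
#' Convenience wrapper: [sum_hills()] + [bias_to_fes()]. With
#' `tail_average = M > 1` the well-tempered estimator is averaged over M
#' checkpoints spread over the last half of the deposition history (the
#' standard fluctuation-damping practice); hill weights are the fraction
#' of checkpoints at which each hill was present, so the average costs one
#' weighted grid sum.
#'
#' @param hills a [hills_log()].
#' @param gamma bias factor; default read from the log's `biasf` column.
#' @param grid grid spec (default [fes_grid()]).
#' @param tail_average number of checkpoints (0 or 1 = final bias only).
#' @return a `fes_grid_2d`.
#' @export
fes_from_hills <- function(hills, gamma = NULL, grid = fes_grid(hills),
                           tail_average = 0) {
  if (is.null(gamma)) gamma <- hills$biasf[1]
  w <- NULL
  n <- nrow(hills)
  if (tail_average > 1 && n > 4) {
    cps <- round(seq(ceiling(n / 2), n, length.out = tail_average))
    w <- vapply(seq_len(n), function(k) mean(cps >= k), numeric(1))
  }
  bias_to_fes(sum_hills(hills, grid, weights = w), gamma)
}

# 8-neighbor steepest-descent assignment; ties broken by lowest linear index
.descend_assign <- function(F) {
  n1 <- nrow(F); n2 <- ncol(F)
  pad <- matrix(Inf, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- F
  bestF <- F
  bestI <- matrix(seq_len(n1 * n2), n1, n2)
  shifts <- expand.grid(di = -1:1, dj = -1:1)
  shifts <- shifts[!(shifts$di == 0 & shifts$dj == 0), ]
  idx_mat <- matrix(seq_len(n1 * n2), n1, n2)
  for (s in seq_len(nrow(shifts))) {
    di <- shifts$di[s]; dj <- shifts$dj[s]
    Fn <- pad[(2 + di):(n1 + 1 + di), (2 + dj):(n2 + 1 + dj)]
    In <- matrix(NA_integer_, n1, n2)
    ii <- seq_len(n1) + di; jj <- seq_len(n2) + dj
    ok_i <- ii >= 1 & ii <= n1; ok_j <- jj >= 1 & jj <= n2
    In[ok_i, ok_j] <- idx_mat[ii[ok_i], jj[ok_j]]
    take <- !is.na(In) & (Fn < bestF | (Fn == bestF & In < bestI))
    bestF[take] <- Fn[take]
    bestI[take] <- In[take]
  }
  nxt <- as.integer(bestI)
  # path doubling to the fixed point
  repeat {
    nn <- nxt[nxt]
    if (identical(nn, nxt)) break
    nxt <- nn
  }
  nxt
}

#' Identify basins on a free-energy surface
#'
#' Local minima by 8-neighbor comparison; every node is assigned to a
#' minimum by steepest descent (watershed regions); basin pairs separated
#' by a saddle lower than `min_barrier` above the shallower minimum are
#' merged into the deeper one. Fully deterministic: ties are broken by the
#' lowest linear node index.
#'
#' @param fes a `fes_grid_2d`.
#' @param min_barrier merge threshold, kcal/mol.
#' @return list of basins, each `(label, cv1, cv2, f_min, node, size)`,
#'   ordered by minimum free energy; the watershed assignment is attached
#'   as attribute `assignment` (matrix of basin labels). Empty list if the
#'   surface has no interior minimum structure.
#' @export
find_basins <- function(fes, min_barrier = 1.0) {
  stopifnot(inherits(fes, "fes_grid_2d"))
  F <- fes$F_kcal
  n1 <- nrow(F); n2 <- ncol(F)
  assign <- .descend_assign(F)
  minima <- sort(unique(assign))
  # drop "basins" whose minimum sits on the grid border with no interior
  # structure (monotone surfaces descend off the edge)
  keep <- vapply(minima, function(m) {
    i <- (m - 1) %% n1 + 1; j <- (m - 1) %/% n1 + 1
    !(i == 1 || i == n1 || j == 1 || j == n2) || length(minima) == 1L
  }, logical(1))
  if (length(minima) == 1L) {
    m <- minima[1]
    i <- (m - 1) %% n1 + 1; j <- (m - 1) %/% n1 + 1
    if (i == 1 || i == n1 || j == 1 || j == n2) return(list())
  }
  minima <- minima[keep]
  if (length(minima) == 0L) return(list())
  lab <- match(assign, minima)
  lab[is.na(lab)] <- 0L

  # minimum crossing height between every adjacent basin pair, one pass
  pair_saddles <- function(lab) {
    lm <- matrix(lab, n1, n2)
    a <- integer(0); b <- integer(0); s <- numeric(0)
    for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
      di <- d[1]; dj <- d[2]
      i1 <- max(1, 1 - di):min(n1, n1 - di)
      j1 <- max(1, 1 - dj):min(n2, n2 - dj)
      L1 <- as.vector(lm[i1, j1, drop = FALSE])
      L2 <- as.vector(lm[i1 + di, j1 + dj, drop = FALSE])
      keep <- L1 > 0 & L2 > 0 & L1 != L2
      if (!any(keep)) next
      Fm <- pmax(as.vector(F[i1, j1, drop = FALSE])[keep],
                 as.vector(F[i1 + di, j1 + dj, drop = FALSE])[keep])
      a <- c(a, pmin(L1[keep], L2[keep]))
      b <- c(b, pmax(L1[keep], L2[keep]))
      s <- c(s, Fm)
    }
    if (!length(a)) return(NULL)
    key <- paste(a, b)
    smin <- tapply(s, key, min)
    ab <- do.call(rbind, strsplit(names(smin), " "))
    data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
               saddle = as.numeric(smin))
  }

  repeat {
    labs <- sort(unique(lab[lab > 0]))
    if (length(labs) < 2L) break
    fmin <- vapply(labs, function(l) min(F[lab == l]), numeric(1))
    names(fmin) <- labs
    ps <- pair_saddles(lab)
    if (is.null(ps)) break
    bar <- ps$saddle - pmax(fmin[as.character(ps$a)],
                            fmin[as.character(ps$b)])
    cand <- which(bar < min_barrier)
    if (!length(cand)) break
    k <- cand[order(bar[cand], ps$a[cand], ps$b[cand])][1]
    a <- ps$a[k]; b <- ps$b[k]
    into <- if (fmin[as.character(a)] <= fmin[as.character(b)]) a else b
    from <- if (into == a) b else a
    lab[lab == from] <- into
  }

  labs <- sort(unique(lab[lab > 0]))
  lab_m <- matrix(lab, n1, n2)
  basins <- lapply(labs, function(l) {
    nodes <- which(lab_m == l)
    node <- nodes[which.min(F[nodes])]
    i <- (node - 1) %% n1 + 1; j <- (node - 1) %/% n1 + 1
    list(label = l, cv1 = fes$cv1[i], cv2 = fes$cv2[j], f_min = F[node],
         node = node, size = length(nodes))
  })
  basins <- basins[order(vapply(basins, `[[`, numeric(1), "f_min"))]
  attr(basins, "assignment") <- lab_m
  basins
}

# pick the two deepest basins (the dominant states), then label by RMSD:
# hairpin = lower cv1, open = higher cv1. Using depth first keeps shallow
# boundary artifacts of an unconverged surface out of the comparison.
.pick_basins <- function(basins) {
  two <- basins[1:2]  # find_basins orders by minimum free energy
  cv1s <- c(two[[1]]$cv1, two[[2]]$cv1)
  list(hairpin = two[[which.min(cv1s)]], open = two[[which.max(cv1s)]])
}

#' Free-energy gap between the hairpin and stem-open basins
#'
#' Default convention: difference of basin minima,
#' `delta_g = F_min(hairpin) - F_min(open)` -- positive when the open state
#' is favored, matching how a single number is read off a 2D map. The
#' `"integral"` convention Boltzmann-integrates each watershed region,
#' `G_b = -kT ln sum_region exp(-F / kT) dA`. Both are returned; `delta_g`
#' follows `convention`.
#'
#' @param fes a `fes_grid_2d`.
#' @param basins output of [find_basins()] (>= 2 basins). By default the
#'   hairpin basin is the minimum at lowest `cv1` (RMSD) and the open
#'   basin the one at highest `cv1`.
#' @param hairpin,open optional explicit basin indices into `basins`.
#' @param convention `"minima"` (default) or `"integral"`.
#' @param temperature K, for the integral convention.
#' @return object of class `basin_report`: `delta_g` (kcal/mol),
#'   `delta_g_minima`, `delta_g_integral`, `barrier` (saddle above the
#'   deeper minimum along the min-energy path proxy), `hairpin`, `open`,
#'   `convention`.
#' @export
basin_delta_g <- function(fes, basins, hairpin = NULL, open = NULL,
                          convention = c("minima", "integral"),
                          temperature = 300) {
  convention <- match.arg(convention)
  if (length(basins) < 2L) stop("need at least two basins")
  if (is.null(hairpin) || is.null(open)) {
    pk <- .pick_basins(basins)
    bh <- pk$hairpin; bo <- pk$open
  } else {
    bh <- basins[[hairpin]]; bo <- basins[[open]]
  }
  if (identical(bh$label, bo$label)) stop("basin labels unresolved")
  dg_min <- bh$f_min - bo$f_min
  kT <- .R_kcal * temperature
  lab_m <- attr(basins, "assignment")
  dA <- mean(diff(fes$cv1)) * mean(diff(fes$cv2))
  gint <- function(b) {
    Fb <- fes$F_kcal[lab_m == b$label]
    -kT * log(sum(exp(-Fb / kT)) * dA)
  }
  dg_int <- gint(bh) - gint(bo)
  # barrier proxy: lowest crossing free energy between the two regions
  n1 <- nrow(fes$F_kcal); n2 <- ncol(fes$F_kcal)
  s <- Inf
  for (d in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    di <- d[1]; dj <- d[2]
    i1 <- max(1, 1 - di):min(n1, n1 - di)
    j1 <- max(1, 1 - dj):min(n2, n2 - dj)
    L1 <- lab_m[i1, j1, drop = FALSE]
    L2 <- lab_m[i1 + di, j1 + dj, drop = FALSE]
    F1 <- fes$F_kcal[i1, j1, drop = FALSE]
    F2 <- fes$F_kcal[i1 + di, j1 + dj, drop = FALSE]
    m <- (L1 == bh$label & L2 == bo$label) | (L1 == bo$label & L2 == bh$label)
    if (any(m)) s <- min(s, min(pmax(F1[m], F2[m])))
  }
  structure(list(delta_g = if (convention == "minima") dg_min else dg_int,
                 delta_g_minima = dg_min, delta_g_integral = dg_int,
                 barrier = if (is.finite(s)) s - min(bh$f_min, bo$f_min) else NA_real_,
                 hairpin = bh, open = bo, convention = convention),
            class = "basin_report")
}

#' @export
print.basin_report <- function(x, ...) {
  cat(sprintf("<basin_report> delta_g (%s convention) = %.3f kcal/mol\n",
              x$convention, x$delta_g))
  cat(sprintf("  hairpin basin: (%.2f, %.1f) F = %.3f; open basin: (%.2f, %.1f) F = %.3f; barrier %.2f\n",
              x$hairpin$cv1, x$hairpin$cv2, x$hairpin$f_min,
              x$open$cv1, x$open$cv2, x$open$f_min, x$barrier))
  invisible(x)
}

#' Half-history convergence diagnostic
#'
#' Compares the basin free-energy gap computed from the full hills log
#' with the gap from the log truncated at `fraction` of the deposition
#' history. A converged well-tempered run changes its (shifted) surface
#' only slowly, so the two gaps agree.
#'
#' @param hills a [hills_log()].
#' @param gamma bias factor (default from the log).
#' @param grid grid spec (default spans the full log).
#' @param fraction truncation point (default 0.5).
#' @param min_barrier passed to [find_basins()].
#' @param tail_average passed to [fes_from_hills()].
#' @return list: `delta_g_full`, `delta_g_part`, `diag` (absolute
#'   difference, kcal/mol).
#' @export
fes_convergence <- function(hills, gamma = NULL, grid = fes_grid(hills),
                            fraction = 0.5, min_barrier = 1.0,
                            tail_average = 10) {
  n <- nrow(hills)
  if (n < 8L) stop("too few hills for a convergence diagnostic")
  part <- hills[seq_len(floor(fraction * n)), ]
  class(part) <- class(hills)
  dg <- function(h) {
    f <- fes_from_hills(h, gamma = gamma, grid = grid,
                        tail_average = tail_average)
    b <- find_basins(f)
    if (length(b) < 2L) return(NA_real_)
    basin_delta_g(f, b)$delta_g
  }
  full <- dg(hills)
  partv <- dg(part)
  list(delta_g_full = full, delta_g_part = partv,
       diag = abs(full - partv))
}
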