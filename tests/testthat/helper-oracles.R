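# Independent oracles used across the suite. Each re-derives the target
# quantity by a route disjoint from the package implementation.

# Bound fraction by bisection on the mass balance
# (P - C)(L - C) = Kd * C for the complex concentration C in [0, min(P, L)].
fb_bisect <- function(P, L, Kd, iter = 200) {
  f <- function(C) (P - C) * (L - C) - Kd * C
  lo <- 0
  hi <- min(P, L)
  if (hi == 0) return(0)
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  ((lo + hi) / 2) / L
}

# Coordination number by explicit double loop over all cross-group pairs.
cn_loop <- function(conf, group_a = 1:4, group_b = 12:15, d0 = 0, r0 = 3,
                    atom_names = NULL) {
  a <- conf$atoms
  if (!is.null(atom_names)) a <- a[a$atom %in% atom_names, ]
  A <- a[a$resid %in% group_a, ]
  A <- A[order(A$resid, A$atom), ]
  B <- a[a$resid %in% group_b, ]
  B <- B[order(B$resid, B$atom), ]
  total <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    r <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                (A$z[i] - B$z[j])^2)
    x <- (r - d0) / r0
    total <- total + if (x <= 0) 1 else if (abs(x - 1) < 1e-12) 0.5 else
      (1 - x^6) / (1 - x^12)
  }
  total
}

# Brute-force superposition RMSD by coarse-to-fine search over three Euler
# angles (z-y-z convention), fully independent of the SVD route.
rmsd_grid_oracle <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  rot <- function(a, b, c) {
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  eval_rmsd <- function(a, b, c) {
    sqrt(mean(rowSums((P %*% t(rot(a, b, c)) - Q)^2)))
  }
  search <- function(as, bs, cs) {
    best <- c(Inf, NA, NA, NA)
    for (a in as) for (b in bs) for (c in cs) {
      v <- eval_rmsd(a, b, c)
      if (v < best[1]) best <- c(v, a, b, c)
    }
    best
  }
  d2r <- pi / 180
  b1 <- search(seq(0, 354, 6) * d2r, seq(0, 180, 6) * d2r,
               seq(0, 354, 6) * d2r)
  b2 <- search(b1[2] + seq(-6, 6, 1) * d2r, b1[3] + seq(-6, 6, 1) * d2r,
               b1[4] + seq(-6, 6, 1) * d2r)
  b3 <- search(b2[2] + seq(-1, 1, 0.1) * d2r, b2[3] + seq(-1, 1, 0.1) * d2r,
               b2[4] + seq(-1, 1, 0.1) * d2r)
  b3[1]
}

# Deterministic random rotation matrix (QR of a seeded Gaussian matrix,
# reflection-corrected).
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
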