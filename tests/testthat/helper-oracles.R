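## Independent oracles used by the tests. These deliberately avoid the
## package's own numerical paths: brute-force grid scans, closed forms,
## and an alternative (quaternion) superposition algorithm.

## Dense-grid scan of the tri-molecular mass-balance equation
## K (A - 2C)^2 (D - C) = C on [0, min(A/2, D)]: locate the sign change of
## the residual on an n-point grid and refine once on a finer local grid.
oracle_trimolecular_grid <- function(K, A, D, n = 1e7) {
  upper <- min(A / 2, D)
  f <- function(C) K * (A - 2 * C)^2 * (D - C) - C
  grid_scan <- function(lo, hi, n) {
    C <- seq(lo, hi, length.out = n)
    s <- sign(f(C))
    i <- which(diff(s) < 0)[1L]
    c(C[i], C[i + 1L])
  }
  b <- grid_scan(0, upper, n)
  b <- grid_scan(b[1L], b[2L], 1e5)
  mean(b)
}

## Direct cubic solve of the same equation via polyroot: expand
## K (A - 2C)^2 (D - C) - C = 0 and take the unique root in range.
oracle_trimolecular_cubic <- function(K, A, D) {
  ## K (4C^2 - 4AC + A^2)(D - C) - C
  ## = -4K C^3 + (4K A + 4K D) C^2 - (A^2 K + 4 A D K + 1) C + K A^2 D
  co <- c(K * A^2 * D,
          -(K * A^2 + 4 * K * A * D + 1),
          4 * K * (A + D),
          -4 * K)
  r <- polyroot(co)
  r <- Re(r[abs(Im(r)) < 1e-8 * Mod(r) + 1e-300])
  r <- r[r >= -1e-12 & r <= min(A / 2, D) * (1 + 1e-9)]
  if (length(r) != 1L) stop("cubic oracle found ", length(r), " roots in range")
  r
}

## Brute 2-D scan for the sequential two-site model: log-spaced free-dimer
## grid, free duplex from the duplex balance (algebraic), pick the grid
## point minimizing the dimer-balance residual, then refine.
oracle_sequential_grid <- function(K1, K2, A_tot, D_tot, n = 2e5) {
  resid <- function(a) {
    d <- D_tot / (1 + K1 * a + K1 * K2 * a^2)
    abs(a + (K1 * a + 2 * K1 * K2 * a^2) * d - A_tot)
  }
  scan <- function(lo, hi) {
    a <- seq(lo, hi, length.out = n)
    a[which.min(resid(a))]
  }
  a <- scan(0, A_tot)
  step <- A_tot / (n - 1)
  a <- scan(max(0, a - step), min(A_tot, a + step))
  d <- D_tot / (1 + K1 * a + K1 * K2 * a^2)
  list(dimer = a, D = d, A2D = K1 * a * d, A4D = K1 * K2 * a^2 * d)
}

## Horn's quaternion absolute-orientation method: independent of the
## SVD-based Kabsch implementation.
oracle_quaternion_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  M <- crossprod(Pc, Qc)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  N <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,    -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,    -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  moved <- Pc %*% t(R)
  sqrt(mean(rowSums((moved - Qc)^2)))
}

## Analytic SASA of two intersecting spheres of equal radius r at
## centre separation s (s < 2r): each loses a spherical cap of height
## h = r - s/2, cap area 2 pi r h.
oracle_two_sphere_sasa <- function(r, s) {
  h <- r - s / 2
  2 * (4 * pi * r^2 - 2 * pi * r * h)
}

## Analytic sphere form factor (normalized to 1 at q = 0).
sphere_form_factor <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

## Shared small fixtures -----------------------------------------------

make_test_protocol <- function(cell_conc = 1.8e-6, syringe_conc = 8e-6,
                               n = 25L, inj = 2) {
  titration_protocol(cell_conc = cell_conc, syringe_conc = syringe_conc,
                     injection_volumes = rep(inj, n))
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
}

## Build a two-chain structure_model from stacked coordinates (first half
## chain A, second half chain B), carbon atoms throughout.
coords_model_for_test <- function(xyz) {
  n <- nrow(xyz); h <- n %/% 2
  df <- data.frame(chain = rep(c("A", "B"), c(h, n - h)),
                   resid = seq_len(n), icode = "", resname = "ALA",
                   atom = "CA", element = "C",
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   occupancy = 1, het = FALSE, stringsAsFactors = FALSE)
  structure(df, class = c("structure_model", "data.frame"),
            source = "synthetic")
}

## A compact, helix-like rigid tail grafted at `anchor`: stand-in for a
## folded-N-terminus comparison model (synthetic, not a deposited fold).
helix_like_tail <- function(anchor, n) {
  i <- seq_len(n) - 1
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang) + anchor[1] + 3,
        2.3 * sin(ang) + anchor[2],
        1.5 * i + anchor[3])
}
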