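## Scattering profiles, Guinier analysis and dimensionless Kratky plots.

#' Scattering profile container
#'
#' A small-angle scattering curve: momentum transfer `q` (A^-1, strictly
#' increasing, positive), intensities `I`, and per-point uncertainties
#' `sigma` (synthesized as 1% of `I` when absent).
#'
#' @param q momentum transfer grid, A^-1.
#' @param I intensities (arbitrary units, finite).
#' @param sigma optional uncertainties, same units as `I`, > 0.
#' @return Object of class `scattering_profile`.
#' @export
scattering_profile <- function(q, I, sigma = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop_domain("`q` and `I` lengths differ")
  if (any(!is.finite(q)) || any(q <= 0)) stop_domain("`q` must be finite and > 0")
  if (any(diff(q) <= 0)) stop_domain("`q` must be strictly increasing")
  if (any(!is.finite(I))) stop_domain("`I` must be finite")
  if (is.null(sigma)) {
    sigma <- 0.01 * abs(I)
    sigma[sigma <= 0] <- 0.01 * max(abs(I), 1e-12)
  } else {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop_domain("`sigma` length differs from `q`")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop_domain("`sigma` must be finite and > 0")
  }
  structure(list(q = q, I = I, sigma = sigma), class = "scattering_profile")
}

#' @export
print.scattering_profile <- function(x, ...) {
  cat(sprintf("Scattering profile: %d points, q in [%.4g, %.4g] A^-1\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Guinier fit of the low-q region
#'
#' Iterative Guinier analysis: fit `ln I` vs `q^2` on the lowest-q points,
#' compute `Rg = sqrt(-3 * slope)`, then shrink the window until
#' `q_max * Rg <= qrg_limit` and the window is a fixed point. `I(0)` is the
#' exponential of the intercept.
#'
#' @param profile a [scattering_profile()].
#' @param qrg_limit window rule cut-off, dimensionless; classical default 1.3.
#' @param min_points minimum points in the fit window (default 8).
#' @return Object of class `guinier_result`: `Rg` (A), `I0`, `fit_window`
#'   `(q_min, q_max)`, `n_points`, `r_squared`.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 8L) {
  if (!inherits(profile, "scattering_profile"))
    stop_domain("`profile` must be a scattering_profile")
  q <- profile$q; I <- profile$I
  pos <- I > 0
  if (sum(pos & seq_along(q) <= max(min_points, 20L)) < min_points)
    stop_domain("too few positive low-q intensities for a Guinier fit")

  window <- seq_along(q)
  Rg <- NA_real_; I0 <- NA_real_; r2 <- NA_real_
  for (iter in seq_len(50L)) {
    idx <- window[pos[window]]
    if (length(idx) < min_points)
      stop_domain("Guinier window shrank below ", min_points, " points")
    x <- q[idx]^2; y <- log(I[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- unname(fit$coefficients[2])
    if (!is.finite(slope) || slope >= 0)
      stop_domain("no Guinier region: non-negative low-q slope (aggregation-like input)")
    Rg <- sqrt(-3 * slope)
    I0 <- exp(unname(fit$coefficients[1]))
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    new_window <- which(q <= qrg_limit / Rg)
    if (length(new_window) < min_points)
      new_window <- seq_len(min_points)
    if (identical(new_window, window)) break
    window <- new_window
  }
  idx <- window[pos[window]]
  structure(list(Rg = Rg, I0 = I0,
                 fit_window = c(q_min = min(q[idx]), q_max = max(q[idx])),
                 n_points = length(idx), r_squared = r2),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.3f A, I0 = %.4g (%d pts, qmax*Rg = %.2f, R2 = %.4f)\n",
              x$Rg, x$I0, x$n_points, x$fit_window[["q_max"]] * x$Rg,
              x$r_squared))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Rescales a profile to `x = q*Rg`, `y = x^2 * I(q)/I(0)`. On these axes a
#' globular particle peaks at `(sqrt(3), 3/e = 1.104)` while an ideal random
#' coil rises monotonically to an asymptote of 2, making the plot a
#' shape-independent foldedness diagnostic. No smoothing is applied here.
#'
#' @param profile a [scattering_profile()].
#' @param Rg radius of gyration, A (> 0).
#' @param I0 forward scattering (> 0).
#' @return Object of class `kratky_curve` with fields `x`, `y`.
#' @export
dimensionless_kratky <- function(profile, Rg, I0) {
  if (!inherits(profile, "scattering_profile"))
    stop_domain("`profile` must be a scattering_profile")
  assert_scalar_finite(Rg, "Rg"); assert_scalar_finite(I0, "I0")
  if (Rg <= 0) stop_domain("`Rg` must be > 0")
  if (I0 <= 0) stop_domain("`I0` must be > 0")
  x <- profile$q * Rg
  structure(list(x = x, y = x^2 * profile$I / I0), class = "kratky_curve")
}

#' Analytic Kratky reference: globular (Guinier-law) particle
#'
#' For a globular scatterer obeying `I(q)/I(0) = exp(-x^2/3)` with
#' `x = q*Rg`, the dimensionless Kratky curve is `y = x^2 exp(-x^2/3)`,
#' with maximum `3/e ~= 1.104` at `x = sqrt(3)`.
#'
#' @param x dimensionless `q*Rg` (>= 0).
#' @return `y` values.
#' @export
theoretical_kratky_globular <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop_domain("`x` must be finite and >= 0")
  x^2 * exp(-x^2 / 3)
}

#' Analytic Kratky reference: ideal random coil (Debye law)
#'
#' The Debye form factor of an ideal Gaussian chain,
#' `I(q)/I(0) = 2 (exp(-x^2) - 1 + x^2) / x^4`, transforms to
#' `y = 2 (exp(-x^2) - 1 + x^2) / x^2`, which increases monotonically with
#' asymptote 2. The `x = 0` limit is 0.
#'
#' @param x dimensionless `q*Rg` (>= 0).
#' @return `y` values.
#' @export
theoretical_kratky_debye <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) stop_domain("`x` must be finite and >= 0")
  y <- numeric(length(x))
  nz <- x > 1e-6
  y[nz] <- 2 * (exp(-x[nz]^2) - 1 + x[nz]^2) / x[nz]^2
  ## series: 2(x^2 - x^2 + x^4/2 - ...)/x^2 -> x^2 - x^4/3 + ...
  y[!nz] <- x[!nz]^2
  y
}

## Savitzky-Golay style local polynomial smoothing, symmetric window.
## Edge points are fitted with the nearest full window.
sg_smooth <- function(y, window = 7L, order = 2L) {
  n <- length(y)
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (n < window) return(y)
  half <- (window - 1L) %/% 2L
  t <- seq(-half, half)
  X <- outer(t, 0:order, `^`)
  ## convolution weights for the centre point of each window
  w <- solve(crossprod(X), t(X))[1L, ]
  out <- y
  for (i in seq_len(n)) {
    lo <- min(max(1L, i - half), n - window + 1L)
    seg <- y[lo:(lo + window - 1L)]
    if (i - half >= 1L && i + half <= n) {
      out[i] <- sum(w * seg)
    } else {
      ## asymmetric edge: evaluate the local fit at the right offset
      off <- i - lo - half
      coef <- solve(crossprod(X), crossprod(X, seg))
      out[i] <- sum(coef * off^(0:order))
    }
  }
  out
}

#' Locate the maximum of a Kratky curve
#'
#' Smooths the curve with a local-polynomial (Savitzky-Golay) filter and
#' finds the maximum restricted to `x <= x_max`. Returns `NULL` when the
#' smoothed curve is monotone increasing over the range (the random-coil
#' signature). The peak abscissa is refined by a parabola through the
#' neighbouring grid points.
#'
#' @param curve a `kratky_curve` (from [dimensionless_kratky()]) or any
#'   list with `x`, `y`.
#' @param smooth_window smoothing window in points (odd; default 7).
#' @param x_max restrict the search to `x <= x_max` (default 4).
#' @return `c(x, y)` of the peak, or `NULL` if none.
#' @export
find_kratky_maximum <- function(curve, smooth_window = 7L, x_max = 4) {
  x <- curve$x; y <- curve$y
  if (length(x) < smooth_window) stop_domain("fewer points than `smooth_window`")
  keep <- x <= x_max
  if (sum(keep) < 3L) return(NULL)
  xs <- x[keep]
  ys <- sg_smooth(y[keep], window = smooth_window)
  i <- which.max(ys)
  if (i >= length(ys)) return(NULL)          # still rising at the edge
  if (i == 1L) return(c(x = xs[1L], y = ys[1L]))
  ## parabolic refinement on the three points around the grid maximum
  x3 <- xs[(i - 1):(i + 1)]; y3 <- ys[(i - 1):(i + 1)]
  denom <- (x3[1] - x3[2]) * (x3[1] - x3[3]) * (x3[2] - x3[3])
  a <- (x3[3] * (y3[2] - y3[1]) + x3[2] * (y3[1] - y3[3]) +
          x3[1] * (y3[3] - y3[2])) / denom
  b <- (x3[3]^2 * (y3[1] - y3[2]) + x3[2]^2 * (y3[3] - y3[1]) +
          x3[1]^2 * (y3[2] - y3[3])) / denom
  if (a < 0) {
    xp <- -b / (2 * a)
    if (xp >= x3[1] && xp <= x3[3]) {
      cc <- y3[2] - a * x3[2]^2 - b * x3[2]
      return(c(x = xp, y = a * xp^2 + b * xp + cc))
    }
  }
  c(x = xs[i], y = ys[i])
}

#' Classify foldedness from a Kratky maximum
#'
#' A globular particle peaks near `(sqrt(3), 1.104)`; partial disorder
#' shifts the maximum up and to the right; a fully disordered chain has no
#' maximum at all. The default thresholds (`x* <= 1.9`, `y* <= 1.17`) sit
#' midway between the analytic globular peak and the peak observed for a
#' partially disordered toxin (2.0, 1.22).
#'
#' @param peak `c(x, y)` from [find_kratky_maximum()], or `NULL`.
#' @param x_threshold,y_threshold globular classification limits.
#' @return One of `"globular"`, `"partially_disordered"`, `"disordered"`.
#' @export
classify_foldedness <- function(peak, x_threshold = 1.9, y_threshold = 1.17) {
  if (is.null(peak)) return("disordered")
  if (peak[[1]] <= x_threshold && peak[[2]] <= y_threshold) "globular"
  else "partially_disordered"
}

#' Porod volume and molecular weight estimate
#'
#' Computes the Porod invariant `Q = integral q^2 I(q) dq` by trapezoid,
#' after subtracting a constant background chosen so that `q^4 I` flattens
#' at high q, and extending the integral below `q_min` with the Guinier
#' model and above `q_max` with the Porod `K/q^4` tail. The Porod volume is
#' `V_p = 2 pi^2 I(0) / Q` and the molecular weight estimate
#' `MW = V_p / divisor` (default divisor 1.66 A^3/Da, an empirical protein
#' packing density).
#'
#' @param profile a [scattering_profile()] extending to `q*Rg >= 5`.
#' @param guinier a `guinier_result` for the same curve.
#' @param divisor volume-to-mass divisor, A^3/Da.
#' @param background_fraction fraction of the high-q end used to estimate
#'   the Porod plateau and flat background (default 0.3).
#' @return List with `porod_volume` (A^3), `mw_from_vp` (kDa), `Q`, and
#'   `background`.
#' @export
porod_mw_estimates <- function(profile, guinier, divisor = 1.66,
                               background_fraction = 0.3) {
  if (!inherits(profile, "scattering_profile"))
    stop_domain("`profile` must be a scattering_profile")
  q <- profile$q; I <- profile$I
  Rg <- guinier$Rg; I0 <- guinier$I0
  if (max(q) * Rg < 5)
    stop_domain("insufficient q range: need q*Rg >= 5 (have ",
                sprintf("%.2f", max(q) * Rg), ")")
  ## constant background from the high-q tail, fitted on the Porod scale:
  ## q^4 I = Kp + B q^4, so that q^4 (I - B) flattens at the plateau Kp
  ntail <- max(5L, round(background_fraction * length(q)))
  ti <- seq(length(q) - ntail + 1L, length(q))
  cf <- stats::lm.fit(cbind(1, q[ti]^4), q[ti]^4 * I[ti])$coefficients
  Kp <- max(0, cf[1]); B <- max(0, cf[2])
  Isub <- pmax(I - B, 0)
  ## low-q completion with the Guinier model on [0, q_min]
  qlow <- seq(0, q[1], length.out = 50L)
  Ilow <- I0 * exp(-(qlow * Rg)^2 / 3)
  Qlow <- sum(diff(qlow) * (qlow[-1]^2 * Ilow[-1] +
                              qlow[-length(qlow)]^2 * Ilow[-length(qlow)]) / 2)
  Qdata <- sum(diff(q) * (q[-1]^2 * Isub[-1] +
                            q[-length(q)]^2 * Isub[-length(q)]) / 2)
  Qtail <- Kp / max(q)                       # integral of Kp/q^2 beyond q_max
  Q <- Qlow + Qdata + Qtail
  Vp <- 2 * pi^2 * I0 / Q
  list(porod_volume = Vp, mw_from_vp = Vp / divisor / 1000, Q = Q,
       background = B)
}
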