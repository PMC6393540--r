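## Closed-cell ITC simulation and fitting for the tri-molecular model.
##
## Titration direction is duplex-into-dimer: the cell holds the protein
## dimer, the syringe the operator duplex, so the equivalence point on the
## injectant:cell molar-ratio axis sits at 0.5 (two dimers consumed per
## duplex).

## Deterministic per-injection model. Returns in-cell totals, complex
## concentration and normalized heats (kcal per mole of injectant).
itc_model_ndh <- function(params, protocol, perfusion = c("simple", "trapezoid"),
                          dilution = TRUE) {
  perfusion <- match.arg(perfusion)
  V0 <- protocol$cell_volume * 1e-6            # L
  dv <- protocol$injection_volumes * 1e-6      # L
  n <- length(dv)
  A_tot <- protocol$cell_conc                  # dimer in cell, M
  D_tot <- 0                                   # duplex in cell, M
  C_prev <- 0
  ndh <- numeric(n)
  ratio <- numeric(n)
  complex <- numeric(n)
  a_tot <- numeric(n); d_tot <- numeric(n)
  for (i in seq_len(n)) {
    f <- if (dilution) 1 - dv[i] / V0 else 1
    ## Trapezoidal variant: injectant enters at the mid-injection average
    ## concentration factor, the classical instrument correction.
    finj <- if (perfusion == "trapezoid" && dilution) 1 - dv[i] / (2 * V0) else 1
    A_tot <- A_tot * f
    D_tot <- D_tot * f + finj * dv[i] * protocol$syringe_conc / V0
    st <- solve_trimolecular_equilibrium(params$K_A, A_tot, D_tot)
    Ci <- st$complex
    ## Heat released in injection i: change in complex moles in the cell,
    ## accounting for displaced (pre-injection) complex leaving the cell.
    heat <- V0 * params$dH * (Ci - C_prev * f)
    moles_inj <- dv[i] * protocol$syringe_conc
    ndh[i] <- heat / moles_inj + params$offset
    ratio[i] <- D_tot / A_tot
    complex[i] <- Ci
    a_tot[i] <- A_tot; d_tot[i] <- D_tot
    C_prev <- Ci
  }
  list(ndh = ndh, molar_ratio = ratio, complex = complex,
       dimer_total = a_tot, duplex_total = d_tot)
}

#' Simulate a cooperative ITC isotherm
#'
#' Simulates per-injection normalized heats for a duplex-into-dimer
#' titration under the tri-molecular cooperative model, with the standard
#' perfusion (displaced-volume) dilution: each injected volume `dv`
#' multiplies existing cell totals by `(1 - dv/V0)` and adds injectant at
#' `dv * syringe_conc / V0`. The heat of injection `i` is
#' `V0 * dH * (C_i - C_{i-1} * (1 - dv_i/V0))`, normalized per mole of
#' injected duplex; the constant offset and seeded Gaussian noise are then
#' added.
#'
#' @param params [binding_parameters()].
#' @param protocol [titration_protocol()].
#' @param noise_sd Gaussian noise SD on normalized heats, kcal/mol (>= 0).
#' @param seed integer seed; the simulation is deterministic given the seed.
#' @param perfusion `"simple"` (default) or `"trapezoid"` mid-injection
#'   averaging of the injectant term.
#' @param dilution logical; set `FALSE` to disable displacement entirely
#'   (useful for heat-conservation checks).
#' @return An object of class `titration_experiment`: list with `protocol`,
#'   `ndh` (kcal/mol of injectant), `sigma`, `molar_ratio` (cumulative
#'   in-cell duplex:dimer ratio, strictly increasing), `complex`, and
#'   metadata (`seed`, `params_true`).
#' @examples
#' p <- titration_protocol(cell_conc = 1.8e-6, syringe_conc = 8e-6,
#'                         injection_volumes = rep(2, 25))
#' sim <- simulate_isotherm(binding_parameters(3e13, -19), p,
#'                          noise_sd = 0.19, seed = 1)
#' @export
simulate_isotherm <- function(params, protocol, noise_sd = 0, seed = 1,
                              perfusion = c("simple", "trapezoid"),
                              dilution = TRUE) {
  if (!inherits(params, "binding_parameters"))
    stop_domain("`params` must be a binding_parameters object")
  if (!inherits(protocol, "titration_protocol"))
    stop_domain("`protocol` must be a titration_protocol object")
  assert_nonneg(noise_sd, "noise_sd")
  perfusion <- match.arg(perfusion)

  m <- itc_model_ndh(params, protocol, perfusion = perfusion,
                     dilution = dilution)
  n <- length(m$ndh)
  noise <- if (noise_sd > 0)
    with_seed(seed, stats::rnorm(n, 0, noise_sd)) else numeric(n)
  structure(list(protocol = protocol,
                 ndh = m$ndh + noise,
                 sigma = rep(noise_sd, n),
                 molar_ratio = m$molar_ratio,
                 complex = m$complex,
                 seed = seed,
                 perfusion = perfusion,
                 params_true = params),
            class = "titration_experiment")
}

#' @export
print.titration_experiment <- function(x, ...) {
  cat(sprintf("ITC titration: %d injections, cell %.3g M, syringe %.3g M\n",
              length(x$ndh), x$protocol$cell_conc, x$protocol$syringe_conc))
  cat(sprintf("  molar ratio %.3g .. %.3g, ndh %.3g .. %.3g kcal/mol\n",
              min(x$molar_ratio), max(x$molar_ratio),
              min(x$ndh), max(x$ndh)))
  invisible(x)
}

## Small Levenberg-Marquardt on a residual function; numeric Jacobian.
## Returns par, converged flag, rss, jacobian at solution.
lm_minimize <- function(resid_fn, par, maxit = 200L, tol = 1e-12) {
  r <- resid_fn(par)
  rss <- sum(r^2)
  lambda <- 1e-3
  np <- length(par)
  conv <- FALSE
  J <- NULL
  for (it in seq_len(maxit)) {
    J <- vapply(seq_len(np), function(j) {
      h <- max(1e-7, 1e-7 * abs(par[j]))
      pj <- par; pj[j] <- pj[j] + h
      (resid_fn(pj) - r) / h
    }, numeric(length(r)))
    g <- crossprod(J, r)
    H <- crossprod(J)
    improved <- FALSE
    for (k in seq_len(30L)) {
      step <- tryCatch(
        solve(H + lambda * diag(diag(H) + 1e-12, np), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        pn <- par + as.numeric(step)
        rn <- resid_fn(pn)
        rssn <- sum(rn^2)
        if (is.finite(rssn) && rssn <= rss) {
          rel <- (rss - rssn) / max(rss, 1e-300)
          par <- pn; r <- rn
          lambda <- max(lambda / 3, 1e-12)
          improved <- TRUE
          if (rel < tol || rssn < 1e-300) conv <- TRUE
          rss <- rssn
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!improved) { conv <- TRUE; break }
    if (conv) break
  }
  list(par = par, converged = conv, rss = rss, jacobian = J,
       residuals = r)
}

#' Fit the cooperative model to a titration
#'
#' Least-squares fit of (`log10(K_A)`, `dH`, `offset`) to the normalized
#' heats of a [titration_experiment]. Optimizing `log10(K_A)` rather than
#' `K_A` conditions the problem across the many-decade range of realistic
#' constants. Three starts spanning +/- 2 decades in `K_A` guard against
#' local minima on steep isotherms; each start is refined by
#' Levenberg-Marquardt. Asymptotic standard errors come from the Jacobian
#' at the optimum, and the free energy `dG = -RT ln(K_A)` is reported at
#' 25 C.
#'
#' @param exp a `titration_experiment` (>= 5 injections).
#' @param init optional [binding_parameters()] initial guess; `NULL` for an
#'   automatic start.
#' @param discard_first drop the first injection before fitting (common
#'   practice for real exported data). Default `FALSE`.
#' @return An object of class `itc_fit`: list with `K_A`, `log10_K_A`,
#'   `dH`, `offset`, `dG_kcal_mol`, standard errors (`se_log10_K_A`,
#'   `se_dH`, `se_offset`), `converged`, `k_lower_bound` (flag for a flat,
#'   K-uninformative isotherm), `residuals`, `residual_rms`,
#'   `n_injections`.
#' @examples
#' p <- titration_protocol(cell_conc = 1.8e-6, syringe_conc = 8e-6,
#'                         injection_volumes = rep(2, 25))
#' sim <- simulate_isotherm(binding_parameters(3e13, -19), p, 0.19, seed = 1)
#' fit <- fit_isotherm(sim)
#' @export
fit_isotherm <- function(exp, init = NULL, discard_first = FALSE) {
  if (!inherits(exp, "titration_experiment"))
    stop_domain("`exp` must be a titration_experiment")
  if (length(exp$ndh) < 5L)
    stop_domain("need at least 5 injections to fit")
  protocol <- exp$protocol
  keep <- seq_along(exp$ndh)
  if (discard_first) keep <- keep[-1L]
  obs <- exp$ndh[keep]

  model_ndh <- function(theta) {
    ## clamp the search to physically sensible decades so trial steps
    ## cannot overflow K_A
    logK <- min(max(theta[1], -5), 30)
    p <- binding_parameters(K_A = 10^logK, dH = theta[2],
                            offset = theta[3])
    itc_model_ndh(p, protocol, perfusion = exp$perfusion %||% "simple")$ndh[keep]
  }
  resid_fn <- function(theta) obs - model_ndh(theta)

  ## Automatic start: offset from the saturated tail, dH from the first
  ## heats, K_A scaled so the dimensionless steepness K_A * A^2 ~ 100.
  n <- length(obs)
  tail_n <- max(3L, round(n / 5))
  offset0 <- mean(obs[(n - tail_n + 1L):n])
  dH0 <- obs[1L] - offset0
  if (abs(dH0) < 1e-6) dH0 <- -1
  logK0 <- 2 - 2 * log10(protocol$cell_conc)
  if (!is.null(init)) {
    if (!inherits(init, "binding_parameters"))
      stop_domain("`init` must be a binding_parameters object")
    logK0 <- log10(max(init$K_A, 1e-30))
    dH0 <- init$dH
    offset0 <- init$offset
  }

  starts <- lapply(c(-2, 0, 2), function(d) c(logK0 + d, dH0, offset0))
  fits <- lapply(starts, function(s) lm_minimize(resid_fn, s))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "rss"))]]

  theta <- best$par
  ## Standard errors from the Jacobian of the model (J of residuals has
  ## opposite sign; J'J identical).
  J <- best$jacobian
  dof <- max(length(obs) - length(theta), 1L)
  s2 <- best$rss / dof
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, 3) else sqrt(pmax(diag(cov), 0))
  k_lower_bound <- is.null(cov) || !is.finite(se[1]) || se[1] > 2

  K_A <- 10^theta[1]
  structure(list(K_A = K_A,
                 log10_K_A = theta[1],
                 dH = theta[2],
                 offset = theta[3],
                 dG_kcal_mol = -.R_KCAL * .T_STANDARD * log(K_A),
                 se_log10_K_A = se[1], se_dH = se[2], se_offset = se[3],
                 converged = isTRUE(best$converged),
                 k_lower_bound = k_lower_bound,
                 residuals = best$residuals,
                 residual_rms = sqrt(mean(best$residuals^2)),
                 n_injections = length(obs)),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat(sprintf("Cooperative fit (%d injections)%s\n", x$n_injections,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  K_A    = %.3g M^-2  (log10 = %.3f +/- %.3f)%s\n",
              x$K_A, x$log10_K_A, x$se_log10_K_A,
              if (x$k_lower_bound) "  [lower bound]" else ""))
  cat(sprintf("  dG     = %.2f kcal/mol\n", x$dG_kcal_mol))
  cat(sprintf("  dH     = %.2f +/- %.2f kcal/mol\n", x$dH, x$se_dH))
  cat(sprintf("  offset = %.3f kcal/mol, residual rms = %.3g\n",
              x$offset, x$residual_rms))
  invisible(x)
}
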