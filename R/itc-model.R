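## Tri-molecular cooperative binding model
##
## The autorepressor binds its operator as two dimers in a single
## concerted step,
##
##     2 A2 + D  <=>  A4D,      K_A = [A4D] / ([A2]^2 [D])   (M^-2)
##
## with no detectable singly-bound intermediate. K_A is the macroscopic
## association constant of the overall tri-molecular reaction.

#' Binding parameters of the tri-molecular cooperative model
#'
#' Container for the fitted/simulated quantities of a cooperative
#' dimer-pair/operator titration: the macroscopic association constant, the
#' molar binding enthalpy, and a constant per-injection background heat.
#'
#' @param K_A macroscopic association constant of the reaction
#'   `2 dimer + duplex <=> complex`, in M^-2. Must be >= 0 and finite.
#' @param dH molar enthalpy of complex formation, kcal per mole of duplex
#'   incorporated (one duplex per complex).
#' @param offset constant background heat per injection, kcal per mole of
#'   injectant. Default 0.
#' @return An object of class `binding_parameters`.
#' @examples
#' binding_parameters(K_A = 3e13, dH = -19)
#' @export
binding_parameters <- function(K_A, dH, offset = 0) {
  assert_scalar_finite(K_A, "K_A")
  if (K_A < 0) stop_domain("`K_A` must be >= 0")
  assert_scalar_finite(dH, "dH")
  assert_scalar_finite(offset, "offset")
  structure(list(K_A = K_A, dH = dH, offset = offset),
            class = "binding_parameters")
}

#' @export
print.binding_parameters <- function(x, ...) {
  cat(sprintf("Binding parameters: K_A = %.4g M^-2, dH = %.4g kcal/mol, offset = %.4g kcal/mol\n",
              x$K_A, x$dH, x$offset))
  invisible(x)
}

#' Titration protocol for a closed-cell ITC experiment
#'
#' Describes a duplex-into-dimer titration: the cell holds the protein
#' species (antitoxin dimer, or toxin-antitoxin heterotetramer), the syringe
#' the operator DNA duplex.
#'
#' @param cell_volume working cell volume, microlitres. Default 200.
#' @param cell_conc cell species concentration (protein dimer), mol/L.
#' @param syringe_conc syringe species concentration (DNA duplex), mol/L.
#' @param injection_volumes ordered vector of injection volumes, microlitres.
#' @return An object of class `titration_protocol`.
#' @examples
#' titration_protocol(cell_conc = 20e-6, syringe_conc = 90e-6,
#'                    injection_volumes = rep(2, 20))
#' @export
titration_protocol <- function(cell_volume = 200, cell_conc, syringe_conc,
                               injection_volumes) {
  assert_scalar_finite(cell_volume, "cell_volume")
  assert_scalar_finite(cell_conc, "cell_conc")
  assert_scalar_finite(syringe_conc, "syringe_conc")
  if (cell_volume <= 0) stop_domain("`cell_volume` must be > 0")
  if (cell_conc <= 0) stop_domain("`cell_conc` must be > 0")
  if (syringe_conc <= 0) stop_domain("`syringe_conc` must be > 0")
  if (length(injection_volumes) < 1L || any(!is.finite(injection_volumes)) ||
      any(injection_volumes <= 0))
    stop_domain("`injection_volumes` must be a non-empty vector of positive volumes")
  structure(list(cell_volume = cell_volume, cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes = as.numeric(injection_volumes)),
            class = "titration_protocol")
}

#' Solve the tri-molecular binding equilibrium
#'
#' Finds the unique complex concentration `C` in
#' `[0, min(dimer_total/2, duplex_total)]` satisfying the mass-action /
#' mass-balance equation of the concerted reaction
#' `2 dimer + duplex <=> complex`:
#'
#'     K_A * (dimer_total - 2C)^2 * (duplex_total - C) = C
#'
#' The left-hand side minus the right-hand side is strictly decreasing in
#' `C` on that interval, so the physical root is unique; it is located by
#' bisection followed by Newton polishing.
#'
#' @param K_A macroscopic association constant, M^-2 (>= 0, finite).
#' @param dimer_total total dimer concentration, M.
#' @param duplex_total total duplex concentration, M.
#' @return An object of class `speciation_state`: a list with `free_dimer`,
#'   `free_duplex` and `complex` concentrations (M).
#' @examples
#' solve_trimolecular_equilibrium(3e13, 20e-6, 5e-6)
#' @export
solve_trimolecular_equilibrium <- function(K_A, dimer_total, duplex_total) {
  assert_nonneg(K_A, "K_A")
  assert_nonneg(dimer_total, "dimer_total")
  assert_nonneg(duplex_total, "duplex_total")

  upper <- min(dimer_total / 2, duplex_total)
  f <- function(C) K_A * (dimer_total - 2 * C)^2 * (duplex_total - C) - C

  if (K_A == 0 || upper == 0) {
    C <- 0
  } else {
    lo <- 0; hi <- upper
    ## f(lo) >= 0, f(hi) = -hi < 0: bisect the guaranteed bracket.
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
      if ((hi - lo) <= 1e-12 * max(1e-30, upper)) break
    }
    C <- (lo + hi) / 2
    ## Newton polish (derivative analytic); stay inside the bracket.
    for (i in seq_len(4L)) {
      A <- dimer_total - 2 * C
      D <- duplex_total - C
      fp <- K_A * (-4 * A * D - A^2) - 1
      step <- f(C) / fp
      Cn <- C - step
      if (!is.finite(Cn) || Cn < lo || Cn > hi) break
      C <- Cn
    }
  }
  structure(list(free_dimer = dimer_total - 2 * C,
                 free_duplex = duplex_total - C,
                 complex = C),
            class = "speciation_state")
}

#' Speciation along a dimer:duplex titration
#'
#' Computes the tri-molecular speciation over a grid of dimer:duplex molar
#' ratios at fixed total duplex concentration, e.g. to locate the ratio at
#' which the operator saturates (2:1 for the concerted two-dimer model).
#'
#' @param K_A macroscopic association constant, M^-2.
#' @param duplex_total total duplex concentration, M.
#' @param dimer_ratios vector of dimer:duplex molar ratios (>= 0).
#' @return A data.frame with columns `ratio`, `free_dimer`, `free_duplex`,
#'   `complex`, and `bound_fraction` (fraction of duplex in complex).
#' @examples
#' speciation_curve(1e20, 5e-6, seq(0, 4, by = 0.1))
#' @export
speciation_curve <- function(K_A, duplex_total, dimer_ratios) {
  assert_nonneg(K_A, "K_A")
  assert_nonneg(duplex_total, "duplex_total")
  if (any(!is.finite(dimer_ratios)) || any(dimer_ratios < 0))
    stop_domain("`dimer_ratios` must be finite and >= 0")
  rows <- lapply(dimer_ratios, function(r) {
    st <- solve_trimolecular_equilibrium(K_A, r * duplex_total, duplex_total)
    data.frame(ratio = r, free_dimer = st$free_dimer,
               free_duplex = st$free_duplex, complex = st$complex,
               bound_fraction = if (duplex_total > 0) st$complex / duplex_total else 0)
  })
  do.call(rbind, rows)
}

#' Sequential (two-step) two-site binding model
#'
#' Contrast model to the concerted tri-molecular reaction: the two dimers
#' bind stepwise,
#' `A2 + D <=> A2D` with `K1` (M^-1) and `A2D + A2 <=> A4D` with `K2`
#' (M^-1), so `K1*K2` plays the role of the macroscopic M^-2 constant. A
#' highly cooperative system (`K2 >> K1`) never populates the singly-bound
#' intermediate, which is what distinguishes it experimentally.
#'
#' @param K1 first stepwise association constant, M^-1.
#' @param K2 second stepwise association constant, M^-1.
#' @param dimer_total total dimer concentration, M.
#' @param duplex_total total duplex concentration, M.
#' @return A list with free `dimer` concentration, duplex-species fractions
#'   `frac_D`, `frac_A2D`, `frac_A4D` (summing to 1), and the absolute
#'   concentrations `D`, `A2D`, `A4D`.
#' @examples
#' sequential_two_site_speciation(sqrt(3e13), sqrt(3e13), 10e-6, 5e-6)
#' @export
sequential_two_site_speciation <- function(K1, K2, dimer_total, duplex_total) {
  assert_nonneg(K1, "K1")
  assert_nonneg(K2, "K2")
  assert_nonneg(dimer_total, "dimer_total")
  assert_nonneg(duplex_total, "duplex_total")

  ## Free duplex given free dimer a: d = D_tot / (1 + K1 a + K1 K2 a^2);
  ## dimer balance g(a) = a + (K1 a + 2 K1 K2 a^2) d - A_tot is strictly
  ## increasing in a, bracketed on [0, A_tot].
  g <- function(a) {
    d <- duplex_total / (1 + K1 * a + K1 * K2 * a^2)
    a + (K1 * a + 2 * K1 * K2 * a^2) * d - dimer_total
  }
  if (dimer_total == 0) {
    a <- 0
  } else {
    lo <- 0; hi <- dimer_total
    for (i in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (g(mid) < 0) lo <- mid else hi <- mid
      if ((hi - lo) <= 1e-14 * dimer_total) break
    }
    a <- (lo + hi) / 2
  }
  d <- duplex_total / (1 + K1 * a + K1 * K2 * a^2)
  A2D <- K1 * a * d
  A4D <- K1 * K2 * a^2 * d
  tot <- max(duplex_total, .Machine$double.xmin)
  list(dimer = a, D = d, A2D = A2D, A4D = A4D,
       frac_D = d / tot, frac_A2D = A2D / tot, frac_A4D = A4D / tot)
}

#' Maximum intermediate population across a sequential-model titration
#'
#' Scans dimer:duplex ratios and reports the largest fraction of duplex
#' present as the singly-bound intermediate `A2D`. In the cooperative limit
#' (`K2/K1 -> Inf` at fixed `K1*K2`) this tends to zero and the sequential
#' model becomes indistinguishable from the concerted tri-molecular one.
#'
#' @inheritParams sequential_two_site_speciation
#' @param dimer_ratios ratios scanned; default `seq(0, 4, by = 0.05)`.
#' @return Maximum `frac_A2D` over the scan.
#' @export
max_intermediate_fraction <- function(K1, K2, duplex_total,
                                      dimer_ratios = seq(0, 4, by = 0.05)) {
  fr <- vapply(dimer_ratios, function(r) {
    sequential_two_site_speciation(K1, K2, r * duplex_total,
                                   duplex_total)$frac_A2D
  }, numeric(1))
  max(fr)
}
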