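## Shrake-Rupley solvent accessibility and buried surface area.

## Bondi van der Waals radii (A); fallback covers rare elements.
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
                SE = 1.90)

## Deterministic quasi-uniform sphere points (golden-angle spiral lattice).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom solvent-accessible area by sphere-point counting on a
#' deterministic golden-spiral lattice (no RNG): each atom's accessible
#' fraction is the share of its probe-inflated sphere points not inside
#' any neighbouring atom's probe-inflated sphere.
#'
#' @param model a `structure_model`, or an N x 3 coordinate matrix with an
#'   `elements` argument.
#' @param probe probe radius, A (water, default 1.4).
#' @param n_sphere_points points per atom sphere (default 960).
#' @param radii named vector of van der Waals radii by element symbol.
#' @param fallback_radius radius for unknown elements; `NA` to error
#'   instead.
#' @param elements element symbols when `model` is a bare matrix.
#' @return Numeric vector of per-atom accessible areas, A^2.
#' @export
shrake_rupley_sasa <- function(model, probe = 1.4, n_sphere_points = 960L,
                               radii = .VDW_RADII, fallback_radius = 1.7,
                               elements = NULL) {
  if (inherits(model, "structure_model")) {
    xyz <- as.matrix(model[, c("x", "y", "z")])
    elements <- model$element
  } else {
    xyz <- as_bead_matrix(model)
    if (is.null(elements)) elements <- rep("C", nrow(xyz))
  }
  r <- radii[toupper(elements)]
  if (anyNA(r)) {
    if (is.na(fallback_radius))
      stop_domain("unknown element(s): ",
                  paste(unique(elements[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- fallback_radius
  }
  r <- unname(r) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  out <- numeric(n)
  ## neighbour lists via one distance matrix; fine at the sizes used here
  dmat <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    nb <- which(dmat[i, ] < r[i] + r & seq_len(n) != i)
    p <- sweep(pts * r[i], 2L, xyz[i, ], `+`)
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      d2 <- rowSums(sweep(p, 2L, xyz[j, ])^2)
      acc <- acc & d2 >= r[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * r[i]^2 * mean(acc)
  }
  out
}

#' Buried surface area between two parts of a structure
#'
#' `BSA = SASA(A alone) + SASA(B alone) - SASA(A and B together)`, the
#' standard interface-burial measure (both faces of the interface).
#'
#' @param model a `structure_model`.
#' @param sel_A,sel_B disjoint selections.
#' @param ... passed to [shrake_rupley_sasa()].
#' @return Buried area in A^2 (>= 0 within numerical tolerance).
#' @export
buried_surface_area <- function(model, sel_A, sel_B, ...) {
  ia <- resolve_selection(model, sel_A)
  ib <- resolve_selection(model, sel_B)
  if (length(intersect(ia, ib)) > 0L)
    stop_domain("selections overlap: buried area is undefined")
  xyz <- as.matrix(model[, c("x", "y", "z")])
  el <- model$element
  sasa <- function(idx)
    sum(shrake_rupley_sasa(xyz[idx, , drop = FALSE],
                           elements = el[idx], ...))
  sasa(ia) + sasa(ib) - sasa(c(ia, ib))
}
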