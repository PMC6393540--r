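## Rigid-body superposition and derived comparison metrics.

#' Kabsch superposition
#'
#' Least-squares optimal rigid superposition of a mobile atom set onto a
#' reference set (Kabsch algorithm via SVD, with the reflection guard that
#' keeps the rotation proper, det = +1, even for near-mirror inputs).
#' Pairing is by position in the resolved selections, by shared residue
#' number, or via an explicit residue map.
#'
#' @param mobile,reference `structure_model` objects, or N x 3 coordinate
#'   matrices (then selections are ignored).
#' @param mobile_sel,reference_sel selections (see [selection()]).
#' @param pairing `"by_position"` (default) or `"by_residue_number"`.
#' @param residue_map optional data.frame with columns `mobile`,
#'   `reference` giving residue-number correspondences (used with CA or
#'   backbone atom sets when the two proteins are homologs with different
#'   numbering).
#' @return Object of class `superposition_result`: `rotation` (3 x 3,
#'   proper orthogonal), `translation` (applied as `x %*% t(R) + t`),
#'   `rmsd` (A), `n_pairs`.
#' @export
kabsch_superpose <- function(mobile, reference,
                             mobile_sel = selection(),
                             reference_sel = selection(),
                             pairing = c("by_position", "by_residue_number"),
                             residue_map = NULL) {
  pairing <- match.arg(pairing)
  pm <- superpose_coords_pair(mobile, reference, mobile_sel, reference_sel,
                              pairing, residue_map)
  P <- pm$mobile; Q <- pm$reference
  if (nrow(P) != nrow(Q))
    stop_domain("pairing mismatch: ", nrow(P), " mobile vs ", nrow(Q),
                " reference atoms")
  if (nrow(P) < 3L) stop_domain("need at least 3 atom pairs")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cq - as.numeric(R %*% cp)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd,
                 n_pairs = nrow(P)),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("Superposition: rmsd = %.4f A over %d pairs (angle %.2f deg)\n",
              x$rmsd, x$n_pairs, rotation_angle(x$rotation)))
  invisible(x)
}

superpose_coords_pair <- function(mobile, reference, mobile_sel,
                                  reference_sel, pairing, residue_map) {
  if (is.matrix(mobile) || !inherits(mobile, "structure_model")) {
    return(list(mobile = as_bead_matrix(mobile),
                reference = as_bead_matrix(reference)))
  }
  mi <- resolve_selection(mobile, mobile_sel)
  ri <- resolve_selection(reference, reference_sel)
  if (!is.null(residue_map)) {
    ## keep only mapped residues, translate mobile numbering to reference
    mm <- mobile[mi, ]; rr <- reference[ri, ]
    mm <- mm[mm$resid %in% residue_map$mobile, ]
    mm$pair_resid <- residue_map$reference[match(mm$resid, residue_map$mobile)]
    rr <- rr[rr$resid %in% residue_map$reference, ]
    rr$pair_resid <- rr$resid
    keym <- paste(mm$pair_resid, mm$atom)
    keyr <- paste(rr$pair_resid, rr$atom)
    common <- intersect(keym, keyr)
    if (length(common) == 0L) stop_domain("residue map yields no atom pairs")
    mm <- mm[match(common, keym), ]
    rr <- rr[match(common, keyr), ]
    return(list(mobile = as.matrix(mm[, c("x", "y", "z")]),
                reference = as.matrix(rr[, c("x", "y", "z")])))
  }
  if (pairing == "by_residue_number") {
    mm <- mobile[mi, ]; rr <- reference[ri, ]
    keym <- paste(mm$resid, mm$icode, mm$atom)
    keyr <- paste(rr$resid, rr$icode, rr$atom)
    common <- intersect(keym, keyr)
    missing_m <- setdiff(keyr, keym); missing_r <- setdiff(keym, keyr)
    if (length(common) == 0L)
      stop_domain("no shared (residue, atom) pairs between selections")
    if (length(missing_m) + length(missing_r) > 0L)
      warning("unpaired atoms dropped: ",
              length(missing_m) + length(missing_r), call. = FALSE)
    mm <- mm[match(common, keym), ]; rr <- rr[match(common, keyr), ]
    return(list(mobile = as.matrix(mm[, c("x", "y", "z")]),
                reference = as.matrix(rr[, c("x", "y", "z")])))
  }
  list(mobile = as.matrix(mobile[mi, c("x", "y", "z")]),
       reference = as.matrix(reference[ri, c("x", "y", "z")]))
}

#' Rotation angle of a rotation matrix
#'
#' @param R 3 x 3 proper rotation matrix.
#' @return Angle in degrees, `acos((trace - 1)/2)`.
#' @export
rotation_angle <- function(R) {
  tr <- sum(diag(R))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}

#' Backbone RMSD between two structures
#'
#' Convenience wrapper over [kabsch_superpose()] using the backbone atom
#' set (N, CA, C, O): superposes the selected ranges and reports the RMSD.
#'
#' @param A,B `structure_model` objects.
#' @param sel_A,sel_B selections; their atom set is forced to backbone
#'   unless they already name explicit atoms.
#' @param pairing,residue_map passed to [kabsch_superpose()].
#' @return RMSD in A.
#' @export
backbone_rmsd <- function(A, B, sel_A, sel_B,
                          pairing = "by_position", residue_map = NULL) {
  sel_A <- parse_selection(sel_A); sel_B <- parse_selection(sel_B)
  if (identical(sel_A$atoms, "all")) sel_A$atoms <- "backbone"
  if (identical(sel_B$atoms, "all")) sel_B$atoms <- "backbone"
  kabsch_superpose(A, B, sel_A, sel_B, pairing = pairing,
                   residue_map = residue_map)$rmsd
}

#' Distance between the centres of mass of two selections
#'
#' @param model a `structure_model`.
#' @param sel_A,sel_B selections.
#' @param weighting `"uniform"` (default; plain centroid of the selected
#'   atoms) or `"mass"` (element-mass weighted).
#' @return Distance in A.
#' @export
com_distance <- function(model, sel_A, sel_B,
                         weighting = c("uniform", "mass")) {
  weighting <- match.arg(weighting)
  com <- function(sel) {
    idx <- resolve_selection(model, sel)
    xyz <- as.matrix(model[idx, c("x", "y", "z")])
    w <- if (weighting == "mass") element_mass(model$element[idx]) else
      rep(1, length(idx))
    colSums(xyz * w) / sum(w)
  }
  sqrt(sum((com(sel_A) - com(sel_B))^2))
}

element_mass <- function(el) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974)
  m <- tab[toupper(el)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Relative rotation of a subunit between two complexes
#'
#' Superposes complex 2 onto complex 1 using the alignment selections
#' (e.g. the antitoxin monomers), then computes the optimal rotation
#' mapping the measured selection of complex 1 onto the transformed
#' measured selection of complex 2 (e.g. the toxins). Reports the rotation
#' angle `acos((trace - 1)/2)` and the displacement between the measured
#' centroids after alignment.
#'
#' @param complex1,complex2 `structure_model` objects.
#' @param align_sel1,align_sel2 alignment selections in each complex.
#' @param measure_sel1,measure_sel2 measured selections in each complex.
#' @param pairing,residue_map passed to the alignment superposition.
#' @return List with `angle` (degrees) and `com_displacement` (A).
#' @export
relative_rotation <- function(complex1, complex2, align_sel1, align_sel2,
                              measure_sel1, measure_sel2,
                              pairing = "by_position", residue_map = NULL) {
  al <- kabsch_superpose(complex2, complex1, align_sel2, align_sel1,
                         pairing = pairing, residue_map = residue_map)
  m1 <- selection_coords(complex1, measure_sel1)
  m2 <- selection_coords(complex2, measure_sel2)
  m2t <- sweep(m2 %*% t(al$rotation), 2L, al$translation, `+`)
  if (nrow(m1) != nrow(m2t))
    stop_domain("measured selections resolve to different atom counts")
  rot <- kabsch_superpose(m1, m2t)
  list(angle = rotation_angle(rot$rotation),
       com_displacement = sqrt(sum((colMeans(m1) - colMeans(m2t))^2)))
}
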