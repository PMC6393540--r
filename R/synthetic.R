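## Synthetic-data generators: every input the pipeline needs, produced in
## code with recorded seeds, so all stages are testable offline. Each
## fixture writer emits a ground-truth sidecar JSON; downstream recovery
## tests read truth only from the sidecars.

truth_sidecar_path <- function(path) paste0(path, ".truth.json")

write_truth <- function(truth, path) {
  jsonlite::write_json(truth, truth_sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(truth_sidecar_path(path))
}

#' Write a synthetic ITC isotherm fixture
#'
#' Simulates a cooperative isotherm with [simulate_isotherm()] and writes
#' it as an ITC CSV (metadata block plus per-injection heats), together
#' with a `.truth.json` sidecar holding the generating parameters. Output
#' is byte-identical for identical (spec, seed).
#'
#' @param params [binding_parameters()].
#' @param protocol [titration_protocol()].
#' @param noise_sd heat noise SD, kcal/mol.
#' @param seed integer seed.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
make_itc_fixture <- function(params, protocol, noise_sd, seed, path) {
  sim <- simulate_isotherm(params, protocol, noise_sd = noise_sd, seed = seed)
  write_itc_csv(sim, path)
  write_truth(list(kind = "itc", K_A = params$K_A, dH = params$dH,
                   offset = params$offset, noise_sd = noise_sd, seed = seed),
              path)
  invisible(path)
}

#' Sample a globular bead body
#'
#' Beads uniformly distributed in a sphere (rejection sampling, seeded) —
#' the coarse-grained stand-in for a compact, well-folded particle. Its Rg
#' tends to `R * sqrt(3/5)` as the bead count grows.
#'
#' @param radius sphere radius, A.
#' @param n_beads number of beads (>= 10).
#' @param seed integer seed.
#' @return N x 3 coordinate matrix.
#' @export
make_globular_body <- function(radius, n_beads, seed = 1L) {
  if (n_beads < 10L) stop_domain("`n_beads` must be >= 10")
  assert_scalar_finite(radius, "radius")
  if (radius <= 0) stop_domain("`radius` must be > 0")
  with_seed(seed, {
    out <- matrix(NA_real_, n_beads, 3L)
    filled <- 0L
    while (filled < n_beads) {
      m <- matrix(stats::runif(3L * (n_beads - filled) * 2L, -radius, radius),
                  ncol = 3L)
      keep <- rowSums(m^2) <= radius^2
      m <- m[keep, , drop = FALSE]
      take <- min(nrow(m), n_beads - filled)
      if (take > 0L) {
        out[(filled + 1L):(filled + take), ] <- m[seq_len(take), ]
        filled <- filled + take
      }
    }
    out
  })
}

#' Build a rigid-body-plus-flexible-tail benchmark system
#'
#' Emulates a partially disordered particle: a globular bead body with a
#' self-avoiding tail of `n_tail` beads (default 22, the length of the
#' disordered toxin N-terminus), a pool of tail conformers, and a noisy
#' "experimental" scattering curve computed as a designated weighted
#' mixture of pool-member profiles with q-dependent Gaussian noise
#' `sigma(q) = a + b * I(q)`.
#'
#' @param body_radius globular body radius, A.
#' @param n_body beads in the body.
#' @param n_tail tail beads (default 22).
#' @param n_conformers pool size.
#' @param true_members indices of the mixture components within the pool.
#' @param true_weights mixture weights (sum 1).
#' @param q_grid momentum-transfer grid, A^-1.
#' @param noise_a,noise_b noise model constants; defaults
#'   `1e-4 * I(0)` and `0.01`.
#' @param seed integer seed.
#' @param path optional base path; when given, writes `<path>.dat` and a
#'   truth sidecar.
#' @return List with `ensemble` ([bead_ensemble()]), `pool_profiles`,
#'   `experiment` (noisy [scattering_profile()]), `truth` (members,
#'   weights, member Rg values).
#' @export
make_rigid_plus_tail_system <- function(body_radius = 15, n_body = 200L,
                                        n_tail = 22L, n_conformers = 50L,
                                        true_members = c(1L, 2L),
                                        true_weights = c(0.7, 0.3),
                                        q_grid = seq(0.005, 0.35,
                                                     length.out = 120L),
                                        noise_a = NULL, noise_b = 0.01,
                                        seed = 1L, path = NULL) {
  if (length(true_members) != length(true_weights) ||
      abs(sum(true_weights) - 1) > 1e-9)
    stop_domain("`true_weights` must match `true_members` and sum to 1")
  body <- make_globular_body(body_radius, n_body, seed = seed)
  ## anchor the tail at the body bead nearest the surface along +x
  anchor <- which.max(body[, 1L])
  ens <- generate_tail_conformers(body, anchor_index = anchor,
                                  n_tail = n_tail,
                                  n_conformers = n_conformers,
                                  seed = seed + 1L)
  pool <- lapply(ens$members, debye_profile, q_grid = q_grid)
  Imix <- Reduce(`+`, Map(function(i, w) w * pool[[i]]$I,
                          true_members, true_weights))
  if (is.null(noise_a)) noise_a <- 1e-4 * Imix[1L]
  sig <- noise_a + noise_b * Imix
  Inoisy <- Imix + with_seed(seed + 2L, stats::rnorm(length(Imix), 0, sig))
  ## zero-noise request: keep the exact curve, synthesize default sigma
  experiment <- scattering_profile(q_grid, Inoisy,
                                   if (all(sig > 0)) sig else NULL)
  truth <- list(kind = "saxs_tail_ensemble", seed = seed,
                members = true_members, weights = true_weights,
                member_rg = vapply(ens$members, rg_from_coords, numeric(1)))
  if (!is.null(path)) {
    write_saxs_dat(experiment, paste0(path, ".dat"),
                   header = sprintf("synthetic tail-ensemble mixture, seed %d",
                                    seed))
    write_truth(truth, paste0(path, ".dat"))
  }
  list(ensemble = ens, pool_profiles = pool, experiment = experiment,
       truth = truth)
}

## Ideal alpha-helix Ca trace: rise 1.5 A/residue, 100 deg/residue,
## helix radius 2.3 A, axis along z through `origin`.
helix_ca <- function(n_res, origin = c(0, 0, 0)) {
  i <- seq_len(n_res) - 1L
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang) + origin[1L],
        2.3 * sin(ang) + origin[2L],
        1.5 * i + origin[3L])
}

coords_to_model <- function(xyz, chain = "A", resid_start = 1L,
                            atom = "CA", resname = "ALA", element = "C") {
  n <- nrow(xyz)
  structure(data.frame(chain = chain,
                       resid = seq.int(resid_start, length.out = n),
                       icode = "", resname = resname, atom = atom,
                       element = element,
                       x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                       occupancy = 1, het = FALSE,
                       stringsAsFactors = FALSE),
            class = c("structure_model", "data.frame"),
            source = "synthetic")
}

rotation_about_axis <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  c_ <- cos(a); s <- sin(a)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
               byrow = TRUE)
  diag(3L) * c_ + s * ux + (1 - c_) * tcrossprod(u)
}

#' Write toy structure fixtures with known ground truth
#'
#' Emits three synthetic PDB fixtures plus a truth sidecar each:
#' `helix_pair.pdb` — two ideal alpha-helices at an exact centroid
#' separation; `rotated_domains_{1,2}.pdb` — a two-domain complex in which
#' domain B is rotated by an exact angle (about an axis through its
#' centroid) and displaced by an exact distance between the copies;
#' `rigid_copy_{1,2}.pdb` — a random cloud and a rigid-transformed copy
#' (RMSD 0 by construction).
#'
#' @param dir output directory (created if needed).
#' @param separation helix-pair centroid separation, A (default 30).
#' @param angle domain rotation angle, degrees (default 25).
#' @param displacement domain centroid displacement, A (default 6.8).
#' @param seed integer seed for the random clouds.
#' @return Named list of file paths, invisibly.
#' @export
make_toy_structures <- function(dir, separation = 30, angle = 25,
                                displacement = 6.8, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  ## (a) helix pair at exact centroid separation along x
  h1 <- helix_ca(21L)
  h2 <- sweep(helix_ca(21L), 2L, c(separation, 0, 0), `+`)
  m <- rbind(coords_to_model(h1, chain = "A"),
             coords_to_model(h2, chain = "B"))
  class(m) <- c("structure_model", "data.frame")
  p <- file.path(dir, "helix_pair.pdb")
  write_structure(m, p)
  write_truth(list(kind = "toy_structure", separation = separation), p)
  paths$helix_pair <- p

  ## (b) two-domain complex with an exact relative rotation of domain B
  cloud <- function(n, centre, spread = 8)
    sweep(matrix(stats::rnorm(3L * n, 0, spread), ncol = 3L), 2L, centre, `+`)
  with_seed(seed, {
    domA <- cloud(40L, c(0, 0, 0))
    domB <- cloud(40L, c(20, 0, 0))
  })
  c1 <- rbind(coords_to_model(domA, chain = "A"),
              coords_to_model(domB, chain = "B"))
  class(c1) <- c("structure_model", "data.frame")
  R <- rotation_about_axis(c(0, 0, 1), angle)
  ctrB <- colMeans(domB)
  shift_dir <- c(0, 1, 0)
  domB2 <- sweep(sweep(domB, 2L, ctrB) %*% t(R), 2L,
                 ctrB + displacement * shift_dir, `+`)
  c2 <- rbind(coords_to_model(domA, chain = "A"),
              coords_to_model(domB2, chain = "B"))
  class(c2) <- c("structure_model", "data.frame")
  p1 <- file.path(dir, "rotated_domains_1.pdb")
  p2 <- file.path(dir, "rotated_domains_2.pdb")
  write_structure(c1, p1); write_structure(c2, p2)
  write_truth(list(kind = "toy_structure", angle = angle,
                   displacement = displacement, seed = seed), p1)
  paths$rotated_domains <- c(p1, p2)

  ## (c) rigid-transformed copy (zero-RMSD pair)
  with_seed(seed + 1L, {
    pts <- matrix(stats::rnorm(60L, 0, 10), ncol = 3L)
  })
  Rt <- rotation_about_axis(c(1, 2, 3), 37)
  pts2 <- sweep(pts %*% t(Rt), 2L, c(5, -3, 2), `+`)
  q1 <- file.path(dir, "rigid_copy_1.pdb")
  q2 <- file.path(dir, "rigid_copy_2.pdb")
  write_structure(coords_to_model(pts, chain = "A"), q1)
  write_structure(coords_to_model(pts2, chain = "A"), q2)
  write_truth(list(kind = "toy_structure", angle = 37,
                   translation = c(5, -3, 2), seed = seed + 1L), q1)
  paths$rigid_copy <- c(q1, q2)

  invisible(paths)
}

## Operator variants: 33 bp wild type with a central TAACGTTA palindrome;
## variant mutations are encoded in lowercase. Some variants are
## truncations.
.OPERATOR_VARIANTS <- c(
  wild_type        = "AAATTAACGAATAACGTTAAGCATTCAGCTCAT",
  variant_1        = "AAATTAACGAATAACGggccGCATTCAGCT",
  variant_2        = "AAATTAACGAAgccCGTTAAGCcggCAGCT",
  variant_3        = "AAATTAACGAATAgtGTTAAGCATTCAGCT",
  variant_4        = "AAAggcACGAATAACGTTAAGCATTCAGCT",
  variant_5        = "AAATTAACGccgAACGTTAAGCATTCAGC",
  variant_6        = "AAATTAACGAATAACGTTAAGCcggCAGCT",
  left_mirrored    = "AAATTAACGAATAACGTTAttcgttaattt",
  right_mirrored   = "agctgaatgctTAACGTTAAGCATTCAGCT",
  central_palindrome = "GAATAACGTTAAG",
  upstream_half    = "AAATTAACGAATAACGTTAAG",
  downstream_half  = "AATAACGTTAAGCATTCAGCT")

#' Reverse complement of a DNA string
#'
#' Case-preserving reverse complement.
#'
#' @param seq DNA string (ACGT, either case).
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A",
           a = "t", c = "g", g = "c", t = "a")
  ch <- rev(strsplit(seq, "")[[1L]])
  out <- map[ch]
  if (anyNA(out)) stop_domain("invalid DNA character in `seq`")
  paste(out, collapse = "")
}

#' Operator sequence variants
#'
#' Returns the named vector of operator variants used in the binding
#' study: the 33 bp wild type (central palindrome TAACGTTA), palindrome
#' point mutants, flank mutants, mirrored constructs, and truncations.
#' Mutations relative to the wild type are lowercase.
#'
#' @return Named character vector.
#' @export
operator_variants <- function() .OPERATOR_VARIANTS

#' Write the operator-variant FASTA fixture
#'
#' Writes every operator variant and its duplex complement strand as
#' FASTA records (case preserved; lowercase marks mutations). Validates
#' that the central 8-mer TAACGTTA is its own reverse complement before
#' writing.
#'
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_operator_fixtures <- function(path) {
  stopifnot(identical(reverse_complement("TAACGTTA"), "TAACGTTA"))
  v <- operator_variants()
  lines <- unlist(lapply(names(v), function(nm) {
    c(sprintf(">%s length=%d", nm, nchar(v[[nm]])), v[[nm]],
      sprintf(">%s_complement length=%d", nm, nchar(v[[nm]])),
      reverse_complement(v[[nm]]))
  }))
  writeLines(lines, path)
  write_truth(list(kind = "operator_fasta", n_variants = length(v),
                   palindrome = "TAACGTTA"), path)
  invisible(path)
}
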