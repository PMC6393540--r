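## A small hand-written PDB fixture exercising models, altlocs, HETATM
## and waters.
write_mini_pdb <- function(path) {
  writeLines(c(
    "MODEL     1",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  CA AGLY A   2      12.000   7.000  -4.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2      12.100   7.100  -4.100  0.50  0.00           C",
    "HETATM    5 MG    MG A 101       0.000   0.000   0.000  1.00  0.00          MG",
    "HETATM    6  O   HOH A 102       1.000   1.000   1.000  1.00  0.00           O",
    "ENDMDL",
    "MODEL     2",
    "ATOM      7  N   ALA A   1      10.000   6.000  -6.000  1.00  0.00           N",
    "ENDMDL",
    "END"), path)
  path
}

test_that("PDB reading honours models, altlocs, waters and HETATM flags", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(p)
  expect_identical(nrow(m), 3L)               # altloc B, MG, HOH dropped
  expect_equal(m$x[1], 11.104)
  expect_identical(m$atom, c("N", "CA", "CA"))
  m2 <- read_structure(p, model_index = 2)
  expect_identical(nrow(m2), 1L)
  mh <- read_structure(p, include_het = TRUE)
  expect_identical(nrow(mh), 4L)              # MG kept, water still excluded
  mb <- read_structure(p, altloc = "B")
  expect_equal(mb$x[3], 12.1)
  expect_error(read_structure(tempfile()), "not found")
})

test_that("structures round-trip through write_structure", {
  p <- write_mini_pdb(tempfile(fileext = ".pdb"))
  m <- read_structure(p)
  p2 <- tempfile(fileext = ".pdb")
  write_structure(m, p2)
  m2 <- read_structure(p2)
  expect_equal(m2$x, m$x)
  expect_identical(m2$atom, m$atom)
  expect_identical(m2$chain, m$chain)
})

test_that("Kabsch superposition recovers exact transforms and stays proper", {
  set.seed(1)
  P <- matrix(rnorm(60, sd = 10), ncol = 3)
  ## identity
  s <- kabsch_superpose(P, P)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  ## exact 37 degree rotation about z plus translation
  R37 <- matrix(c(cos(37 * pi / 180), -sin(37 * pi / 180), 0,
                  sin(37 * pi / 180), cos(37 * pi / 180), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  Q <- sweep(P %*% t(R37), 2, c(5, -3, 2), `+`)
  s <- kabsch_superpose(P, Q)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(rotation_angle(s$rotation), 37, tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  ## mirror-image input: rotation must stay proper
  s <- kabsch_superpose(P, P %*% diag(c(-1, 1, 1)))
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
})

test_that("Kabsch RMSD agrees with the quaternion oracle on jittered clouds", {
  for (s in 1:5) {
    set.seed(s)
    P <- matrix(rnorm(60, sd = 8), ncol = 3)
    Q <- sweep(P %*% t(random_rotation()), 2, rnorm(3, sd = 5), `+`) +
      matrix(rnorm(60, sd = 0.5), ncol = 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_quaternion_rmsd(P, Q),
                 tolerance = 1e-6)
  }
})

test_that("RMSD is invariant under common rigid transforms of both inputs", {
  set.seed(2)
  P <- matrix(rnorm(90, sd = 8), ncol = 3)
  Q <- P + matrix(rnorm(90, sd = 1), ncol = 3)
  base <- kabsch_superpose(P, Q)$rmsd
  for (i in 1:5) {
    R <- random_rotation(); t <- rnorm(3, sd = 20)
    r2 <- kabsch_superpose(sweep(P %*% t(R), 2, t, `+`),
                           sweep(Q %*% t(R), 2, t, `+`))$rmsd
    expect_equal(r2, base, tolerance = 1e-9)
  }
})

test_that("backbone_rmsd and pairing modes work on the toy fixtures", {
  d <- tempfile()
  paths <- make_toy_structures(d, seed = 3)
  a <- read_structure(paths$rigid_copy[1])
  b <- read_structure(paths$rigid_copy[2])
  ## PDB coordinates are written at 0.001 A precision
  expect_lt(kabsch_superpose(a, b, selection(atoms = "CA"),
                             selection(atoms = "CA"))$rmsd, 2e-3)
  ## residue-number pairing with a residue map
  map <- data.frame(mobile = 1:20, reference = 1:20)
  expect_lt(backbone_rmsd(a, b, "A::CA", "A::CA", residue_map = map), 2e-3)
  ## mismatched selections error
  expect_error(kabsch_superpose(a, b, selection(resid_range = c(1, 10)),
                                selection(resid_range = c(1, 5))),
               "pairing mismatch")
})

test_that("centre-of-mass distances match constructed truth", {
  d <- tempfile()
  paths <- make_toy_structures(d, separation = 30, seed = 4)
  m <- read_structure(paths$helix_pair)
  expect_equal(com_distance(m, "A", "B"), 30, tolerance = 1e-3)
  expect_equal(com_distance(m, "A", "A"), 0)
  expect_equal(com_distance(m, "A", "B"),
               com_distance(m, "A", "B", weighting = "mass"),
               tolerance = 1e-9)   # single-element selection: same centroid
  expect_error(com_distance(m, "C", "B"), "no atoms")
})

test_that("relative rotation recovers the constructed angle and displacement", {
  d <- tempfile()
  paths <- make_toy_structures(d, angle = 25, displacement = 6.8, seed = 5)
  c1 <- read_structure(paths$rotated_domains[1])
  c2 <- read_structure(paths$rotated_domains[2])
  ## identity case
  r0 <- relative_rotation(c1, c1, "A", "A", "B", "B")
  expect_lt(r0$angle, 1e-6)
  expect_lt(r0$com_displacement, 1e-9)
  r <- relative_rotation(c1, c2, "A", "A", "B", "B")
  expect_equal(r$angle, 25, tolerance = 0.01 / 25)
  expect_equal(r$com_displacement, 6.8, tolerance = 0.01)
})

test_that("SASA matches closed forms for one and two spheres", {
  ## isolated atom: 4 pi (r + probe)^2 within 0.5%
  a1 <- shrake_rupley_sasa(matrix(0, 1, 3), elements = "C")
  expect_equal(a1, 4 * pi * (1.7 + 1.4)^2, tolerance = 0.005)
  ## additivity for distant atoms
  a2 <- shrake_rupley_sasa(rbind(c(0, 0, 0), c(100, 0, 0)),
                           elements = c("C", "C"))
  expect_equal(sum(a2), 2 * 4 * pi * 3.1^2, tolerance = 0.005)
  ## overlapping unit spheres vs the spherical-cap formula within 1%
  for (sep in c(0.6, 1.0, 1.5)) {
    got <- sum(shrake_rupley_sasa(rbind(c(0, 0, 0), c(sep, 0, 0)),
                                  probe = 0, radii = c(X = 1),
                                  elements = c("X", "X")))
    expect_equal(got, oracle_two_sphere_sasa(1, sep), tolerance = 0.01)
  }
  ## unknown element without fallback errors
  expect_error(shrake_rupley_sasa(matrix(0, 1, 3), elements = "ZZ",
                                  fallback_radius = NA), "unknown element")
})

test_that("SASA decreases monotonically as two bodies approach", {
  set.seed(6)
  blob <- matrix(rnorm(30, sd = 2), ncol = 3)
  seps <- c(30, 15, 10, 7, 5, 4)
  areas <- vapply(seps, function(s) {
    xyz <- rbind(blob, sweep(blob, 2, c(s, 0, 0), `+`))
    sum(shrake_rupley_sasa(xyz, elements = rep("C", nrow(xyz))))
  }, numeric(1))
  expect_true(all(diff(areas) <= 1e-6))
})

test_that("buried surface area is symmetric, zero at distance, positive in contact", {
  set.seed(7)
  blob <- matrix(rnorm(45, sd = 2.5), ncol = 3)
  far <- coords_model_for_test(rbind(blob, sweep(blob, 2, c(100, 0, 0), `+`)))
  expect_lt(abs(buried_surface_area(far, selection(chain = "A"),
                                    selection(chain = "B"))), 1)
  near <- coords_model_for_test(rbind(blob, sweep(blob, 2, c(5, 0, 0), `+`)))
  ab <- buried_surface_area(near, selection(chain = "A"), selection(chain = "B"))
  ba <- buried_surface_area(near, selection(chain = "B"), selection(chain = "A"))
  expect_identical(ab, ba)
  expect_gt(ab, 10)
  expect_error(buried_surface_area(near, selection(chain = "A"),
                                   selection(chain = "A")), "overlap")
})

test_that("sequence net charge follows the formal side-chain convention", {
  expect_identical(sequence_net_charge("AAAA"), 0L)
  expect_identical(sequence_net_charge("KKRDE"), 1L)
  expect_identical(sequence_net_charge("KRDEKRH"), 2L)
  expect_error(sequence_net_charge("KRB"), "invalid one-letter")
})

test_that("selection strings parse to the documented semantics", {
  s <- parse_selection("A:4-99:backbone")
  expect_identical(s$chain, "A")
  expect_identical(s$resid_range[[1]], c(4L, 99L))
  expect_identical(s$atoms, "backbone")
  s2 <- parse_selection("B")
  expect_null(s2$resid_range)
  expect_identical(s2$atoms, "all")
})
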