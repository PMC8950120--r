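test_that("SASA of isolated, enclosed and disjoint atoms is exact", {
  one <- mol_structure(data.frame(serial = 1, name = "C", resname = "X",
                                  resno = 1, chain = "A", x = 0, y = 0, z = 0,
                                  element = "C", stringsAsFactors = FALSE))
  one$atoms$radius <- 1.6
  expect_equal(sasa(one)$total, 4 * pi * 3^2, tolerance = 1e-9)

  # tight cage of large spheres fully occludes the centre atom
  cage <- expand.grid(x = c(-2, 2), y = c(-2, 2), z = c(-2, 2))
  at <- data.frame(serial = 1:9, name = "C", resname = "X", resno = 1:9,
                   chain = "A", x = c(0, cage$x), y = c(0, cage$y),
                   z = c(0, cage$z), element = "C", stringsAsFactors = FALSE)
  caged <- mol_structure(at)
  caged$atoms$radius <- c(1.0, rep(5, 8))
  expect_equal(sasa(caged)$per_atom[1], 0)

  # disjoint pair: areas add like isolated spheres
  two <- mol_structure(data.frame(serial = 1:2, name = "C", resname = "X",
                                  resno = 1:2, chain = "A", x = c(0, 50),
                                  y = 0, z = 0, element = "C",
                                  stringsAsFactors = FALSE))
  two$atoms$radius <- c(1.6, 1.8)
  expect_equal(sasa(two)$total, 4 * pi * (3^2 + 3.2^2), tolerance = 1e-9)

  # hydrogens neither contribute nor occlude
  withh <- mol_structure(data.frame(serial = 1:2, name = c("C", "H"),
                                    resname = "X", resno = 1, chain = "A",
                                    x = c(0, 1), y = 0, z = 0,
                                    element = c("C", "H"),
                                    stringsAsFactors = FALSE))
  withh$atoms$radius <- c(1.6, 0)
  res <- sasa(withh)
  expect_equal(res$per_atom[2], 0)
  expect_equal(res$total, 4 * pi * 3^2, tolerance = 1e-9)

  bad <- one; bad$atoms$radius <- NA_real_; bad$atoms$element <- "XX"
  expect_error(sasa(bad), "no radius")
})

test_that("SASA is rigid-motion invariant to quadrature tolerance", {
  # the 122-point covering is fixed in the lab frame, so invariance holds to
  # quadrature error (~1-2% on a tightly packed solute)
  h <- assign_parameters(build_helix(30))
  a0 <- sasa(h)$total
  for (seed in 1:3) {
    a1 <- sasa(rigid_move(h, seed))$total
    expect_equal(a1, a0, tolerance = 0.02)
  }
  # and tightens with the quadrature order
  p488 <- solvation_params(sphere_points = 488L)
  a0f <- sasa(h, p488)$total
  a1f <- sasa(rigid_move(h, 1), p488)$total
  expect_equal(a1f, a0f, tolerance = 0.008)
})

test_that("SASA agrees with an independent implementation within 2%", {
  h <- assign_parameters(build_helix(50))
  ours <- sasa(h)$total
  tmp <- tempfile(fileext = ".pdb")
  write_structure(h, tmp)
  py <- sprintf('
from Bio.PDB import PDBParser
from Bio.PDB.SASA import ShrakeRupley
s = PDBParser(QUIET=True).get_structure("x", "%s")
sr = ShrakeRupley(probe_radius=1.4, n_points=960,
                  radii_dict={"C":1.70,"N":1.55,"O":1.52,"S":1.80,"H":0.0})
sr.compute(s, level="A")
print(sum(a.sasa for a in s.get_atoms()))
', tmp)
  ref <- as.numeric(system2("python", "-", input = py, stdout = TRUE))
  expect_equal(ours, ref, tolerance = 0.02)
})

test_that("nonpolar term is the sigma-weighted area, linear in the areas", {
  h <- assign_parameters(build_helix(10))
  ar <- sasa(h)
  zero_sig <- solvation_params(sigma_table = data.frame(
    element = c("C", "N", "O", "H"), sigma = 0))
  expect_equal(nonpolar_solvation(ar, h, zero_sig), 0)
  one <- mol_structure(data.frame(serial = 1, name = "C", resname = "X",
                                  resno = 1, chain = "A", x = 0, y = 0, z = 0,
                                  element = "C", stringsAsFactors = FALSE))
  sp <- solvation_params(sigma_table = data.frame(element = "C", sigma = 0.01))
  expect_equal(nonpolar_solvation(100, one, sp), 1.0)
  e1 <- nonpolar_solvation(ar, h)
  e2 <- nonpolar_solvation(lapply(ar, `*`, 2), h)
  expect_equal(e2, 2 * e1, tolerance = 1e-12)
})

test_that("PB solver: zero charge, Born ion and negativity", {
  # all charges zero -> 0 without solving
  neutral <- born_ion(q = 0)
  expect_equal(solve_pb(neutral, pb_grid())$energy, 0)

  # Born ion on a reduced lattice (the full-lattice check runs in the
  # acceptance suite): q = 1 e, a = 2 A, eps 1 -> 80, no salt
  g <- pb_grid(dims = 64, spacing = 0.875, ionic_strength = 0)
  res <- solve_pb(born_ion(), g)
  expect_equal(res$energy, born_energy(), tolerance = 0.03)
  expect_lt(res$energy, 0)

  # solute clearance guard
  expect_error(solve_pb(born_ion(), pb_grid(dims = 24, spacing = 0.875)),
               "boundary")
})

test_that("two distant ions match the far-field closed form", {
  two <- mol_structure(data.frame(serial = 1:2, name = "NA", resname = "ION",
                                  resno = 1:2, chain = "A", x = c(-25, 25),
                                  y = 0, z = 0, element = "NA",
                                  stringsAsFactors = FALSE))
  two$atoms$radius <- 2; two$atoms$charge <- 1
  res <- solve_pb(two, pb_grid(dims = c(100, 72, 72), spacing = 0.875,
                               ionic_strength = 0))
  # exact far-field value: two Born terms plus the screened cross-interaction
  exact <- 2 * born_energy() + 332.0636 * (1 / 80 - 1) / 50
  expect_equal(res$energy, exact, tolerance = 0.03)
})

test_that("mean-field energy assembles its components additively", {
  ion <- born_ion()
  g <- pb_grid(dims = 64, spacing = 0.875, ionic_strength = 0)
  sp <- solvation_params(sigma_table = data.frame(element = "NA", sigma = 0),
                         radii_table = data.frame(element = "NA", radius = 2))
  mfe <- mean_field_energy(ion, c(str = 0, vdw = 0), params = sp, grid = g)
  expect_equal(mfe$total, sum(unlist(mfe$components)), tolerance = 1e-12)
  expect_equal(mfe$total, solve_pb(ion, g)$energy, tolerance = 1e-9)
  expect_error(mean_field_energy(ion, numeric()), "named")

  # zero charge, zero sigma, zero intra -> exactly zero
  mfe0 <- mean_field_energy(born_ion(q = 0), c(el = 0), params = sp, grid = g)
  expect_equal(mfe0$total, sasa(born_ion(q = 0), sp)$total * 0)
})
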