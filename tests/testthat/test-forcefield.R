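test_that("atom typing follows hybridization and aromaticity", {
  b <- assign_atom_types(fx("benzene"))
  expect_equal(sum(b$atoms$type == "C.ar"), 6)
  expect_equal(sum(b$atoms$type == "H"), 6)
  m <- assign_atom_types(fx("methanol"))
  expect_equal(m$atoms$type, c("C.3", "O.3", "H", "H", "H", "H"))
  # GO epoxy oxygen bridges two sp3 carbons
  go <- functionalize_graphene(build_circular_graphene(12),
                               functionalization_spec(0, 2, 0, max_models = 1,
                                                      seed = 6))[[1]]
  for (o3 in which(go$atoms$type == "O.3")) {
    nb <- qgadock:::neighbor_list(go)[[o3]]
    expect_equal(go$atoms$type[nb], c("C.3", "C.3"))
  }
  # unknown element is reported by atom
  bad <- molecule(data.frame(element = "Xx", type = "Xx", x = 0, y = 0, z = 0))
  expect_error(assign_atom_types(bad), "atom 1")
})

test_that("gasteiger charges have the right signs, sums and symmetry", {
  bu <- fx("n_butane")
  expect_lt(max(bu$atoms$charge[bu$atoms$element == "C"]), 0)
  expect_gt(min(bu$atoms$charge[bu$atoms$element == "H"]), 0)
  expect_equal(sum(bu$atoms$charge), 0, tolerance = 1e-9)
  # symmetry: the two terminal carbons are equivalent
  expect_equal(bu$atoms$charge[1], bu$atoms$charge[4], tolerance = 1e-9)
  # conservation equals the total formal charge on every fixture
  for (nm in fixture_names()) {
    m <- fx(nm)
    expect_equal(sum(m$atoms$charge), total_formal_charge(m),
                 tolerance = 1e-6)
  }
})

test_that("the Lennard-Jones pair minimum sits at the radius sum with depth eps", {
  pair_at <- function(d) {
    m <- molecule(data.frame(element = "Ar", type = "Ar", x = c(0, d),
                             y = 0, z = 0))
    potential_energy(m)$terms[["vdw"]]
  }
  expect_equal(pair_at(3.76), -0.234, tolerance = 1e-9)
  expect_gt(pair_at(3.40), pair_at(3.76))
  expect_gt(pair_at(4.20), pair_at(3.76))
})

test_that("binding energy vanishes for far-separated neutral fragments", {
  b <- fx("benzene")
  patch <- fx("coronene_patch")
  far <- transform_molecule(b, diag(3), c(0, 0, 100))
  rep <- potential_energy(complex_pose(patch, far))
  expect_lt(abs(rep$E_Delta), 0.01)
  # monotone decay beyond 20 A
  ed <- vapply(c(20, 30, 50), function(z) abs(
    potential_energy(complex_pose(patch,
      transform_molecule(b, diag(3), c(0, 0, z))))$E_Delta), 0)
  expect_true(all(diff(ed) < 0))
})

test_that("the binding-energy identity and report arithmetic hold exactly", {
  rep <- energy_report(-100, E_G = -60, E_lig = -15)
  expect_equal(rep$E_Delta, -25)
  expect_equal(fitness_from_report(rep, "potential"), 100)
  expect_equal(fitness_from_report(rep, "binding"), 25)
  b <- fx("benzene")
  patch <- fx("coronene_patch")
  posed <- transform_molecule(b, diag(3), c(0, 0, 3.4))
  full <- potential_energy(complex_pose(patch, posed))
  expect_equal(full$E_Delta, full$E_GDDS - full$E_G - full$E_lig)
  expect_equal(full$E_G, potential_energy(patch)$E_GDDS)
  expect_equal(full$E_lig, potential_energy(posed)$E_GDDS)
})

test_that("energy is invariant under rigid motion and atom reordering", {
  m <- fx("go_patch_oh")
  e0 <- potential_energy(m)$E_GDDS
  m2 <- transform_molecule(m, rotation_matrix(c(2, -1, 3), 0.91), c(11, -6, 4))
  expect_lt(abs(potential_energy(m2)$E_GDDS - e0), 1e-6)
  set.seed(17)
  m3 <- renumber_molecule(m, sample(n_atoms(m)))
  expect_lt(abs(potential_energy(m3)$E_GDDS - e0), 1e-9)
})

test_that("benzene stacks over the patch at the physical interplanar distance", {
  b <- fx("benzene")
  patch <- fx("coronene_patch")
  evalr <- ff_engine()$prepare(patch, b)
  zs <- seq(2.8, 5.0, by = 0.05)
  es <- vapply(zs, function(z)
    evalr(sweep(coords(b), 2, c(0, 0, z), `+`))$E_Delta, 0)
  zopt <- zs[which.min(es)]
  expect_gte(zopt, 3.2)
  expect_lte(zopt, 4.2)
  expect_lt(min(es), -4)  # clearly bound
})

test_that("missing vdW parameters raise a clear error", {
  m <- molecule(data.frame(element = "C", type = "C.weird", x = c(0, 5),
                           y = 0, z = 0))
  expect_error(potential_energy(m), "C.weird")
})
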