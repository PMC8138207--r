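test_that("molecule construction enforces the structural invariants", {
  a <- data.frame(element = c("C", "C"), type = c("C.3", "C.3"),
                  x = c(0, 1.5), y = 0, z = 0)
  expect_s3_class(molecule(a, data.frame(i = 1, j = 2, order = "1")), "qmol")
  expect_error(molecule(a, data.frame(i = 1, j = 1, order = "1")), "self-bond")
  expect_error(molecule(a, data.frame(i = c(1, 2), j = c(2, 1),
                                      order = "1")), "duplicate")
  expect_error(molecule(a, data.frame(i = 1, j = 3, order = "1")),
               "non-existent")
  a$x[1] <- NaN
  expect_error(molecule(a, data.frame(i = 1, j = 2, order = "1")),
               "non-finite")
})

test_that("total formal charge sums per-atom charges", {
  g <- build_circular_graphene(8)
  expect_identical(total_formal_charge(g), 0L)
  a <- data.frame(element = c("O", "N"), type = c("O.co2", "N.4"),
                  x = c(0, 3), y = 0, z = 0,
                  formal_charge = c(-1L, 1L))
  expect_identical(total_formal_charge(molecule(a)), 0L)
  a$formal_charge <- c(-1L, 0L)
  expect_identical(total_formal_charge(molecule(a)), -1L)
})

test_that("longest intramolecular distance matches geometry and brute force", {
  a <- data.frame(element = "C", type = "C.3", x = c(0, 3), y = c(0, 4),
                  z = 0)
  expect_equal(longest_intramolecular_distance(molecule(a)), 5.0)
  single <- molecule(a[1, ])
  expect_equal(longest_intramolecular_distance(single), 0)
  expect_error(longest_intramolecular_distance(
    molecule(a[0, ])), "empty")
  set.seed(31)
  xyz <- matrix(rnorm(30, sd = 4), 10, 3)
  m <- molecule(data.frame(element = "C", type = "C.3",
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  brute <- 0
  for (i in 1:9) for (j in (i + 1):10)
    brute <- max(brute, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  expect_equal(longest_intramolecular_distance(m), brute)
  # rigid-motion invariance
  R <- rotation_matrix(c(1, 2, 3), 0.83)
  m2 <- transform_molecule(m, R, c(-4, 7, 2))
  expect_equal(longest_intramolecular_distance(m2),
               longest_intramolecular_distance(m), tolerance = 1e-12)
})

test_that("mol2 round-trip preserves atoms, bonds, types and charges", {
  m <- fx("benzene")
  path <- withr::local_tempfile(fileext = ".mol2")
  write_mol2(m, path)
  m2 <- read_mol2(path)
  expect_equal(m2$atoms$element, m$atoms$element)
  expect_equal(m2$atoms$type, m$atoms$type)
  expect_equal(coords(m2), coords(m), tolerance = 1e-4, ignore_attr = TRUE)
  expect_lt(max(abs(m2$atoms$charge - m$atoms$charge)), 1e-6)
  expect_equal(m2$bonds[, c("i", "j", "order")], m$bonds[, c("i", "j", "order")])
})

test_that("mol2 energy annotations are comment lines and files stay standard", {
  m <- fx("methanol")
  rep <- energy_report(-100, E_G = -60, E_lig = -15)
  path <- withr::local_tempfile(fileext = ".mol2")
  write_mol2(m, path, energies = rep)
  lines <- readLines(path)
  expect_true(any(grepl("^# E_Delta=-25.0000", lines)))
  expect_true(any(grepl("^# E_GDDS=-100.0000", lines)))
  m2 <- read_mol2(path)  # still parseable
  expect_equal(n_atoms(m2), n_atoms(m))
  # without energies there are no comment lines
  write_mol2(m, path)
  expect_false(any(grepl("^#", readLines(path))))
})

test_that("mol2 parser reads minimal records and reports malformed input", {
  path <- withr::local_tempfile(fileext = ".mol2")
  writeLines(c("@<TRIPOS>MOLECULE", "tiny", " 2 1", "SMALL", "NO_CHARGES",
               "@<TRIPOS>ATOM",
               " 1 C1 0.0 0.0 0.0 C.3",
               " 2 O1 1.43 0.0 0.0 O.3",
               "@<TRIPOS>BOND", " 1 1 2 1"), path)
  m <- read_mol2(path)
  expect_equal(n_atoms(m), 2)
  expect_equal(nrow(m$bonds), 1)
  expect_equal(m$atoms$type, c("C.3", "O.3"))

  writeLines(c("@<TRIPOS>MOLECULE", "bad", " 1 0", "SMALL", "NO_CHARGES",
               "@<TRIPOS>ATOM", " 1 C1 oops 0.0 0.0 C.3",
               "@<TRIPOS>BOND"), path)
  expect_error(read_mol2(path), "line 7")
  writeLines(c("@<TRIPOS>MOLECULE", "nobonds", " 1 0", "SMALL", "NO_CHARGES",
               "@<TRIPOS>ATOM", " 1 C1 0.0 0.0 0.0 C.3"), path)
  expect_error(read_mol2(path), "BOND")
})

test_that("xyz output carries the total charge and multiplicity 1", {
  m <- fx("methanol")
  m$atoms$formal_charge[2] <- -1L
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(m, path)
  lines <- readLines(path)
  expect_equal(as.integer(lines[1]), n_atoms(m))
  expect_match(lines[2], "charge=-1 multiplicity=1")
})

test_that("sdf reading populates atoms, bonds and types", {
  skip_if_not_installed("ChemmineR")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "ethanol", "  test", "",
    "  9  8  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0",
    "    1.5200    0.0000    0.0000 C   0  0",
    "    2.0000    1.3500    0.0000 O   0  0",
    "   -0.4000   -0.5000    0.9000 H   0  0",
    "   -0.4000   -0.5000   -0.9000 H   0  0",
    "   -0.4000    1.0000    0.0000 H   0  0",
    "    1.9000   -0.5200    0.9000 H   0  0",
    "    1.9000   -0.5200   -0.9000 H   0  0",
    "    2.9600    1.3300    0.0000 H   0  0",
    "  1  2  1  0", "  1  4  1  0", "  1  5  1  0", "  1  6  1  0",
    "  2  3  1  0", "  2  7  1  0", "  2  8  1  0", "  3  9  1  0",
    "M  END", "$$$$"), path)
  mols <- read_sdf(path)
  expect_length(mols, 1)
  m <- mols[[1]]
  expect_equal(n_atoms(m), 9)
  expect_equal(nrow(m$bonds), 8)
  expect_equal(m$atoms$type[1:3], c("C.3", "C.3", "O.3"))
})
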