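test_that("XYZ input parses minimal and multi-record files", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "lone carbon", "C 0 0 0"), path)
  mols <- readStructures(path, "xyz", chargeSource = "assign")
  expect_length(mols, 1L)
  expect_equal(nAtoms(mols[[1]]), 1L)
  expect_equal(nrow(bonds(mols[[1]])), 0L)
  # optional 4th column = partial charges
  writeLines(c("2", "charged pair", "C 0 0 0 0.25", "O 5 0 0 -0.25"), path)
  m <- readStructures(path, "xyz", chargeSource = "file")[[1]]
  expect_equal(charges(m), c(0.25, -0.25))
  # chargeSource = file without charges present must fail
  writeLines(c("1", "bare", "C 0 0 0"), path)
  expect_error(readStructures(path, "xyz", chargeSource = "file"),
               "charges")
})

test_that("XYZ bond inference follows the covalent-radius-sum rule", {
  path <- withr::local_tempfile(fileext = ".xyz")
  # C-C covalent radii sum = 1.52; threshold at tol 1.2 is 1.824 A
  writeLines(c("2", "bonded", "C 0 0 0", "C 1.5 0 0"), path)
  m <- readStructures(path, "xyz", chargeSource = "assign")[[1]]
  expect_equal(nrow(bonds(m)), 1L)
  expect_equal(nrow(enumerateAngles(m)), 0L)
  writeLines(c("2", "apart", "C 0 0 0", "C 2.0 0 0"), path)
  m <- readStructures(path, "xyz", chargeSource = "assign")[[1]]
  expect_equal(nrow(bonds(m)), 0L)
})

test_that("malformed structures fail loudly with the record index", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "truncated", "C 0 0 0"), path)
  expect_error(readStructures(path, "xyz", chargeSource = "assign"),
               "record 1")
  writeLines(c("1", "mystery element", "Xx 0 0 0"), path)
  expect_error(readStructures(path, "xyz", chargeSource = "assign"),
               "unknown element")
})

test_that("SDF charges pass through from the property block", {
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "probe", "  test", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "M  END",
    "> <ATOM.PARTIAL.CHARGES>",
    "1 -0.4", "2 0.4",
    "", "$$$$"), path)
  m <- readStructures(path, "sdf", chargeSource = "file")[[1]]
  expect_equal(charges(m)[1], -0.4)
  expect_equal(elements(m), c("C", "O"))
  expect_equal(nrow(bonds(m)), 1L)
})

test_that("SDF write-then-read round-trips elements, coordinates, charges", {
  m0 <- toyMolecule("toy-05")
  path <- withr::local_tempfile(fileext = ".sdf")
  writeSDF(m0, path)
  m1 <- readStructures(path, "sdf", chargeSource = "file")[[1]]
  expect_identical(elements(m1), elements(m0))
  expect_equal(coords(m1), coords(m0), tolerance = 1e-4)  # printed precision
  expect_equal(charges(m1), charges(m0))
  expect_equal(nrow(bonds(m1)), nrow(bonds(m0)))
})

test_that("angle enumeration matches brute force and the degree formula", {
  # water-like: central O bonded to two H -> one angle
  w <- toyMolecule("bent-triatomic")
  expect_equal(nrow(enumerateAngles(w)), 1L)
  # linear chain of 4 -> two angles
  expect_equal(nrow(enumerateAngles(toyMolecule("linear-chain-4"))), 2L)
  # random graphs vs exhaustive enumeration and the sum-of-degrees count
  for (seed in 1:5) {
    bnd <- randomBondGraph(8L, 9L, seed)
    m <- molecule(rep("C", 8L), matrix(rnorm(24), 8L, 3L), bonds = bnd)
    got <- enumerateAngles(m)
    want <- oracleAngles(8L, bnd)
    expect_equal(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want)) {
      key <- function(a) paste(a[, 1], a[, 2], a[, 3])
      expect_setequal(key(got), key(want))
    }
    deg <- tabulate(c(bnd[, 1], bnd[, 2]), nbins = 8L)
    expect_equal(nrow(got), sum(deg * (deg - 1) / 2))
  }
})

test_that("electronegativity-equalization charges are physically sensible", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "water", "O 0 0 0", "H 0.96 0 0", "H -0.24 0.93 0"), path)
  m <- readStructures(path, "xyz", chargeSource = "assign")[[1]]
  q <- charges(m)
  expect_lt(q[1], 0)             # oxygen negative
  expect_true(all(q[2:3] > 0))   # hydrogens positive
  expect_equal(sum(q), 0, tolerance = 1e-12)  # charge conserved
})
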