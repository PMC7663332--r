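ff <- defaultForcefield()

test_that("nonbonded energy matches closed forms and a brute-force oracle", {
  # a single atom has no pairs
  expect_equal(nonbondedEnergy(molecule("C", matrix(0, 1, 3))), 0)
  # two neutral atoms at the Lennard-Jones minimum separation: E = -eps
  rmin <- 2 * ff$lj$rminHalf[ff$lj$element == "C"]
  eps <- ff$lj$eps[ff$lj$element == "C"]
  m <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(rmin, 0, 0)))
  expect_equal(nonbondedEnergy(m), -eps, tolerance = 1e-12)
  # 5-atom toy vs an exhaustive pair sum (pairs (3,4) and (3,5) are the
  # only ones beyond the 1-2/1-3 exclusions; both are 1-4 pairs)
  toy <- toyMolecule("toy-05")
  xyz <- coords(toy); q <- charges(toy); el <- elements(toy)
  pairE <- function(i, j) {
    li <- match(el[i], ff$lj$element); lj_ <- match(el[j], ff$lj$element)
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    e <- sqrt(ff$lj$eps[li] * ff$lj$eps[lj_])
    rm <- ff$lj$rminHalf[li] + ff$lj$rminHalf[lj_]
    e * ((rm / r)^12 - 2 * (rm / r)^6) + ff$coulombK * q[i] * q[j] / r
  }
  want <- ff$scale14 * (pairE(3, 4) + pairE(3, 5))
  expect_equal(nonbondedEnergy(toy), want, tolerance = 1e-9)
  # coincident atoms are rejected
  bad <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(nonbondedEnergy(bad), "zero interatomic distance")
})

test_that("repulsion of like charges decays monotonically beyond the LJ minimum", {
  rmin <- 2 * ff$lj$rminHalf[ff$lj$element == "C"]
  ds <- seq(rmin, rmin + 6, length.out = 25)
  es <- sapply(ds, function(d) {
    nonbondedEnergy(molecule(c("C", "C"), rbind(c(0, 0, 0), c(d, 0, 0)),
                             charges = c(0.3, 0.3)))
  })
  expect_true(all(diff(es) < 0))
})

test_that("angle-bend energy is harmonic in the displacement", {
  # equilibrium geometry scores zero
  th0 <- 104.5 * pi / 180
  eq <- molecule(c("O", "H", "H"),
                 rbind(c(0, 0, 0), c(0.96, 0, 0),
                       c(0.96 * cos(th0), 0.96 * sin(th0), 0)),
                 bonds = rbind(c(1L, 2L), c(1L, 3L)))
  expect_equal(angleBendEnergy(eq), 0, tolerance = 1e-12)
  # a 10-degree displacement scores exactly k * delta^2
  bent <- toyMolecule("bent-triatomic")
  expect_equal(angleBendEnergy(bent), 60 * (10 * pi / 180)^2,
               tolerance = 1e-9)
  # multi-angle molecule equals the term-by-term hand sum
  chain <- toyMolecule("linear-chain-4")
  xyz <- coords(chain)
  want <- sum(sapply(list(c(1, 2, 3), c(2, 3, 4)), function(t) {
    60 * (oracleAngleAt(xyz, t[1], t[2], t[3]) - 109.47 * pi / 180)^2
  }))
  expect_equal(angleBendEnergy(chain), want, tolerance = 1e-9)
  # coincident atoms in a triplet are rejected
  bad <- molecule(c("C", "C", "C"),
                  rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                  bonds = rbind(c(1L, 2L), c(2L, 3L)))
  expect_error(angleBendEnergy(bad), "degenerate")
})

test_that("vsa_pol counts only atoms that are both donor and acceptor", {
  # alkane-like: no N/O at all
  alkane <- molecule(c("C", "H", "H"),
                     rbind(c(0, 0, 0), c(1.1, 0, 0), c(-1.1, 0, 0)),
                     bonds = rbind(c(1L, 2L), c(1L, 3L)))
  expect_equal(vsaPol(alkane), 0)
  # a lone hydroxyl oxygen (H bonded but placed far: no occlusion)
  # contributes its full vdW sphere
  oh <- molecule(c("O", "H"), rbind(c(0, 0, 0), c(3.5, 0, 0)),
                 bonds = rbind(c(1L, 2L)))
  expect_equal(vsaPol(oh), 4 * pi * 1.52^2, tolerance = 1e-6)
  # hydroxyl + ether oxygen: only the hydroxyl one counts
  mixed <- molecule(c("O", "H", "C", "O", "C"),
                    rbind(c(0, 0, 0), c(3.5, 0, 0), c(20, 0, 0),
                          c(23, 0, 0), c(26, 0, 0)),
                    bonds = rbind(c(1L, 2L), c(3L, 4L), c(4L, 5L)))
  expect_equal(vsaPol(mixed), 4 * pi * 1.52^2, tolerance = 1e-6)
  # amide-like nitrogen is excluded even with an H
  amide <- molecule(c("N", "H", "C", "O"),
                    rbind(c(0, 0, 0), c(1.0, 0, 0), c(-1.35, 0, 0),
                          c(-2.0, 1.0, 0)),
                    bonds = rbind(c(1L, 2L), c(1L, 3L), c(3L, 4L)),
                    bondOrders = c(1, 1, 2))
  expect_equal(vsaPol(amide), 0)
})

test_that("the assembled descriptor vector is consistent and invariant", {
  cfg <- descriptorConfig()
  # a single neutral atom scores zero on every term
  v0 <- computeDescriptors(molecule("C", matrix(0, 1, 3)), cfg)
  expect_equal(unname(v0), rep(0, 6))
  expect_named(v0, descriptorNameSet())
  # composite fixture equals the vector assembled from the per-term paths
  toy <- toyMolecule("toy-05")
  v <- computeDescriptors(toy, cfg)
  s <- accessibleSurfaceArea(toy, cfg$probeRadius, cfg$nSpherePoints)
  cs <- casaTerms(s, charges(toy), cfg$casaNegMode)
  expect_equal(v[["E_nb"]], nonbondedEnergy(toy, ff))
  expect_equal(v[["E_ang"]], angleBendEnergy(toy, ff))
  expect_equal(v[["ASA_neg"]], cs$ASA_neg)
  expect_equal(v[["CASA_pos"]], cs$CASA_pos)
  expect_equal(v[["CASA_neg"]], cs$CASA_neg)
  # recomputation is bit-identical
  expect_identical(v, computeDescriptors(toy, cfg))
  # rigid-body motion leaves all six descriptors unchanged
  set.seed(42)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  moved <- molecule(elements(toy), coords(toy) %*% Q +
                      matrix(c(5, -3, 2), nAtoms(toy), 3, byrow = TRUE),
                    charges = charges(toy), bonds = bonds(toy),
                    bondOrders = bondOrders(toy))
  vm <- computeDescriptors(moved, cfg)
  expect_equal(vm, v, tolerance = 1e-6)
})

test_that("descriptor tables carry one row per molecule with canonical columns", {
  tab <- descriptorTable(list(toyMolecule("toy-05"),
                              toyMolecule("bent-triatomic")))
  expect_equal(nrow(tab), 2L)
  expect_identical(names(tab), c("id", descriptorNameSet()))
})
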