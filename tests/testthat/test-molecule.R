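test_that("bond distance matrix gives known path lengths", {
  eth <- ethanol_fix()
  D <- bond_distance_matrix(eth)
  expect_equal(diag(D), rep(0, 9))
  expect_true(isSymmetric(D))
  # O (atom 3) to the methyl carbon (atom 1): C-C-O path
  expect_identical(D[1, 3], 2)
  benz <- benzene_fix()
  Db <- bond_distance_matrix(benz)
  expect_identical(Db[1, 4], 3)  # para carbons
})

test_that("bond distance matrix matches Floyd-Warshall on random trees", {
  set.seed(42)
  for (rep in 1:8) {
    mol <- random_tree_mol(sample(5:20, 1))
    expect_equal(bond_distance_matrix(mol), floyd_warshall_oracle(mol))
  }
})

test_that("disconnected fragments get infinite distances", {
  two <- molecule("pair",
    atoms = data.frame(element = c("C", "C", "C"),
                       x = c(0, 1.5, 9), y = 0, z = 0),
    bonds = data.frame(a1 = 1, a2 = 2, order = 1))
  D <- bond_distance_matrix(two)
  expect_identical(D[1, 3], Inf)
  expect_identical(D[1, 2], 1)
})

test_that("ring perception flags exactly the cyclic atoms", {
  expect_equal(sum(perceive_rings(benzene_fix())), 6)
  cats <- atom_categories(pyridine_fix())
  expect_equal(sum(cats$is_ring_carbon), 5)
  expect_equal(sum(cats$is_ring_nitrogen), 1)
  bip <- biphenyl_fix()
  ring <- perceive_rings(bip)
  expect_equal(sum(ring), 12)
  expect_false(any(ring[atom_elements(bip) == "H"]))
  # acyclic molecules have no ring atoms
  expect_false(any(perceive_rings(ethanol_fix())))
})

test_that("centre of mass is the mass-weighted mean and rigid-equivariant", {
  h2 <- molecule("h2", atoms = data.frame(element = c("H", "H"),
                                          x = c(0, 2), y = 0, z = 0),
                 bonds = data.frame(a1 = 1, a2 = 2, order = 1))
  expect_equal(center_of_mass(h2), c(1, 0, 0))
  one <- molecule("he", atoms = data.frame(element = "C", x = 1.2, y = -3,
                                           z = 0.5))
  expect_equal(center_of_mass(one), c(1.2, -3, 0.5))
  # 5-atom toy with unequal masses against hand arithmetic
  toy <- molecule("toy",
    atoms = data.frame(element = c("C", "O", "N", "H", "H"),
                       x = c(0, 1, -1, 2, -2), y = c(0, 1, 1, 0, 0),
                       z = c(0, 0, 0, 1, -1)),
    bonds = data.frame(a1 = c(1, 1, 1, 1), a2 = 2:5, order = 1))
  m <- c(12.011, 15.999, 14.007, 1.008, 1.008)
  expect_equal(center_of_mass(toy),
               colSums(m * cbind(c(0, 1, -1, 2, -2), c(0, 1, 1, 0, 0),
                                 c(0, 0, 0, 1, -1))) / sum(m))
  set.seed(7)
  mol <- ethanol_fix()
  molt <- rigid_transform(mol)
  co <- as.matrix(molt$atoms[, c("x", "y", "z")])
  # com of the transformed molecule is the transformed com: recover via
  # nearest atom distances staying equal
  d0 <- sqrt(colSums((t(as.matrix(mol$atoms[, c("x", "y", "z")])) -
                        center_of_mass(mol))^2))
  d1 <- sqrt(colSums((t(co) - center_of_mass(molt))^2))
  expect_equal(d0, d1, tolerance = 1e-10)
})

test_that("molecule constructor enforces its invariants", {
  expect_error(molecule("bad", data.frame(element = "C", x = Inf, y = 0, z = 0)),
               "finite")
  expect_error(molecule("bad", data.frame(element = "Xx", x = 0, y = 0, z = 0)),
               "Xx")
  expect_error(
    molecule("bad", data.frame(element = c("C", "C"), x = c(0, 1), y = 0, z = 0),
             bonds = data.frame(a1 = 1, a2 = 1, order = 1)),
    "distinct")
  # activity consistency: pic50 must equal 9 - log10(ic50_nM)
  expect_error(
    molecule("act", data.frame(element = "C", x = 0, y = 0, z = 0),
             ic50_nM = 10, pic50 = 5), "inconsistent")
  ok <- molecule("act", data.frame(element = "C", x = 0, y = 0, z = 0),
                 ic50_nM = 10)
  expect_equal(ok$pic50, 8)
})

test_that("largest fragment strips counterions", {
  salt <- molecule("salt",
    atoms = data.frame(element = c("C", "C", "O", "Na"),
                       x = c(0, 1.5, 2.6, 8), y = 0, z = 0),
    bonds = data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1))
  frag <- largest_fragment(salt)
  expect_equal(n_atoms <- nrow(frag$atoms), 3)
  expect_false("Na" %in% frag$atoms$element)
  expect_equal(nrow(frag$bonds), 2)
  # single-fragment molecules pass through untouched
  expect_identical(largest_fragment(ethanol_fix()), ethanol_fix())
})
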