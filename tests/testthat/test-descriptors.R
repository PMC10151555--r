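test_that("rsa is the msa/sasa ratio with guarded domain", {
  expect_equal(rsa(460.1, 677.8), 0.6788, tolerance = 1e-4)
  expect_identical(rsa(5, 5), 1)
  expect_identical(rsa(0, 3), 0)
  expect_error(rsa(1, 0), "positive")
  expect_error(rsa(-1, 2), "non-negative")
})

test_that("com_lipohyd_3A counts lipophilic hydrogens near the com", {
  m <- with_charges(methane_fix())
  expect_equal(com_lipohyd_3A(m), 4)   # com ~at C, C-H = 1.09, |q| < 0.2
  nf <- perfluorobenzene_fix()
  expect_equal(com_lipohyd_3A(nf), 0)  # no hydrogens at all
  # rigid-body invariance: the com moves with the molecule
  set.seed(11)
  for (i in 1:3)
    expect_equal(com_lipohyd_3A(rigid_transform(m)), com_lipohyd_3A(m))
})

test_that("pair counts at exact bond distances match hand enumeration", {
  benz <- benzene_fix()
  D <- bond_distance_matrix(benz)
  # each of 6 H sees its 2 ortho ring carbons at 2 bonds
  expect_equal(pair_count_at_distance(benz, "hydrogen", "ring_carbon", 2, D = D), 12)
  # ring-carbon/carbon pairs at 3 bonds: the 3 para pairs
  expect_equal(pair_count_at_distance(benz, "ring_carbon", "carbon", 3, D = D), 3)
  # beyond the graph diameter everything is zero
  expect_equal(pair_count_at_distance(benz, "any", "any", 20, D = D), 0)
  expect_equal(fHringC2B(cyclohexane_fix()), 24)
  expect_equal(fHringC2B(benz), 12)
  expect_equal(fHringC2B(perfluorobenzene_fix()), 0)
  expect_equal(fringCC3B(benz), 3)
  expect_equal(fringCC3B(toluene_fix()), 5)
  expect_equal(fringCC3B(methane_fix()), 0)
})

test_that("pair counts are invariant under atom reordering", {
  set.seed(21)
  mol <- toluene_fix()
  base <- c(fHringC2B(mol), fringCC3B(mol))
  for (r in 1:3) {
    perm <- sample.int(nrow(mol$atoms))
    inv <- order(perm)
    shuffled <- molecule(mol$id, mol$atoms[perm, , drop = FALSE],
                         data.frame(a1 = inv[mol$bonds$a1],
                                    a2 = inv[mol$bonds$a2],
                                    order = mol$bonds$order))
    expect_equal(c(fHringC2B(shuffled), fringCC3B(shuffled)), base)
  }
})

test_that("fringNdon3B pairs ring nitrogens with donors at 3 bonds", {
  expect_equal(fringNdon3B(pyridine_fix()), 0)   # no donors present
  expect_gte(fringNdon3B(proline_fix()), 1)      # carboxyl OH 3 bonds from ring N
})

test_that("fsp2OC9B counts carbons 9 bonds from a carbonyl oxygen", {
  expect_equal(fsp2OC9B(acetone_fix()), 0)       # diameter < 9
  expect_equal(fsp2OC9B(decan2one_fix()), 1)     # O=C2 ... C10 is exactly 9
  # exclusion clause: a symmetric diketone on a 19-carbon chain puts C10 at
  # exactly 9 bonds from BOTH carbonyl oxygens, so it must be dropped
  m <- qsarmlr:::.build_chain_molecule("diket", rep("C", 19),
                                       carbonyl_at = c(2L, 18L))
  D <- bond_distance_matrix(m)
  el <- atom_elements(m)
  oxy <- which(el == "O")          # atoms 20 (on C2) and 21 (on C18)
  at9 <- lapply(oxy, function(o) which(D[o, ] == 9 & el == "C"))
  both <- Reduce(intersect, at9)
  expect_true(10 %in% both)        # the midpoint carbon
  expect_equal(fsp2OC9B(m, apply_exclusion = FALSE),
               sum(lengths(at9)))
  expect_equal(fsp2OC9B(m, apply_exclusion = TRUE),
               sum(lengths(at9)) - 2 * length(both))
})

test_that("descriptor matrix is deterministic and row-consistent", {
  mols <- list(benzene_fix(), toluene_fix(), decan2one_fix())
  X1 <- compute_descriptors(mols)
  X2 <- compute_descriptors(mols)
  expect_identical(X1, X2)
  expect_equal(dim(X1), c(3, 6))
  expect_false(anyNA(X1))
  # the benzene row equals the six individually computed values
  b <- with_charges(benzene_fix())
  sa <- surface_areas(b)
  expect_equal(unlist(X1["benzene", ]),
               c(rsa = rsa(sa[["msa"]], sa[["sasa"]]),
                 com_lipohyd_3A = com_lipohyd_3A(b),
                 fringNdon3B = fringNdon3B(b), fsp2OC9B = fsp2OC9B(b),
                 fHringC2B = fHringC2B(b), fringCC3B = fringCC3B(b)))
  # all named descriptors are non-negative; rsa within its physical band
  expect_true(all(X1 >= 0))
  expect_true(all(X1$rsa > 0 & X1$rsa < 1.2))
})

test_that("a failing molecule is excluded and reported, others survive", {
  bad <- molecule("bad_element", data.frame(element = "Ca", x = 0, y = 0, z = 0))
  expect_warning(X <- compute_descriptors(list(benzene_fix(), bad)), "failed")
  expect_equal(rownames(X), "benzene")
  expect_match(attr(X, "failed"), "bad_element")
})

test_that("OFS pruning removes constant, near-constant and correlated columns", {
  set.seed(5)
  X <- as.data.frame(matrix(rnorm(40 * 20), 40, 20))
  names(X) <- paste0("d", 1:20)
  X$const <- 1
  X$nearconst <- c(rep(0, 39), 1)
  X$dup1 <- X$d1
  X$dup2 <- X$d2
  pruned <- ofs_prune(X)
  expect_false(any(c("const", "nearconst") %in% names(pruned)))
  expect_equal(ncol(pruned), 20)          # 20 independent survivors
  # no surviving pair violates the cutoff (brute-force scan oracle)
  C <- abs(stats::cor(pruned))
  expect_true(all(C[upper.tri(C)] <= 0.90))
  # idempotence
  expect_identical(names(ofs_prune(pruned)), names(pruned))
  # of two identical columns exactly one survives
  expect_equal(sum(c("d1", "dup1") %in% names(pruned)), 1)
})

test_that("OFS tie-break keeps the column more correlated with activity", {
  set.seed(8)
  a <- rnorm(60)
  y <- a + rnorm(60, sd = 0.2)
  X <- data.frame(noisy = a + rnorm(60, sd = 0.45), clean = a)
  # columns are correlated beyond the cutoff; 'clean' predicts y better
  stopifnot(abs(cor(X$noisy, X$clean)) > 0.9)
  kept <- ofs_prune(X, activity = y)
  expect_identical(names(kept), "clean")
})

test_that("descriptor correlation matches the textbook formula", {
  set.seed(13)
  X <- as.data.frame(matrix(rnorm(15), 5, 3))
  C <- descriptor_correlation(X)
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
  expect_true(isSymmetric(C))
  # two-pass formula oracle
  oracle <- function(u, v) {
    um <- mean(u); vm <- mean(v)
    sum((u - um) * (v - vm)) / sqrt(sum((u - um)^2) * sum((v - vm)^2))
  }
  for (i in 1:3) for (j in 1:3)
    expect_equal(C[i, j], oracle(X[[i]], X[[j]]), tolerance = 1e-12)
  # a column against its negation
  Y <- data.frame(a = X[[1]], b = -X[[1]] )
  expect_equal(descriptor_correlation(cbind(Y, c = X[[2]]))["a", "b"], -1)
  expect_error(descriptor_correlation(data.frame(a = rep(1, 5), b = rnorm(5))),
               "a")
})
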