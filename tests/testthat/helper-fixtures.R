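# Fixed-coordinate molecular fixtures built in code, plus small oracles.

hexagon <- function(r = 1.397) {
  ang <- 2 * pi * (0:5) / 6
  cbind(r * cos(ang), r * sin(ang), 0)
}

# six-membered aromatic ring with one substituent atom per ring position
ring6_mol <- function(id, ring_elements = rep("C", 6),
                      sub_elements = rep("H", 6), kekulize = TRUE) {
  co <- hexagon()
  atoms <- data.frame(element = ring_elements,
                      x = co[, 1], y = co[, 2], z = co[, 3])
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1),
                      order = if (kekulize) rep(c(2L, 1L), 3) else rep(1L, 6))
  blen <- c(H = 1.09, F = 1.35, C = 1.50)
  for (i in 1:6) {
    e <- sub_elements[i]
    if (is.na(e)) next
    scale <- (1.397 + blen[[e]]) / 1.397
    atoms <- rbind(atoms, data.frame(element = e, x = co[i, 1] * scale,
                                     y = co[i, 2] * scale, z = 0))
    bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms), order = 1L))
  }
  molecule(id, atoms, bonds)
}

benzene_fix <- function() ring6_mol("benzene")

pyridine_fix <- function()
  ring6_mol("pyridine", ring_elements = c("N", rep("C", 5)),
            sub_elements = c(NA, rep("H", 5)))

perfluorobenzene_fix <- function()
  ring6_mol("perfluorobenzene", sub_elements = rep("F", 6))

# toluene: benzene with one H replaced by a methyl group
toluene_fix <- function() {
  m <- ring6_mol("toluene", sub_elements = c("C", rep("H", 5)))
  # atom 7 is the methyl carbon; give it 3 hydrogens
  pos <- c(m$atoms$x[7], m$atoms$y[7], m$atoms$z[7])
  dirv <- pos / sqrt(sum(pos^2))
  for (j in 1:3) {
    ang <- 2 * pi * j / 3
    hp <- pos + 1.09 * (0.5 * dirv + 0.87 * c(-dirv[2] * cos(ang),
                                              dirv[1] * cos(ang), sin(ang)))
    m$atoms <- rbind(m$atoms, data.frame(element = "H", x = hp[1], y = hp[2],
                                         z = hp[3], charge = NA_real_))
    m$bonds <- rbind(m$bonds, data.frame(a1 = 7L, a2 = nrow(m$atoms),
                                         order = 1L))
  }
  molecule(m$id, m$atoms, m$bonds)
}

cyclohexane_fix <- function() {
  co <- hexagon(1.25)
  co[, 3] <- rep(c(0.25, -0.25), 3)      # chair-like pucker
  atoms <- data.frame(element = rep("C", 6), x = co[, 1], y = co[, 2],
                      z = co[, 3])
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 1L)
  for (i in 1:6) for (s in c(1, -1)) {
    dirv <- c(co[i, 1], co[i, 2], 0) / sqrt(sum(co[i, 1:2]^2))
    hp <- co[i, ] + 1.09 * (0.7 * dirv * s + c(0, 0, 0.7) * sign(co[i, 3]) * s)
    atoms <- rbind(atoms, data.frame(element = "H", x = hp[1], y = hp[2],
                                     z = hp[3]))
    bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms), order = 1L))
  }
  molecule("cyclohexane", atoms, bonds)
}

biphenyl_fix <- function() {
  co1 <- hexagon()
  co2 <- hexagon()
  co2[, 1] <- -co2[, 1] + 2 * 1.397 + 1.48   # mirrored ring shifted +x
  atoms <- data.frame(element = rep("C", 12),
                      x = c(co1[, 1], co2[, 1]), y = c(co1[, 2], co2[, 2]),
                      z = 0)
  bonds <- rbind(
    data.frame(a1 = 1:6, a2 = c(2:6, 1), order = rep(c(2L, 1L), 3)),
    data.frame(a1 = 6 + (1:6), a2 = 6 + c(2:6, 1), order = rep(c(2L, 1L), 3)),
    data.frame(a1 = 1L, a2 = 7L, order = 1L))   # both para atoms at angle 0
  for (i in c(2:6, 8:12)) {
    ctr <- if (i <= 6) c(0, 0) else c(2 * 1.397 + 1.48, 0)
    dirv <- c(atoms$x[i] - ctr[1], atoms$y[i] - ctr[2], 0)
    dirv <- dirv / sqrt(sum(dirv^2))
    atoms <- rbind(atoms, data.frame(element = "H",
                                     x = atoms$x[i] + 1.09 * dirv[1],
                                     y = atoms$y[i] + 1.09 * dirv[2], z = 0))
    bonds <- rbind(bonds, data.frame(a1 = i, a2 = nrow(atoms), order = 1L))
  }
  molecule("biphenyl", atoms, bonds)
}

ethanol_fix <- function() {
  atoms <- data.frame(
    element = c("C", "C", "O", "H", "H", "H", "H", "H", "H"),
    x = c(0, 1.51, 2.22, -0.5, -0.5, -0.5, 2.0, 2.0, 3.17),
    y = c(0, 0, 1.16, 0.9, -0.9, 0, -0.9, 0.7, 1.10),
    z = c(0, 0, 0, 0.3, 0.3, -1.0, -0.3, -0.9, 0.3))
  bonds <- data.frame(a1 = c(1, 2, 1, 1, 1, 2, 2, 3),
                      a2 = c(2, 3, 4, 5, 6, 7, 8, 9), order = 1L)
  molecule("ethanol", atoms, bonds)
}

methane_fix <- function() {
  t <- 1.09 / sqrt(3)
  atoms <- data.frame(element = c("C", "H", "H", "H", "H"),
                      x = c(0, t, -t, -t, t), y = c(0, t, -t, t, -t),
                      z = c(0, t, t, -t, -t))
  bonds <- data.frame(a1 = 1, a2 = 2:5, order = 1L)
  molecule("methane", atoms, bonds)
}

formic_acid_fix <- function() {
  atoms <- data.frame(element = c("C", "O", "O", "H", "H"),
                      x = c(0, 1.05, -0.68, -1.62, -0.55),
                      y = c(0, 0.65, 1.06, 0.85, -1.0),
                      z = 0)
  bonds <- data.frame(a1 = c(1, 1, 3, 1), a2 = c(2, 3, 4, 5),
                      order = c(2L, 1L, 1L, 1L))
  molecule("formic_acid", atoms, bonds)
}

acetone_fix <- function() {
  m <- qsarmlr:::.build_chain_molecule("acetone", c("C", "C", "C"),
                                       carbonyl_at = 2L)
  m
}

decan2one_fix <- function()
  qsarmlr:::.build_chain_molecule("decan2one", rep("C", 10), carbonyl_at = 2L)

# pyrrolidine ring with a carboxylic acid on the carbon next to N
proline_fix <- function() {
  ang <- 2 * pi * (0:4) / 5
  r <- 1.48 / (2 * sin(pi / 5))
  atoms <- data.frame(element = c("N", rep("C", 4)),
                      x = r * cos(ang), y = r * sin(ang), z = 0)
  bonds <- data.frame(a1 = 1:5, a2 = c(2:5, 1), order = 1L)
  # carboxyl on atom 2: C6(=O7)(O8-H)
  d <- c(cos(ang[2]), sin(ang[2]), 0)
  p2 <- c(atoms$x[2], atoms$y[2], 0)
  atoms <- rbind(atoms,
    data.frame(element = "C", x = p2[1] + 1.52 * d[1],
               y = p2[2] + 1.52 * d[2], z = 0),
    data.frame(element = "O", x = p2[1] + 1.52 * d[1] + 0.6,
               y = p2[2] + 1.52 * d[2] + 1.05, z = 0),
    data.frame(element = "O", x = p2[1] + 1.52 * d[1] + 0.72,
               y = p2[2] + 1.52 * d[2] - 1.1, z = 0))
  bonds <- rbind(bonds, data.frame(a1 = c(2L, 6L, 6L), a2 = c(6L, 7L, 8L),
                                   order = c(1L, 2L, 1L)))
  fb <- qsarmlr:::.fill_hydrogens(
    cbind(atoms, charge = NA_real_), bonds)
  molecule("proline_like", fb$atoms, fb$bonds)
}

# --- oracles -------------------------------------------------------------

# independent all-pairs shortest path oracle (Floyd-Warshall)
floyd_warshall_oracle <- function(mol) {
  n <- nrow(mol$atoms)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(nrow(mol$bonds)))
    D[mol$bonds$a1[i], mol$bonds$a2[i]] <-
      D[mol$bonds$a2[i], mol$bonds$a1[i]] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# random labelled tree on n atoms (all carbons, arbitrary coords)
random_tree_mol <- function(n, id = "tree") {
  parents <- c(NA, vapply(2:n, function(i) sample.int(i - 1, 1), 1L))
  atoms <- data.frame(element = rep("C", n),
                      x = stats::runif(n, -5, 5), y = stats::runif(n, -5, 5),
                      z = stats::runif(n, -5, 5))
  bonds <- data.frame(a1 = parents[-1], a2 = 2:n, order = 1L)
  molecule(id, atoms, bonds)
}

# random rigid-body transform applied to a molecule
rigid_transform <- function(mol) {
  M <- matrix(stats::rnorm(9), 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- stats::runif(3, -10, 10)
  co <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% Q
  mol$atoms$x <- co[, 1] + shift[1]
  mol$atoms$y <- co[, 2] + shift[2]
  mol$atoms$z <- co[, 3] + shift[3]
  mol
}

# charge every fixture the same way the pipeline does
with_charges <- function(mol) assign_partial_charges(mol)
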