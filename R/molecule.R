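#' @keywords internal
"_PACKAGE"

# Standard atomic masses (amu) and Bondi-style van der Waals radii (Angstrom)
# for the elements that occur in drug-like small molecules.
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Br = 79.904, I = 126.904
)

.VDW_RADII <- c(
  H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
  Na = 2.27, Mg = 1.73, Si = 2.10, P = 1.80, S = 1.80,
  Cl = 1.75, K = 2.75, Ca = 2.31, Br = 1.85, I = 1.98
)

#' Construct a molecule
#'
#' A molecule is an atom table plus a bond table. Atoms carry element symbols,
#' 3D coordinates in Angstrom and (once assigned) Gasteiger partial charges;
#' bonds carry integer orders. Optionally an experimental IC50 (nM) and/or its
#' pIC50 may be attached: pIC50 = -log10(IC50 in molar) = 9 - log10(IC50 in nM).
#'
#' @param id compound identifier (character scalar).
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and optionally
#'   `charge` (partial charge, e-units).
#' @param bonds data.frame with columns `a1`, `a2` (1-based atom indices) and
#'   `order` (integer bond order); zero-row data.frame for a single atom.
#' @param ic50_nM optional experimental IC50 in nM (positive).
#' @param pic50 optional pIC50; if both activities are given they must agree
#'   (pic50 = 9 - log10(ic50_nM)) within 1e-6.
#' @return an object of class `"molecule"`.
#' @examples
#' # a minimal hydrogen molecule
#' h2 <- molecule("H2",
#'   atoms = data.frame(element = c("H", "H"), x = c(0, 0.74), y = 0, z = 0),
#'   bonds = data.frame(a1 = 1, a2 = 2, order = 1))
#' center_of_mass(h2)
#' @export
molecule <- function(id, atoms, bonds = NULL, ic50_nM = NULL, pic50 = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  atoms <- as.data.frame(atoms)
  if (!all(c("element", "x", "y", "z") %in% names(atoms)))
    stop("atoms must have columns element, x, y, z")
  if (nrow(atoms) < 1L) stop("molecule needs at least one atom")
  atoms$element <- as.character(atoms$element)
  unknown <- setdiff(unique(atoms$element), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("no mass parameters for element(s): ", paste(unknown, collapse = ", "))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("atom coordinates must be finite")
  if (is.null(atoms$charge)) atoms$charge <- NA_real_

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    if (!all(c("a1", "a2") %in% names(bonds)))
      stop("bonds must have columns a1, a2")
    if (is.null(bonds$order)) bonds$order <- 1L
    n <- nrow(atoms)
    if (any(bonds$a1 == bonds$a2)) stop("bond endpoints must be distinct")
    if (any(bonds$a1 < 1L | bonds$a1 > n | bonds$a2 < 1L | bonds$a2 > n))
      stop("bond endpoint out of range")
  }

  if (!is.null(ic50_nM)) {
    if (!is.finite(ic50_nM) || ic50_nM <= 0) stop("ic50_nM must be positive")
    p <- pic50_from_ic50(ic50_nM)
    if (!is.null(pic50) && abs(pic50 - p) > 1e-6)
      stop("pic50 inconsistent with ic50_nM (expected ", signif(p, 8), ")")
    if (is.null(pic50)) pic50 <- p
  }

  structure(
    list(id = id, atoms = atoms, bonds = bonds,
         ic50_nM = ic50_nM, pic50 = pic50),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s: %d atoms, %d bonds%s>\n", x$id,
              nrow(x$atoms), nrow(x$bonds),
              if (!is.null(x$pic50)) sprintf(", pIC50 = %.3f", x$pic50) else ""))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

atom_elements <- function(mol) mol$atoms$element

atom_coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

atom_masses <- function(mol) unname(.ATOMIC_MASS[mol$atoms$element])

#' Centre of mass of a molecule
#'
#' Mass-weighted mean of all atomic coordinates, hydrogens included.
#'
#' @param mol a [molecule()].
#' @return numeric length-3 vector (Angstrom).
#' @export
center_of_mass <- function(mol) {
  m <- atom_masses(mol)
  drop(crossprod(atom_coords(mol), m)) / sum(m)
}

# adjacency list (list of integer neighbour vectors, 1-based)
adjacency_list <- function(mol) {
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

#' Topological (bond-count) distance matrix
#'
#' Shortest path length in bonds between every atom pair, by breadth-first
#' search from every atom. Atoms in different fragments get `Inf`.
#'
#' @param mol a [molecule()].
#' @return an n x n numeric matrix; 0 on the diagonal, symmetric.
#' @export
bond_distance_matrix <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]]) {
        if (!is.finite(dist[w])) { dist[w] <- d; nxt <- c(nxt, w) }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

#' Ring membership of every atom
#'
#' An atom is a ring atom iff it lies on some cycle of the bond graph, i.e.
#' iff it is an endpoint of a non-bridge bond. On molecular graphs this set
#' equals the union of the smallest-set-of-smallest-rings memberships.
#'
#' @param mol a [molecule()].
#' @return logical vector, one flag per atom.
#' @export
perceive_rings <- function(mol) {
  n <- n_atoms(mol)
  in_ring <- rep(FALSE, n)
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(in_ring)
  # bond (a,b) is on a cycle iff b is still reachable from a with it removed
  for (k in seq_len(nb)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    if (in_ring[a] && in_ring[b]) next  # may still be a bridge between rings
    adj <- vector("list", n)
    for (j in seq_len(nb)) {
      if (j == k) next
      p <- mol$bonds$a1[j]; q <- mol$bonds$a2[j]
      adj[[p]] <- c(adj[[p]], q); adj[[q]] <- c(adj[[q]], p)
    }
    seen <- rep(FALSE, n); seen[a] <- TRUE; frontier <- a
    while (length(frontier) && !seen[b]) {
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]])
        if (!seen[w]) { seen[w] <- TRUE; nxt <- c(nxt, w) }
      frontier <- nxt
    }
    if (seen[b]) in_ring[a] <- in_ring[b] <- TRUE
  }
  in_ring
}

#' Atom category flags used by the descriptor family
#'
#' Derives, for every atom, the chemistry flags the descriptors consume:
#' ring membership, ring nitrogen/carbon, hydrogen-bond donor (N or O with at
#' least one bonded hydrogen), sp2 oxygen (oxygen in a double bond), and
#' lipophilic hydrogen (hydrogen with |partial charge| <= `lipo_charge`,
#' default 0.200 inclusive).
#'
#' @param mol a [molecule()], with charges assigned if lipophilic-hydrogen
#'   flags are wanted.
#' @param lipo_charge absolute partial-charge bound defining a lipophilic
#'   hydrogen (e-units).
#' @return data.frame of logical columns `is_ring`, `is_ring_nitrogen`,
#'   `is_ring_carbon`, `is_donor`, `is_sp2_oxygen`, `is_lipophilic_hydrogen`,
#'   plus convenience columns `is_carbon`, `is_hydrogen`.
#' @export
atom_categories <- function(mol, lipo_charge = 0.200) {
  el <- atom_elements(mol)
  ring <- perceive_rings(mol)
  adj <- adjacency_list(mol)
  has_h <- vapply(adj, function(nb) any(el[nb] == "H"), logical(1))
  dbl <- rep(FALSE, n_atoms(mol))
  if (nrow(mol$bonds)) {
    idx <- mol$bonds$order >= 2L
    dbl[c(mol$bonds$a1[idx], mol$bonds$a2[idx])] <- TRUE
  }
  q <- mol$atoms$charge
  lipo <- el == "H" & !is.na(q) & abs(q) <= lipo_charge
  data.frame(
    is_ring = ring,
    is_ring_nitrogen = ring & el == "N",
    is_ring_carbon = ring & el == "C",
    is_donor = el %in% c("N", "O") & has_h,
    is_sp2_oxygen = el == "O" & dbl,
    is_lipophilic_hydrogen = lipo,
    is_carbon = el == "C",
    is_hydrogen = el == "H")
}

# connected components of the bond graph (integer labels per atom)
fragment_labels <- function(mol) {
  n <- n_atoms(mol)
  adj <- adjacency_list(mol)
  lab <- rep(0L, n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (lab[s]) next
    comp <- comp + 1L
    frontier <- s; lab[s] <- comp
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) for (w in adj[[v]])
        if (!lab[w]) { lab[w] <- comp; nxt <- c(nxt, w) }
      frontier <- nxt
    }
  }
  lab
}

#' Keep the largest connected fragment (salt stripping)
#'
#' Multi-fragment records (salts, solvates) are reduced to their largest
#' fragment before descriptor computation, the usual QSAR curation step.
#' Ties are broken in favour of the fragment with the larger total mass.
#'
#' @param mol a [molecule()].
#' @return a [molecule()] containing only the largest fragment, with bond
#'   indices remapped.
#' @export
largest_fragment <- function(mol) {
  lab <- fragment_labels(mol)
  if (max(lab) == 1L) return(mol)
  m <- atom_masses(mol)
  sizes <- tapply(rep(1L, length(lab)), lab, sum)
  mass <- tapply(m, lab, sum)
  best <- as.integer(names(sizes))[order(-sizes, -mass)][1L]
  keep <- which(lab == best)
  remap <- match(seq_along(lab), keep)
  bonds <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  molecule(mol$id, mol$atoms[keep, , drop = FALSE], bonds,
           ic50_nM = mol$ic50_nM, pic50 = mol$pic50)
}
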