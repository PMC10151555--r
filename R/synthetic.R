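# Synthetic inputs: descriptor/activity matrices following a known linear
# model, and small valence-legal 3D molecules spanning the atom categories
# the descriptors consume (ring nitrogens, donors, sp2 oxygens, lipophilic
# hydrogens). Everything is reproducible from a seed.

.VALENCE <- c(H = 1L, C = 4L, N = 3L, O = 2L, F = 1L, Cl = 1L, Br = 1L,
              S = 2L, P = 3L)

#' Synthetic descriptor/activity dataset with a planted linear model
#'
#' Draws a compound-by-descriptor pool from a correlated multivariate normal
#' (equicorrelation `rho`, unit variances) and generates the activity as
#' y = intercept + X_inf beta + N(0, sigma^2) over the informative columns.
#' `sigma` may be given directly or derived from a target population R2:
#' sigma^2 = Var(X beta) (1 - R2) / R2, with Var(X beta) taken from the
#' realized informative block so the attained R2 concentrates on the target.
#' The defaults are the package's canonical planted benchmark: 150
#' compounds, a 43-descriptor pool, 3 informative descriptors, R2 = 0.9.
#'
#' @param n_compounds number of compounds (default 150).
#' @param n_pool total descriptors in the pool (default 43).
#' @param beta named numeric vector of planted coefficients; names must be
#'   among the pool names `d1..d<n_pool>` (default `d1`, `d2`, `d3` with
#'   coefficients 2, -1.5, 1).
#' @param intercept planted intercept (default 1).
#' @param target_r2 population R2 used to derive `sigma` (default 0.9).
#' @param sigma noise standard deviation; overrides `target_r2` when given.
#' @param rho pairwise descriptor correlation (default 0.2).
#' @param descriptor_style if TRUE, map columns to descriptor-like ranges
#'   (first column squashed to (0, 1) like a surface ratio, the rest rounded
#'   to non-negative counts) before the response is generated.
#' @param seed RNG seed.
#' @return list with `X` (data.frame), `y`, and `truth` (beta, intercept,
#'   sigma, informative names, seed).
#' @export
make_regression_dataset <- function(n_compounds = 150L, n_pool = 43L,
                                    beta = c(d1 = 2, d2 = -1.5, d3 = 1),
                                    intercept = 1, target_r2 = 0.9,
                                    sigma = NULL, rho = 0.2,
                                    descriptor_style = FALSE, seed = NULL) {
  stopifnot(n_pool >= length(beta), all(names(beta) != ""))
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  pool_names <- paste0("d", seq_len(n_pool))
  if (!all(names(beta) %in% pool_names))
    stop("beta names must be within the pool (d1..d", n_pool, ")")
  # equicorrelated MVN via one shared factor: z = sqrt(rho) g + sqrt(1-rho) e
  g <- stats::rnorm(n_compounds)
  Z <- sqrt(rho) * g + sqrt(1 - rho) *
    matrix(stats::rnorm(n_compounds * n_pool), n_compounds, n_pool)
  colnames(Z) <- pool_names
  if (descriptor_style) {
    Z[, 1] <- stats::plogis(Z[, 1])
    if (n_pool > 1L)
      Z[, -1] <- round(pmax(0, 2 + 1.5 * Z[, -1]))
  }
  X <- as.data.frame(Z)
  lin <- as.matrix(X[, names(beta), drop = FALSE]) %*% beta
  if (is.null(sigma)) {
    if (target_r2 <= 0 || target_r2 >= 1) stop("target_r2 must be in (0,1)")
    v <- stats::var(drop(lin))
    sigma <- sqrt(v * (1 - target_r2) / target_r2)
  }
  y <- intercept + drop(lin) + stats::rnorm(n_compounds, 0, sigma)
  list(X = X, y = y,
       truth = list(beta = beta, intercept = intercept, sigma = sigma,
                    informative = names(beta), seed = seed))
}

# --- geometric helpers for template-built molecules ---------------------

# unit vector
.uv <- function(v) v / sqrt(sum(v^2))

# any unit vector orthogonal to v
.ortho <- function(v) {
  u <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .uv(u - sum(u * v) * v)
}

# fill free valences with explicit hydrogens at ~1.09 A
.fill_hydrogens <- function(atoms, bonds) {
  repeat {
    n <- nrow(atoms)
    el <- atoms$element
    used <- rep(0L, n)
    for (i in seq_len(nrow(bonds))) {
      used[bonds$a1[i]] <- used[bonds$a1[i]] + bonds$order[i]
      used[bonds$a2[i]] <- used[bonds$a2[i]] + bonds$order[i]
    }
    deficit <- unname(.VALENCE[el]) - used
    idx <- which(deficit > 0 & el != "H")
    if (!length(idx)) break
    for (a in idx) {
      pos <- c(atoms$x[a], atoms$y[a], atoms$z[a])
      nb <- c(bonds$a2[bonds$a1 == a], bonds$a1[bonds$a2 == a])
      base <- if (length(nb)) {
        ctr <- c(mean(atoms$x[nb]), mean(atoms$y[nb]), mean(atoms$z[nb]))
        d <- pos - ctr
        if (sum(d^2) < 1e-8) c(0, 0, 1) else .uv(d)
      } else c(0, 0, 1)
      o1 <- .ortho(base); o2 <- pracma_cross(base, o1)
      k <- deficit[a]
      for (j in seq_len(k)) {
        ang <- 2 * pi * (j - 1) / max(k, 2) + 0.4
        # single H on a multiply-bonded atom points straight out; otherwise
        # spread hydrogens on a ~tetrahedral cone around the base direction
        tilt <- if (k == 1L && length(nb) >= 2L) 0
                else if (length(nb)) 0.9 else 1.9106
        dirv <- .uv(cos(tilt) * base + sin(tilt) *
                      (cos(ang) * o1 + sin(ang) * o2))
        hp <- pos + 1.09 * dirv
        atoms <- rbind(atoms, data.frame(element = "H", x = hp[1], y = hp[2],
                                         z = hp[3], charge = NA_real_))
        bonds <- rbind(bonds, data.frame(a1 = a, a2 = nrow(atoms), order = 1L))
      }
    }
  }
  list(atoms = atoms, bonds = bonds)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# six-membered ring scaffold with optional ring nitrogens and substituents.
# subs: character vector length 6 from "H","OH","NH2","CH3","F","CHO";
# positions holding a ring N ignore their substituent (pyridine-type N).
.build_ring_molecule <- function(id, n_nitrogen = 0L,
                                 subs = rep("H", 6), kekulize = TRUE) {
  r <- 1.40 / (2 * sin(pi / 6))
  ang <- 2 * pi * (0:5) / 6
  el <- rep("C", 6)
  if (n_nitrogen > 0) el[seq(1, by = 2, length.out = min(n_nitrogen, 3))] <- "N"
  atoms <- data.frame(element = el, x = r * cos(ang), y = r * sin(ang),
                      z = 0, charge = NA_real_)
  ords <- if (kekulize) rep(c(2L, 1L), 3) else rep(1L, 6)
  bonds <- data.frame(a1 = 1:6, a2 = c(2:6, 1), order = ords)
  for (i in 1:6) {
    if (el[i] == "N" || subs[i] == "H") next
    dirv <- .uv(c(cos(ang[i]), sin(ang[i]), 0))
    pos <- c(atoms$x[i], atoms$y[i], 0)
    add_atom <- function(e, p) {
      atoms <<- rbind(atoms, data.frame(element = e, x = p[1], y = p[2],
                                        z = p[3], charge = NA_real_))
      nrow(atoms)
    }
    if (subs[i] == "OH") {
      o <- add_atom("O", pos + 1.36 * dirv)
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = o, order = 1L))
    } else if (subs[i] == "NH2") {
      nn <- add_atom("N", pos + 1.40 * dirv)
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = nn, order = 1L))
    } else if (subs[i] == "CH3") {
      cc <- add_atom("C", pos + 1.50 * dirv)
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = cc, order = 1L))
    } else if (subs[i] == "F") {
      f <- add_atom("F", pos + 1.35 * dirv)
      bonds <- rbind(bonds, data.frame(a1 = i, a2 = f, order = 1L))
    } else if (subs[i] == "CHO") {
      cc <- add_atom("C", pos + 1.50 * dirv)
      oo <- add_atom("O", pos + 1.50 * dirv + 1.22 * .uv(dirv + c(0, 0, 1)))
      bonds <- rbind(bonds,
                     data.frame(a1 = c(i, cc), a2 = c(cc, oo),
                                order = c(1L, 2L)))
    } else if (subs[i] == "CH2OH") {
      cc <- add_atom("C", pos + 1.50 * dirv)
      oo <- add_atom("O", pos + 1.50 * dirv + 1.43 * .uv(dirv + c(0, 0, 0.9)))
      bonds <- rbind(bonds,
                     data.frame(a1 = c(i, cc), a2 = c(cc, oo),
                                order = c(1L, 1L)))
    }
  }
  fb <- .fill_hydrogens(atoms, bonds)
  molecule(id, fb$atoms, fb$bonds)
}

# zig-zag heavy-atom chain; elements: character vector; carbonyl_at: index
# of a chain carbon given a double-bonded exocyclic O.
.build_chain_molecule <- function(id, elements, carbonyl_at = NULL) {
  n <- length(elements)
  x <- 1.26 * (seq_len(n) - 1)
  y <- 0.44 * rep_len(c(0, 1), n)
  atoms <- data.frame(element = elements, x = x, y = y, z = 0,
                      charge = NA_real_)
  bonds <- if (n > 1)
    data.frame(a1 = seq_len(n - 1), a2 = 2:n, order = 1L)
  else data.frame(a1 = integer(), a2 = integer(), order = integer())
  if (!is.null(carbonyl_at)) {
    for (ci in carbonyl_at) {
      stopifnot(elements[ci] == "C")
      atoms <- rbind(atoms, data.frame(element = "O", x = x[ci],
                                       y = y[ci] + 1.22, z = 0.1,
                                       charge = NA_real_))
      bonds <- rbind(bonds, data.frame(a1 = ci, a2 = nrow(atoms), order = 2L))
    }
  }
  fb <- .fill_hydrogens(atoms, bonds)
  molecule(id, fb$atoms, fb$bonds)
}

#' Generate synthetic small molecules
#'
#' Builds valence-legal 3D structures from ring and chain templates, with
#' heteroatom placements chosen so the generated set spans the atom
#' categories the descriptor family needs: ring nitrogens, hydrogen-bond
#' donors, sp2 oxygens and lipophilic hydrogens. Structures are idealized
#' (planar kekulized rings, zig-zag chains, template bond lengths) and
#' explicit hydrogens are added to fill every valence.
#'
#' @param n number of molecules.
#' @param scaffold `"mixed"` (default), `"ring"`, `"pyridine"` (every
#'   molecule gets exactly one ring nitrogen) or `"chain"`.
#' @param heteroatoms if FALSE, suppress N/O substituents (hydrocarbons
#'   only).
#' @param seed RNG seed.
#' @return list of [molecule()] objects with ids `syn_001`, `syn_002`, ...
#' @export
make_molecules <- function(n, scaffold = c("mixed", "ring", "pyridine",
                                           "chain"),
                           heteroatoms = TRUE, seed = NULL) {
  scaffold <- match.arg(scaffold)
  stopifnot(n >= 1)
  if (!is.null(seed)) { old <- .save_rng(); on.exit(.restore_rng(old)); set.seed(seed) }
  sub_pool <- if (heteroatoms) c("H", "OH", "NH2", "CH3", "F", "CHO", "CH2OH")
              else c("H", "CH3")
  chain_pool <- if (heteroatoms) c("C", "C", "C", "O", "N") else "C"
  out <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("syn_%03d", i)
    kind <- switch(scaffold, mixed = sample(c("ring", "pyridine", "chain"), 1),
                   scaffold)
    out[[i]] <- if (kind == "chain") {
      len <- sample(3:12, 1)
      els <- c("C", sample(chain_pool, len - 1, replace = TRUE))
      # avoid adjacent heteroatoms (keeps valence chemistry simple)
      for (j in 2:len)
        if (els[j] != "C" && els[j - 1] != "C") els[j] <- "C"
      carbo <- if (heteroatoms && stats::runif(1) < 0.5) {
        cand <- which(els == "C")
        cand <- cand[vapply(cand, function(ci) {
          nb <- c(ci - 1, ci + 1); nb <- nb[nb >= 1 & nb <= len]
          all(els[nb] == "C")
        }, logical(1))]
        if (length(cand)) cand[sample.int(length(cand), 1)] else NULL
      } else NULL
      .build_chain_molecule(id, els, carbo)
    } else {
      nN <- switch(kind, ring = 0L, pyridine = 1L)
      subs <- sample(sub_pool, 6, replace = TRUE,
                     prob = c(0.45, rep(0.55 / (length(sub_pool) - 1),
                                        length(sub_pool) - 1)))
      .build_ring_molecule(id, n_nitrogen = nN, subs = subs)
    }
  }
  out
}

#' A designed high-activity screening ligand (synthetic)
#'
#' A fully synthetic branched aliphatic
#' (2,2,4,4,6,6,8,8-octamethylnonane) designed by inverting the published
#' equation: the gem-dimethyl quaternary carbons give a compact surface
#' (high molecular-to-accessible surface ratio) and crowd many lipophilic
#' hydrogens around the centre of mass, while contributing no ring-carbon
#' pair counts, so the published equation predicts pIC50 well above the
#' conventional hit threshold of 8. The frozen 3D structure ships with the
#' package; it stands in for a library hit, not for any real inhibitor.
#' Used by [make_library()] to plant a known hit.
#'
#' @param id compound id.
#' @return a [molecule()].
#' @export
planted_hit_molecule <- function(id = "planted_hit") {
  path <- system.file("extdata", "planted_hit_synthetic.sdf",
                      package = "qsarmlr", mustWork = TRUE)
  mol <- read_structures(path, format = "sdf")[[1]]
  mol$id <- id
  mol
}

#' Write a synthetic screening library
#'
#' Generates `n` synthetic molecules (plus, optionally, the designed
#' [planted_hit_molecule()]) and writes them as an SDF library with
#' deterministic ids. Byte-identical output for identical seeds.
#'
#' @param n number of random library entries (>= 1).
#' @param path output SDF path.
#' @param seed RNG seed.
#' @param planted_hit include the designed high-activity ligand (default
#'   TRUE).
#' @return `path`, invisibly; ids in attribute `"ids"`.
#' @export
make_library <- function(n, path, seed = NULL, planted_hit = TRUE) {
  stopifnot(n >= 1)
  mols <- make_molecules(n, scaffold = "mixed", seed = seed)
  for (i in seq_along(mols)) mols[[i]]$id <- sprintf("LIB%06d", i)
  if (planted_hit) mols <- c(mols, list(planted_hit_molecule("LIB_PLANTED")))
  write_sdf(mols, path)
  ids <- vapply(mols, function(m) m$id, "")
  invisible(structure(path, ids = ids))
}
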