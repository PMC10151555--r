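# The six model descriptors and their generalized families.
#
# Counting convention ("frequency of occurrence"): the number of unordered
# atom pairs (a, b), a != b, with a in the source category, b in the target
# category and shortest-path distance exactly k bonds; each pair is counted
# once even when both orientations qualify. A per-target-atom alternative is
# available via counting_mode = "target_atoms".

#' Surface-area ratio descriptor
#'
#' Ratio of the molecular (van der Waals) surface area to the
#' solvent-accessible surface area. Dimensionless, typically in (0, 1) for
#' the conventional 1.4-Angstrom probe.
#'
#' @param msa molecular surface area (Angstrom^2, >= 0).
#' @param sasa solvent-accessible surface area (Angstrom^2, > 0).
#' @return `msa / sasa`.
#' @examples
#' rsa(460.1, 677.8)  # 0.6788...
#' @export
rsa <- function(msa, sasa) {
  if (any(sasa <= 0)) stop("sasa must be positive")
  if (any(msa < 0)) stop("msa must be non-negative")
  msa / sasa
}

#' Lipophilic hydrogens near the centre of mass
#'
#' Counts hydrogen atoms with |partial charge| <= `lipo_charge` (default
#' 0.200, inclusive) lying within `radius` (default 3 Angstrom) of the
#' molecule's centre of mass. Rigid-body invariant: the centre of mass moves
#' with the molecule.
#'
#' @param mol a [molecule()] with charges assigned.
#' @param radius shell radius in Angstrom.
#' @param lipo_charge absolute partial-charge bound (e-units).
#' @return integer count.
#' @export
com_lipohyd_3A <- function(mol, radius = 3.0, lipo_charge = 0.200) {
  cats <- atom_categories(mol, lipo_charge = lipo_charge)
  if (any(atom_elements(mol) == "H") && all(is.na(mol$atoms$charge)))
    stop("partial charges not assigned; run assign_partial_charges() first")
  com <- center_of_mass(mol)
  d <- sqrt(colSums((t(atom_coords(mol)) - com)^2))
  sum(cats$is_lipophilic_hydrogen & d <= radius)
}

#' Count atom pairs at an exact bond distance
#'
#' Number of unordered atom pairs (a, b) with a in `source`, b in `target`
#' and shortest-path distance exactly `k` bonds. With
#' `counting_mode = "target_atoms"` it instead counts target atoms having at
#' least one source atom at distance `k`.
#'
#' @param mol a [molecule()].
#' @param source,target logical atom masks or a category name among
#'   `"hydrogen"`, `"carbon"`, `"ring"`, `"ring_carbon"`, `"ring_nitrogen"`,
#'   `"donor"`, `"sp2_oxygen"`, `"lipophilic_hydrogen"`, `"any"`.
#' @param k exact topological distance in bonds (> 0).
#' @param counting_mode `"pairs"` (default) or `"target_atoms"`.
#' @param D optional precomputed [bond_distance_matrix()].
#' @return integer count.
#' @export
pair_count_at_distance <- function(mol, source, target, k,
                                   counting_mode = c("pairs", "target_atoms"),
                                   D = NULL) {
  counting_mode <- match.arg(counting_mode)
  if (k <= 0) stop("k must be positive")
  S <- .category_mask(mol, source)
  Tg <- .category_mask(mol, target)
  if (is.null(D)) D <- bond_distance_matrix(mol)
  at_k <- is.finite(D) & D == k
  if (counting_mode == "target_atoms")
    return(sum(vapply(which(Tg), function(b) any(S & at_k[, b]), logical(1))))
  n <- n_atoms(mol)
  cnt <- 0L
  if (n > 1L) for (a in seq_len(n - 1L)) for (b in (a + 1L):n)
    if (at_k[a, b] && ((S[a] && Tg[b]) || (S[b] && Tg[a]))) cnt <- cnt + 1L
  cnt
}

.category_mask <- function(mol, x) {
  if (is.logical(x)) {
    stopifnot(length(x) == n_atoms(mol))
    return(x)
  }
  cats <- atom_categories(mol)
  switch(x,
    hydrogen = cats$is_hydrogen,
    carbon = cats$is_carbon,
    ring = cats$is_ring,
    ring_carbon = cats$is_ring_carbon,
    ring_nitrogen = cats$is_ring_nitrogen,
    donor = cats$is_donor,
    sp2_oxygen = cats$is_sp2_oxygen,
    lipophilic_hydrogen = cats$is_lipophilic_hydrogen,
    any = rep(TRUE, n_atoms(mol)),
    stop("unknown atom category: ", x))
}

#' @rdname model_descriptors
#' @export
fringNdon3B <- function(mol, D = NULL)
  pair_count_at_distance(mol, "ring_nitrogen", "donor", 3L, D = D)

#' @rdname model_descriptors
#' @param apply_exclusion drop carbons that also lie at exactly 9 bonds from
#'   some other oxygen atom (the descriptor's exclusion clause); default TRUE.
#' @export
fsp2OC9B <- function(mol, D = NULL, apply_exclusion = TRUE) {
  if (is.null(D)) D <- bond_distance_matrix(mol)
  cats <- atom_categories(mol)
  oxy <- which(atom_elements(mol) == "O")
  sp2o <- which(cats$is_sp2_oxygen)
  carb <- which(cats$is_carbon)
  cnt <- 0L
  for (o in sp2o) for (c in carb) {
    if (!(is.finite(D[o, c]) && D[o, c] == 9)) next
    if (apply_exclusion) {
      others <- setdiff(oxy, o)
      if (length(others) && any(is.finite(D[c, others]) & D[c, others] == 9))
        next
    }
    cnt <- cnt + 1L
  }
  cnt
}

#' @rdname model_descriptors
#' @export
fHringC2B <- function(mol, D = NULL)
  pair_count_at_distance(mol, "hydrogen", "ring_carbon", 2L, D = D)

#' Named topological pair-count descriptors
#'
#' The four bond-distance pair-count descriptors of the arginase-I model:
#' `fringNdon3B` (ring nitrogen / hydrogen-bond donor pairs at 3 bonds),
#' `fsp2OC9B` (sp2 oxygen / carbon pairs at 9 bonds, with an exclusion for
#' carbons equidistant from another oxygen), `fHringC2B` (hydrogen /
#' ring-carbon pairs at 2 bonds) and `fringCC3B` (ring-carbon / carbon pairs
#' at 3 bonds). All are unordered pair counts on the explicit-hydrogen bond
#' graph.
#'
#' @param mol a [molecule()].
#' @param D optional precomputed [bond_distance_matrix()].
#' @return integer count.
#' @name model_descriptors
#' @export
fringCC3B <- function(mol, D = NULL)
  pair_count_at_distance(mol, "ring_carbon", "carbon", 3L, D = D)

.MODEL_DESCRIPTORS <- c("rsa", "com_lipohyd_3A", "fringNdon3B",
                        "fsp2OC9B", "fHringC2B", "fringCC3B")

#' Compute a descriptor matrix for a set of molecules
#'
#' Computes, per molecule, either the six model descriptors
#' (`pool = "model6"`) or an extended pool adding same-family descriptors:
#' pair counts over category combinations and bond distances 1-10, and
#' centre-of-mass shell counts at 2-5 Angstrom (`pool = "extended"`).
#' Molecules are salt-stripped to their largest fragment and get Gasteiger
#' charges if missing. Per-molecule failures are dropped with a warning; the
#' failed ids are in the `"failed"` attribute.
#'
#' @param mols list of [molecule()] objects.
#' @param pool `"model6"` or `"extended"`.
#' @param params a [surface_params()].
#' @return data.frame of descriptors, one row per molecule, row names the
#'   compound ids; attribute `"activity"` carries pIC50 values when present.
#' @export
compute_descriptors <- function(mols, pool = c("model6", "extended"),
                                params = surface_params()) {
  pool <- match.arg(pool)
  if (inherits(mols, "molecule")) mols <- list(mols)
  rows <- list(); ids <- character(); act <- numeric(); failed <- character()
  for (mol in mols) {
    row <- tryCatch(.descriptor_row(mol, pool, params),
                    error = function(e) {
                      failed <<- c(failed,
                                   sprintf("%s: %s", mol$id, conditionMessage(e)))
                      NULL
                    })
    if (is.null(row)) next
    rows[[length(rows) + 1L]] <- row
    ids <- c(ids, mol$id)
    act <- c(act, if (is.null(mol$pic50)) NA_real_ else mol$pic50)
  }
  if (length(failed))
    warning(length(failed), " molecule(s) failed descriptor computation:\n  ",
            paste(failed, collapse = "\n  "))
  if (!length(rows)) stop("descriptor computation failed for every molecule")
  X <- as.data.frame(do.call(rbind, rows))
  rownames(X) <- make.unique(ids)
  attr(X, "activity") <- act
  attr(X, "failed") <- failed
  X
}

.descriptor_row <- function(mol, pool, params) {
  mol <- largest_fragment(mol)
  if (all(is.na(mol$atoms$charge))) mol <- assign_partial_charges(mol)
  D <- bond_distance_matrix(mol)
  sa <- surface_areas(mol, params)
  base <- c(rsa = unname(rsa(sa["msa"], sa["sasa"])),
            com_lipohyd_3A = com_lipohyd_3A(mol),
            fringNdon3B = fringNdon3B(mol, D),
            fsp2OC9B = fsp2OC9B(mol, D),
            fHringC2B = fHringC2B(mol, D),
            fringCC3B = fringCC3B(mol, D))
  if (pool == "model6") return(base)
  combos <- list(c("hydrogen", "carbon"), c("hydrogen", "ring"),
                 c("donor", "carbon"), c("donor", "donor"),
                 c("ring_nitrogen", "carbon"), c("sp2_oxygen", "carbon"),
                 c("ring_carbon", "carbon"), c("ring", "ring"))
  extra <- numeric(); nms <- character()
  for (cm in combos) for (k in c(1L, 2L, 3L, 4L, 6L, 9L)) {
    extra <- c(extra, pair_count_at_distance(mol, cm[1], cm[2], k, D = D))
    nms <- c(nms, sprintf("f_%s_%s_%dB", cm[1], cm[2], k))
  }
  for (r in c(2, 4, 5)) {
    extra <- c(extra, com_lipohyd_3A(mol, radius = r))
    nms <- c(nms, sprintf("com_lipohyd_%gA", r))
  }
  names(extra) <- nms
  c(base, extra)
}

#' Objective feature selection (activity-blind pruning)
#'
#' Removes constant columns, near-constant columns (more than
#' `near_constant_frac` of the values identical) and, from every remaining
#' pair with |Pearson r| > `corr_cutoff`, one column. Of a correlated pair,
#' the column with the larger |correlation to activity| is kept when an
#' activity vector is available, otherwise the earlier column. Idempotent.
#'
#' @param x descriptor data.frame or matrix (compounds x descriptors).
#' @param corr_cutoff pairwise absolute-correlation threshold (default 0.90).
#' @param near_constant_frac fraction of identical values above which a
#'   column counts as near-constant (default 0.95).
#' @param activity optional numeric response used for tie-breaking; defaults
#'   to the matrix's `"activity"` attribute.
#' @return the pruned data.frame; dropped column names in attribute
#'   `"dropped"`.
#' @export
ofs_prune <- function(x, corr_cutoff = 0.90, near_constant_frac = 0.95,
                      activity = attr(x, "activity")) {
  X <- as.data.frame(x)
  if (nrow(X) < 2L) stop("need at least two compounds")
  dropped <- character()
  modal_frac <- vapply(X, function(col)
    max(table(col)) / length(col), numeric(1))
  const <- modal_frac > near_constant_frac |
    vapply(X, function(col) length(unique(col)) == 1L, logical(1))
  dropped <- names(X)[const]
  X <- X[, !const, drop = FALSE]
  if (!ncol(X)) stop("all columns pruned as (near-)constant")
  usable_y <- !is.null(activity) && sum(!is.na(activity)) >= 3L
  ycor <- if (usable_y)
    abs(vapply(X, function(col)
      suppressWarnings(stats::cor(col, activity, use = "complete.obs")),
      numeric(1)))
  else rep(NA_real_, ncol(X))
  keep <- rep(TRUE, ncol(X))
  C <- abs(suppressWarnings(stats::cor(X)))
  p <- ncol(X)
  for (i in seq_len(p - 1L)) {
    if (!keep[i]) next
    for (j in (i + 1L):p) {
      if (!keep[j] || is.na(C[i, j]) || C[i, j] <= corr_cutoff) next
      drop_j <- TRUE
      if (usable_y && !is.na(ycor[i]) && !is.na(ycor[j]) && ycor[j] > ycor[i])
        drop_j <- FALSE
      if (drop_j) keep[j] <- FALSE else { keep[i] <- FALSE; break }
    }
  }
  dropped <- c(dropped, names(X)[!keep])
  out <- X[, keep, drop = FALSE]
  if (!ncol(out)) stop("all columns pruned")
  attr(out, "activity") <- activity
  attr(out, "dropped") <- dropped
  out
}

#' Pearson correlation matrix of descriptors
#'
#' @param x descriptor data.frame or matrix (>= 3 rows).
#' @param names optional subset of column names.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
descriptor_correlation <- function(x, names = NULL) {
  X <- as.data.frame(x)
  if (!is.null(names)) {
    missing <- setdiff(names, colnames(X))
    if (length(missing)) stop("unknown descriptor(s): ",
                              paste(missing, collapse = ", "))
    X <- X[, names, drop = FALSE]
  }
  if (nrow(X) < 3L) stop("need at least three compounds")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  stats::cor(as.matrix(X))
}
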