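#' Surface-area sampling parameters
#'
#' Controls the Shrake-Rupley numerical surface integration: the solvent
#' probe radius (1.4 Angstrom, the conventional water probe), the van der
#' Waals radius table, and the number of test points per atomic sphere.
#'
#' @param probe_radius probe radius in Angstrom (>= 0).
#' @param vdw_radius_set named numeric vector of van der Waals radii per
#'   element symbol (Angstrom); defaults to Bondi-style radii.
#' @param sample_points_per_atom number of quasi-uniform sphere points
#'   (>= 92; default 960).
#' @return an object of class `"surface_params"`.
#' @export
surface_params <- function(probe_radius = 1.4,
                           vdw_radius_set = NULL,
                           sample_points_per_atom = 960L) {
  if (probe_radius < 0) stop("probe_radius must be >= 0")
  if (sample_points_per_atom < 92L) stop("sample_points_per_atom must be >= 92")
  if (is.null(vdw_radius_set)) vdw_radius_set <- .VDW_RADII
  structure(list(probe_radius = probe_radius,
                 vdw_radius_set = vdw_radius_set,
                 sample_points_per_atom = as.integer(sample_points_per_atom)),
            class = "surface_params")
}

# deterministic quasi-uniform unit-sphere points (Fibonacci lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Molecular and solvent-accessible surface area
#'
#' Shrake-Rupley numerical integration: each atom's sphere of radius
#' (vdW + probe) is sampled with a deterministic Fibonacci lattice and a test
#' point counts as accessible when it lies outside every other atom's
#' inflated sphere. `sasa` uses the probe radius from `params` (default 1.4);
#' `msa` is the same integral at probe 0, i.e. the van der Waals surface.
#' Their ratio is the `rsa` descriptor.
#'
#' @param mol a [molecule()] with 3D coordinates.
#' @param params a [surface_params()].
#' @return named numeric vector `c(msa = , sasa = )` in Angstrom^2.
#' @export
surface_areas <- function(mol, params = surface_params()) {
  radii <- params$vdw_radius_set[atom_elements(mol)]
  missing <- unique(atom_elements(mol)[is.na(radii)])
  if (length(missing))
    stop("no van der Waals radius for element(s): ",
         paste(missing, collapse = ", "))
  co <- atom_coords(mol)
  pts <- .sphere_points(params$sample_points_per_atom)
  c(msa  = .shrake_rupley(co, radii, 0, pts),
    sasa = .shrake_rupley(co, radii, params$probe_radius, pts))
}

.shrake_rupley <- function(co, radii, probe, pts) {
  n <- nrow(co)
  rr <- unname(radii) + probe
  total <- 0
  for (i in seq_len(n)) {
    # candidate occluders: spheres that can reach atom i's surface
    d2 <- colSums((t(co) - co[i, ])^2)
    nb <- which(d2 < (rr + rr[i])^2 & seq_len(n) != i)
    p <- pts * rr[i]
    p <- sweep(p, 2, co[i, ], `+`)
    acc <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[, 1] - co[j, 1])^2 + (p[, 2] - co[j, 2])^2 +
             (p[, 3] - co[j, 3])^2
      # inside (up to a relative eps band) occludes; a point exactly on the
      # other sphere (coincident atoms) is owned by the lower-indexed atom
      lim <- rr[j]^2 * (1 + 1e-9)
      on_boundary <- dj2 <= lim & dj2 >= rr[j]^2 * (1 - 1e-9)
      acc <- acc & (dj2 > lim | (on_boundary & j > i))
    }
    total <- total + 4 * pi * rr[i]^2 * mean(acc)
  }
  total
}
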