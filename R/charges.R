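#' Assign Gasteiger-Marsili partial charges
#'
#' Computes partial atomic charges by Gasteiger-Marsili iterative partial
#' equalization of orbital electronegativity (the OpenBabel implementation,
#' reached through ChemmineOB) and stores them in the molecule's atom table.
#' Charges are connectivity-based, so supplied coordinates are not altered.
#' The total charge of a neutral molecule sums to ~0 (within 1e-3).
#'
#' @param mol a [molecule()] with explicit hydrogens.
#' @param method charge model name passed to OpenBabel (default
#'   `"gasteiger"`).
#' @return the molecule with a filled `charge` column.
#' @export
assign_partial_charges <- function(mol, method = "gasteiger") {
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("ChemmineOB is required for partial-charge assignment")
  el <- atom_elements(mol)
  ok <- c("H", "C", "N", "O", "F", "S", "Cl", "Br", "I", "P", "B")
  bad <- setdiff(unique(el), ok)
  if (length(bad))
    stop("charge model not parameterized for element(s): ",
         paste(bad, collapse = ", "))
  sdf <- .molecule_sdf_string(mol)
  mol2 <- ChemmineOB::convertFormat("SDF", "MOL2", sdf)
  q <- .mol2_charges(mol2)
  if (length(q) != n_atoms(mol))
    stop("charge assignment returned ", length(q), " charges for ",
         n_atoms(mol), " atoms (", mol$id, ")")
  if (!all(is.finite(q))) stop("non-finite partial charges for ", mol$id)
  mol$atoms$charge <- q
  mol
}

# parse the per-atom charge column out of a TRIPOS MOL2 string
.mol2_charges <- function(mol2) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  a0 <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)[1]
  if (is.na(a0)) stop("malformed MOL2 output")
  a1 <- grep("@<TRIPOS>", lines, fixed = TRUE)
  a1 <- min(a1[a1 > a0], length(lines) + 1L)
  rows <- lines[(a0 + 1L):(a1 - 1L)]
  rows <- rows[nzchar(trimws(rows))]
  vapply(strsplit(trimws(rows), "[ \t]+"), function(f)
    as.numeric(f[[length(f)]]), numeric(1))
}
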