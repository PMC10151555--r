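# Structure input: SDF/MOL via ChemmineR, SMILES via the OpenBabel CLI
# (distance-geometry 3D embedding + MMFF94-style cleanup, explicit hydrogens).

# split an SD file into records at "$$$$" and parse each independently with
# ChemmineR, so one corrupt record cannot take down the whole file
.parse_sdf_lines <- function(lines, ids = NULL) {
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends)) ends <- length(lines)   # single MOL record
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  out <- list()
  errs <- character()
  for (i in seq_along(starts)) {
    rec <- lines[starts[i]:ends[i]]
    if (all(!nzchar(trimws(rec)))) next
    id <- if (!is.null(ids) && i <= length(ids)) ids[i] else paste0("mol_", i)
    mol <- tryCatch({
      rec <- rec[trimws(rec) != "$$$$"]
      sdfset <- suppressWarnings(ChemmineR::read.SDFset(c(rec, "$$$$")))
      sdf <- sdfset[[1]]
      ab <- ChemmineR::atomblock(sdf)
      bb <- ChemmineR::bondblock(sdf)
      if (!is.matrix(ab) || nrow(ab) < 1L) stop("empty atom block")
      el <- gsub("_.*$", "", rownames(ab))
      atoms <- data.frame(element = el,
                          x = ab[, 1], y = ab[, 2], z = ab[, 3])
      bonds <- if (is.null(bb) || !is.matrix(bb) || nrow(bb) == 0L) NULL else
        data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
      nm <- trimws(rec[1])
      if (nzchar(nm) && is.null(ids)) id <- nm
      molecule(id, atoms, bonds)
    }, error = function(e) {
      errs <<- c(errs, sprintf("%s: %s", id, conditionMessage(e)))
      NULL
    })
    if (!is.null(mol)) out[[length(out) + 1L]] <- mol
  }
  attr(out, "errors") <- errs
  out
}

.obabel <- function() {
  path <- Sys.which("obabel")
  if (!nzchar(path)) stop("the OpenBabel CLI (obabel) is required for SMILES input")
  path
}

.smiles_to_sdf_file <- function(smiles, ids) {
  smi <- tempfile(fileext = ".smi")
  on.exit(unlink(smi))
  writeLines(paste(smiles, ids, sep = "\t"), smi)
  out <- tempfile(fileext = ".sdf")
  res <- suppressWarnings(system2(.obabel(),
    c(shQuote(smi), "-osdf", "-O", shQuote(out), "--gen3d", "-h"),
    stdout = TRUE, stderr = TRUE))
  if (!file.exists(out) || file.size(out) == 0)
    stop("OpenBabel failed to embed SMILES input: ",
         paste(utils::tail(res, 2), collapse = " "))
  out
}

#' Read molecular structures
#'
#' Reads an SDF/MOL file (V2000, 3D coordinates used as supplied) or a SMILES
#' file (one molecule per line, optional tab-separated id), in which case 3D
#' coordinates and explicit hydrogens are generated with OpenBabel's standard
#' distance-geometry embedder. Unparsable records are skipped with a warning
#' naming the record; the per-record messages are returned in the `"errors"`
#' attribute. A file yielding no valid molecule is an error.
#'
#' @param path file path.
#' @param format `"sdf"`, `"mol"` or `"smiles"`; the default guesses from the
#'   file extension.
#' @return list of [molecule()] objects, with attribute `"errors"` (character
#'   vector of per-record failure messages).
#' @export
read_structures <- function(path, format = c("auto", "sdf", "mol", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "mol", smi = "smiles",
                     smiles = "smiles", txt = "smiles",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (format %in% c("sdf", "mol")) {
    lines <- readLines(path, warn = FALSE)
    mols <- .parse_sdf_lines(lines)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("no SMILES records in ", path)
    parts <- strsplit(lines, "[ \t]+")
    smiles <- vapply(parts, `[`, "", 1L)
    ids <- vapply(seq_along(parts), function(i)
      if (length(parts[[i]]) > 1L) parts[[i]][2L] else paste0("mol_", i), "")
    sdf <- .smiles_to_sdf_file(smiles, ids)
    on.exit(unlink(sdf))
    mols <- .parse_sdf_lines(readLines(sdf, warn = FALSE), ids = ids)
  }
  errs <- attr(mols, "errors")
  if (length(errs))
    warning(length(errs), " record(s) skipped:\n  ",
            paste(errs, collapse = "\n  "))
  if (!length(mols)) stop("no valid structure records in ", path)
  mols
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols a [molecule()] or list of molecules.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    na <- n_atoms(mol); nb <- nrow(mol$bonds)
    lines <- c(mol$id, "  qsarmlr", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
    co <- atom_coords(mol)
    for (i in seq_len(na))
      lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                                co[i, 1], co[i, 2], co[i, 3], mol$atoms$element[i]))
    for (j in seq_len(nb))
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                mol$bonds$a1[j], mol$bonds$a2[j], mol$bonds$order[j]))
    lines <- c(lines, "M  END")
    if (!is.null(mol$pic50))
      lines <- c(lines, "> <pIC50>", sprintf("%.6f", mol$pic50), "")
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

# molecule -> single-record SDF string (for charge assignment)
.molecule_sdf_string <- function(mol) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_sdf(mol, tmp)
  paste(readLines(tmp), collapse = "\n")
}
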