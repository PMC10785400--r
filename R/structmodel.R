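#' Molecular structures as atom tibbles
#'
#' A `vd_structure` is a tibble with one row per atom and columns
#' `serial`, `element`, `x`, `y`, `z` (Angstrom), `mass` (Da),
#' `is_hetero`, `residue_name`, `chain_id`, plus attributes `mol_name`,
#' `kind` (`"protein"` or `"ligand"`) and, when connectivity is known,
#' `bonds` (a tibble with columns `i`, `j`, `order`).
#'
#' @param atoms A data frame with at least `element`, `x`, `y`, `z`.
#'   Missing metadata columns are filled with defaults.
#' @param name Identifier string for the molecule.
#' @param kind `"protein"` or `"ligand"`.
#' @param bonds Optional bond tibble (`i`, `j`, `order`), 1-based atom
#'   indices into `atoms`.
#' @return A `vd_structure` tibble.
#' @export
as_structure <- function(atoms, name = "molecule",
                         kind = c("protein", "ligand"), bonds = NULL) {
  kind <- match.arg(kind)
  atoms <- tibble::as_tibble(atoms)
  if (nrow(atoms) < 1L) abort("a structure needs at least one atom")
  for (col in c("element", "x", "y", "z")) {
    if (!col %in% names(atoms)) abort(paste0("atoms is missing column '", col, "'"))
  }
  atoms$element <- normalize_element(atoms$element)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    abort("atom coordinates must be finite")
  }
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"is_hetero" %in% names(atoms)) atoms$is_hetero <- FALSE
  if (!"residue_name" %in% names(atoms)) atoms$residue_name <- "UNK"
  if (!"chain_id" %in% names(atoms)) atoms$chain_id <- "A"
  if (!"mass" %in% names(atoms)) atoms$mass <- element_mass(atoms$element)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    abort("atomic masses must be positive and finite")
  }
  atoms <- dplyr::select(
    atoms, "serial", "element", "x", "y", "z", "mass",
    "is_hetero", "residue_name", "chain_id",
    dplyr::any_of("residue_id")
  )
  out <- structure(atoms, class = c("vd_structure", class(tibble::tibble())))
  attr(out, "mol_name") <- name
  attr(out, "kind") <- kind
  if (!is.null(bonds)) {
    bonds <- tibble::as_tibble(bonds)
    stopifnot(all(c("i", "j") %in% names(bonds)))
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    attr(out, "bonds") <- bonds
  }
  out
}

#' @export
print.vd_structure <- function(x, ...) {
  cat(sprintf(
    "<vd_structure> %s (%s): %d atoms (%d heavy)%s\n",
    attr(x, "mol_name"), attr(x, "kind"), nrow(x),
    sum(x$element != "H"),
    if (is.null(attr(x, "bonds"))) "" else
      sprintf(", %d bonds", nrow(attr(x, "bonds")))
  ))
  NextMethod()
}

# canonical element symbol: first letter upper, rest lower ("CL" -> "Cl")
normalize_element <- function(el) {
  el <- trimws(as.character(el))
  paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, nchar(el))))
}

# standard atomic masses from bio3d's periodic table
periodic_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      e <- new.env()
      utils::data("elements", package = "bio3d", envir = e)
      tab <<- e$elements
    }
    tab
  }
})

element_mass <- function(el) {
  pt <- periodic_table()
  m <- pt$mass[match(el, as.character(pt$symb))]
  if (any(is.na(m))) {
    abort(paste0("unknown element symbol(s): ",
                 paste(unique(el[is.na(m)]), collapse = ", ")))
  }
  m
}

#' Heavy-atom subset of a structure
#'
#' @param s A `vd_structure`.
#' @return The structure restricted to non-hydrogen atoms (attributes,
#'   including bonds re-indexed to the subset, are preserved).
#' @export
heavy_atoms <- function(s) {
  keep <- which(!s$element %in% c("H", "D"))
  if (length(keep) == 0L) abort("structure has no heavy atoms")
  out <- s[keep, ]
  bonds <- attr(s, "bonds")
  if (!is.null(bonds)) {
    remap <- match(seq_len(nrow(s)), keep)
    bonds <- dplyr::filter(bonds, !is.na(remap[.data$i]), !is.na(remap[.data$j]))
    bonds$i <- remap[bonds$i]
    bonds$j <- remap[bonds$j]
    attr(out, "bonds") <- bonds
  }
  attr(out, "mol_name") <- attr(s, "mol_name")
  attr(out, "kind") <- attr(s, "kind")
  class(out) <- class(s)
  out
}

#' Read a molecular structure from PDB, SDF or MOL2
#'
#' Reads all ATOM/HETATM records (PDB) or the first molecule of an
#' SDF/MOL2 file. Hydrogens are retained; heavy-atom views are obtained
#' with [heavy_atoms()]. For NMR-style multi-MODEL PDB files only the
#' first model is read; alternate locations other than blank or 'A' are
#' dropped.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"pdb"`, `"sdf"` or `"mol2"`.
#' @param kind `"protein"` or `"ligand"`; defaults to protein for PDB
#'   and ligand for SDF/MOL2.
#' @return A `vd_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "sdf", "mol2"),
                           kind = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      pdb = "pdb", pdbqt = "pdb", ent = "pdb",
      sdf = "sdf", sd = "sdf", mol = "sdf",
      mol2 = "mol2",
      abort(paste0("cannot infer format from extension of ", path))
    )
  }
  switch(format,
    pdb  = read_structure_pdb(path, kind %||% "protein"),
    sdf  = read_structure_sdf(path, kind %||% "ligand"),
    mol2 = read_structure_mol2(path, kind %||% "ligand")
  )
}

read_structure_pdb <- function(path, kind) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) abort(paste0("failed to parse PDB '", path, "': ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0L) abort(paste0("no atoms in PDB file: ", path))
  elem <- at$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  if (any(blank)) elem[blank] <- element_from_atom_name(at$elety[blank])
  as_structure(
    tibble::tibble(
      serial = at$eleno, element = elem,
      x = at$x, y = at$y, z = at$z,
      is_hetero = at$type == "HETATM",
      residue_name = at$resid, chain_id = at$chain,
      residue_id = at$resno
    ),
    name = sub("\\.[^.]*$", "", basename(path)), kind = kind
  )
}

# PDB files without the element column: strip digits/primes from the atom name
element_from_atom_name <- function(name) {
  core <- gsub("[0-9'\"]", "", trimws(name))
  two <- c("Cl", "Br", "Fe", "Zn", "Mg", "Mn", "Na", "Ca", "Cu", "Se")
  first2 <- normalize_element(substr(core, 1, 2))
  ifelse(first2 %in% two, first2, substr(core, 1, 1))
}

read_structure_sdf <- function(path, kind) {
  set <- tryCatch(ChemmineR::read.SDFset(path),
    error = function(e) abort(paste0("failed to parse SDF '", path, "': ",
                                     conditionMessage(e))))
  if (length(set) == 0L) abort(paste0("no molecules in SDF file: ", path))
  sdf <- set[[1]]
  ab <- ChemmineR::atomblock(sdf)
  if (nrow(ab) == 0L) abort(paste0("empty atom block in ", path))
  elem <- sub("_.*$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  bonds <- if (!is.null(bb) && nrow(bb) > 0) {
    tibble::tibble(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  } else NULL
  as_structure(
    tibble::tibble(element = elem,
                   x = ab[, 1], y = ab[, 2], z = ab[, 3],
                   is_hetero = TRUE, residue_name = "LIG"),
    name = ChemmineR::sdfid(sdf) %||% basename(path), kind = kind,
    bonds = bonds
  )
}

read_structure_mol2 <- function(path, kind) {
  mol <- tryCatch(bio3d::read.mol2(path),
    error = function(e) abort(paste0("failed to parse MOL2 '", path, "': ",
                                     conditionMessage(e))))
  if (is.list(mol) && !is.null(mol$atom)) mol <- list(mol)
  m1 <- mol[[1]]
  at <- m1$atom
  if (is.null(at) || nrow(at) == 0L) abort(paste0("no atoms in MOL2 file: ", path))
  # SYBYL atom types ("C.3", "O.co2") carry the element before the dot;
  # fall back to the atom name with digits stripped
  elem <- sub("\\..*$", "", at$elety)
  bad <- !grepl("^[A-Za-z]", elem)
  elem[bad] <- gsub("[0-9'\"]", "", at$elena[bad])
  bonds <- if (!is.null(m1$bond) && nrow(m1$bond) > 0) {
    ord <- suppressWarnings(as.integer(m1$bond$type))
    tibble::tibble(i = as.integer(m1$bond$origin),
                   j = as.integer(m1$bond$target),
                   order = ifelse(is.na(ord), 1L, ord))
  } else NULL
  as_structure(
    tibble::tibble(element = elem, x = at$x, y = at$y, z = at$z,
                   is_hetero = TRUE, residue_name = "LIG"),
    name = basename(path), kind = kind, bonds = bonds
  )
}

#' Write a structure as a PDB file
#'
#' Coordinates are written at PDB precision (3 decimals); hetero atoms
#' become HETATM records.
#'
#' @param s A `vd_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(s, path) {
  resid <- if ("residue_id" %in% names(s)) s$residue_id else rep(1L, nrow(s))
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    ifelse(s$is_hetero, "HETATM", "ATOM"),
    s$serial %% 100000L,
    formatC(substr(paste0(s$element, seq_len(nrow(s))), 1, 4), width = 4),
    "", substr(s$residue_name, 1, 3), substr(s$chain_id, 1, 1),
    resid %% 10000L, "",
    s$x, s$y, s$z, 1, 0, toupper(s$element)
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Remove waters, ions, free atoms and bound ligands from a protein
#'
#' Drops water residues (HOH/WAT/H2O/DOD), monoatomic hetero groups
#' (free ions and free atoms) and any remaining hetero group with two or
#' more atoms (treated as a bound ligand). Standard polymer (ATOM
#' record) atoms are retained. No protonation is performed; downstream
#' docking inputs are expected to be pre-protonated.
#'
#' @param s A `vd_structure` with `kind = "protein"`.
#' @return The cleaned structure; the input is not modified.
#' @export
clean_target <- function(s) {
  if (attr(s, "kind") != "protein") abort("clean_target expects a protein structure")
  water <- c("HOH", "WAT", "H2O", "DOD")
  keep <- !s$is_hetero & !(s$residue_name %in% water)
  if (!any(keep)) abort("no polymer atoms remain after cleaning; structure is not a protein")
  out <- s[keep, ]
  attr(out, "mol_name") <- attr(s, "mol_name")
  attr(out, "kind") <- attr(s, "kind")
  class(out) <- class(s)
  out
}

#' Centroid of a set of atoms
#'
#' The mass centre used throughout the pipeline: a weighted mean of the
#' heavy-atom positions. Hydrogens are excluded because docking outputs
#' and the RMSD metrics are heavy-atom based; with
#' `weighting = "geometric"` all weights are 1.
#'
#' @param x A `vd_structure` or any data frame with `element`, `x`, `y`,
#'   `z` (and `mass` for mass weighting).
#' @param weighting `"mass"` (default) or `"geometric"`.
#' @return Named numeric vector `c(x, y, z)` in Angstrom.
#' @export
centroid <- function(x, weighting = c("mass", "geometric")) {
  weighting <- match.arg(weighting)
  if (nrow(x) == 0L) abort("cannot take the centroid of zero atoms")
  hv <- x[!x$element %in% c("H", "D"), , drop = FALSE]
  if (nrow(hv) == 0L) hv <- x  # all-hydrogen input: fall back to all atoms
  w <- if (weighting == "mass") {
    if (!"mass" %in% names(hv)) element_mass(hv$element) else hv$mass
  } else rep(1, nrow(hv))
  c(x = sum(hv$x * w), y = sum(hv$y * w), z = sum(hv$z * w)) / sum(w)
}
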