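#' Construct a protein structure from an atom table
#'
#' Low-level constructor used by [load_structure()] and the synthetic toy
#' structure generator. Atom records carry PDB-convention atom names so that
#' coordinator selection operates on the same vocabulary as real structures.
#'
#' @param atoms data.frame with columns `serial`, `atom_name`,
#'   `residue_name`, `chain_id`, `residue_seq`, `alt_loc`, `occupancy`,
#'   `x`, `y`, `z`, `element`, `is_hetero`.
#' @param identifier Character label for the structure.
#' @param resolution_note Optional free-text note.
#' @return Object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, identifier = "structure",
                              resolution_note = NULL) {
  required <- c("serial", "atom_name", "residue_name", "chain_id",
                "residue_seq", "alt_loc", "occupancy", "x", "y", "z",
                "element", "is_hetero")
  missing <- setdiff(required, names(atoms))
  if (length(missing))
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms retained")
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE))
    stop("occupancy outside [0, 1]")
  if (any(!nzchar(atoms$element)))
    stop("empty element field")
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom) after alt-loc resolution")
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, identifier = identifier,
                 resolution_note = resolution_note),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("Protein structure '%s': %d heavy atoms, %d chain(s)\n",
              x$identifier, nrow(x$atoms), length(unique(x$atoms$chain_id))))
  invisible(x)
}

infer_element <- function(atom_name, residue_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1, 2)
  known2 <- c("ZN", "CA", "MG", "NA", "CL", "FE", "MN", "CU", "NI", "CO",
              "CD", "BR", "SE", "K")
  # two-letter element names are only trusted for hetero/ion residues, since
  # e.g. protein "CA"/"CD1" are carbons
  if (residue_name %in% c(known2, "ZN2", "CA2", "MG2") && two %in% known2)
    return(two)
  substr(nm, 1, 1)
}

#' Read a protein structure from PDB or mmCIF
#'
#' Parses a structure file (via bio3d), drops hydrogens, resolves alternate
#' locations by keeping the highest-occupancy conformer (ties broken by the
#' alphabetically first alt-loc code), drops waters unless requested, and
#' retains hetero-atom metals flagged as such.
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file.
#' @param chain_filter Optional chain identifier(s) to keep.
#' @param include_waters Keep water oxygens (default `FALSE`).
#' @return A [protein_structure()].
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' gen_toy_structure(seed = 1, path = pdb)
#' load_structure(pdb)
load_structure <- function(path, chain_filter = NULL, include_waters = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  parsed <- tryCatch({
    # rm.alt = FALSE: alternate locations are resolved here by occupancy,
    # not by bio3d's keep-"A" rule
    if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, rm.alt = FALSE,
                                                    verbose = FALSE)
    else bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  }, error = function(e) stop("unparseable structure file '", path, "': ",
                              conditionMessage(e)))
  at <- parsed$atom
  el <- toupper(trimws(as.character(at$elesy)))
  need <- is.na(el) | !nzchar(el)
  if (any(need))
    el[need] <- mapply(infer_element, at$elety[need], at$resid[need])
  occ <- suppressWarnings(as.numeric(at$o))
  occ[is.na(occ)] <- 1
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    atom_name = toupper(trimws(at$elety)),
    residue_name = toupper(trimws(at$resid)),
    chain_id = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    residue_seq = as.integer(at$resno),
    alt_loc = ifelse(is.na(at$alt) | !nzchar(at$alt), "", at$alt),
    occupancy = pmin(pmax(occ, 0), 1),
    x = at$x, y = at$y, z = at$z,
    element = el,
    is_hetero = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  if (!include_waters)
    atoms <- atoms[!(atoms$residue_name %in% water_residues()), , drop = FALSE]
  if (!is.null(chain_filter))
    atoms <- atoms[atoms$chain_id %in% chain_filter, , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("empty structure: no atoms retained from '", path, "'")
  # alt-loc resolution: highest occupancy wins, ties -> first alt code
  ord <- order(atoms$chain_id, atoms$residue_seq, atoms$atom_name,
               -atoms$occupancy, atoms$alt_loc)
  atoms <- atoms[ord, , drop = FALSE]
  key <- paste(atoms$chain_id, atoms$residue_seq, atoms$atom_name)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  atoms <- atoms[order(match(atoms$serial, at$eleno)), , drop = FALSE]
  protein_structure(atoms, identifier = basename(path))
}

atom_xyz <- function(atoms) {
  cbind(atoms$x, atoms$y, atoms$z)
}
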