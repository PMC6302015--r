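#' Default van der Waals radii (Bondi set)
#'
#' Radii in Angstrom for the elements commonly found in protein crystal
#' structures, after Bondi's compilation. Used by [apply_vdw_exclusion()] to
#' carve out sterically forbidden cation positions. The table can be
#' overridden element-by-element through [geometry_params()].
#'
#' @return Named numeric vector of radii (Angstrom), names are element symbols.
#' @export
#' @examples
#' bondi_radii()[["O"]]
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
    ZN = 1.39, CA = 2.31, MG = 1.73, "NA" = 2.27, K = 2.75,
    MN = 2.05, FE = 2.04, CU = 1.40, NI = 1.63, CO = 2.00, CD = 1.58)
}

# Side-chain/backbone oxygen, nitrogen and sulfur atoms able to ligate a
# divalent cation: Cys SG; His ND1/NE2; Asp OD1/OD2; Glu OE1/OE2; Ser OG;
# Thr OG1; Tyr OH; and the backbone carbonyl oxygen "O".
coordinator_atom_names_default <- function() {
  c("SG", "ND1", "NE2", "OD1", "OD2", "OE1", "OE2", "OG", "OG1", "OH", "O")
}

standard_residues <- function() {
  c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
    "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
    "MSE", "SEC", "PYL")
}

water_residues <- function() c("HOH", "WAT", "DOD", "H2O")

#' Geometry parameters for the zinc-site grid search
#'
#' Bundles the tunable geometric criteria of the site-prediction pipeline.
#' Defaults reflect surveyed Zn2+ coordination geometry in protein crystal
#' structures: a cation-to-chelator cap of 3 Angstrom, seed cliques of at
#' least 3 mutually close (< 6 Angstrom) coordinator atoms, and a
#' 0.1-Angstrom placement grid.
#'
#' @param coordinator_atom_names Character vector of PDB atom names accepted
#'   as cation coordinators. `"O"` is interpreted as the backbone carbonyl
#'   oxygen of standard residues only.
#' @param d_max Maximal cation-to-chelator distance (Angstrom).
#' @param d_min Clash floor (Angstrom): a cation is never placed closer than
#'   this to a chelator. Default 1.7, just below the shortest Zn-O/Zn-S
#'   contacts observed crystallographically.
#' @param clique_pair_max Maximal pairwise distance (Angstrom) between
#'   coordinator atoms of one seed clique (edges require distance strictly
#'   less than this).
#' @param clique_min_size Minimal clique size (and minimal per-voxel
#'   coordinator count for a voxel to be retained).
#' @param grid_step Voxel edge length (Angstrom).
#' @param vdw_radii Named numeric vector of van der Waals radii (Angstrom)
#'   by element symbol; entries override [bondi_radii()].
#' @param max_voxels Voxel budget; grids larger than this raise an error
#'   suggesting a coarser `grid_step`.
#' @param angle_window Optional reserved hook (numeric length-2, degrees) for
#'   a chelator-cation-chelator angle filter; `NULL` (default) disables it.
#'
#' @return Object of class `geometry_params`.
#' @export
#' @examples
#' geometry_params(grid_step = 0.2)
geometry_params <- function(coordinator_atom_names = coordinator_atom_names_default(),
                            d_max = 3.0,
                            d_min = 1.7,
                            clique_pair_max = 6.0,
                            clique_min_size = 3L,
                            grid_step = 0.1,
                            vdw_radii = NULL,
                            max_voxels = 4e7,
                            angle_window = NULL) {
  radii <- bondi_radii()
  if (!is.null(vdw_radii)) {
    if (is.null(names(vdw_radii)) || any(!nzchar(names(vdw_radii))))
      stop("vdw_radii must be a named numeric vector (element symbols)")
    radii[toupper(names(vdw_radii))] <- vdw_radii
  }
  stopifnot(d_min > 0, d_min < d_max, d_max < clique_pair_max,
            clique_min_size >= 3, grid_step > 0, max_voxels > 0)
  structure(list(
    coordinator_atom_names = toupper(coordinator_atom_names),
    d_max = d_max, d_min = d_min,
    clique_pair_max = clique_pair_max,
    clique_min_size = as.integer(clique_min_size),
    grid_step = grid_step,
    vdw_radii = radii,
    max_voxels = max_voxels,
    angle_window = angle_window
  ), class = "geometry_params")
}

#' @export
print.geometry_params <- function(x, ...) {
  cat("Geometry parameters for metal-site search\n")
  cat(sprintf("  coordinators : %s\n", paste(x$coordinator_atom_names, collapse = " ")))
  cat(sprintf("  d range      : [%.2f, %.2f] A, clique < %.2f A (size >= %d)\n",
              x$d_min, x$d_max, x$clique_pair_max, x$clique_min_size))
  cat(sprintf("  grid step    : %.3f A (budget %g voxels)\n", x$grid_step, x$max_voxels))
  invisible(x)
}
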