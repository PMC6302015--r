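#' Select cation-coordinating atoms
#'
#' Returns the atoms of a structure whose names are in the configured
#' coordinator list. The bare name `"O"` matches only the backbone carbonyl
#' oxygen of standard amino-acid residues (never water or ligand oxygens),
#' so that side-chain chemistry is encoded entirely by the named side-chain
#' atoms. Order is file order.
#'
#' @param structure A [protein_structure()].
#' @param params A [geometry_params()].
#' @return data.frame of atom records (possibly 0 rows).
#' @export
select_coordinators <- function(structure, params = geometry_params()) {
  at <- structure$atoms
  keep <- at$atom_name %in% setdiff(params$coordinator_atom_names, "O")
  if ("O" %in% params$coordinator_atom_names)
    keep <- keep | (at$atom_name == "O" &
                    at$residue_name %in% standard_residues() &
                    !at$is_hetero)
  at[keep, , drop = FALSE]
}

#' Find cliques of mutually close coordinator atoms
#'
#' Builds the undirected graph whose vertices are coordinator atoms and whose
#' edges join pairs strictly closer than `clique_pair_max`, then enumerates
#' all maximal cliques of at least `clique_min_size` atoms. These cliques
#' seed the density grid: an isolated pair of oxygens cannot chelate a
#' divalent cation, but three or more mutually close coordinators can.
#'
#' @param coordinators data.frame of atom records (from
#'   [select_coordinators()]).
#' @param params A [geometry_params()].
#' @return List of `coordinator_clique` objects (each with `member_atoms`
#'   and `centroid`), sorted lexicographically by centroid. Empty list when
#'   no clique exists.
#' @export
find_cliques <- function(coordinators, params = geometry_params()) {
  n <- nrow(coordinators)
  if (is.null(n) || n < params$clique_min_size) return(list())
  xyz <- atom_xyz(coordinators)
  d <- as.matrix(stats::dist(xyz))
  adj <- d < params$clique_pair_max
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cl <- igraph::max_cliques(g, min = params$clique_min_size)
  cliques <- lapply(cl, function(v) {
    idx <- sort(as.integer(v))
    members <- coordinators[idx, , drop = FALSE]
    structure(list(member_atoms = members,
                   centroid = colMeans(atom_xyz(members))),
              class = "coordinator_clique")
  })
  if (length(cliques) == 0L) return(list())
  cent <- t(vapply(cliques, `[[`, numeric(3), "centroid"))
  cliques[order(cent[, 1], cent[, 2], cent[, 3])]
}

grid_axes <- function(grid) {
  lapply(1:3, function(k) grid$origin[k] + grid$step * (seq_len(grid$shape[k]) - 1))
}

#' Build the cation-placement density grid
#'
#' Lays a cubic voxel grid (edge `grid_step`) over the bounding box of all
#' clique-member atoms, padded by `d_max`, and counts at every voxel center
#' the number of clique-member coordinator atoms at a distance within
#' `[d_min, d_max]`. Counts below `clique_min_size` are zeroed: a voxel is a
#' feasible cation position only if enough chelators are simultaneously in
#' range. The count field is the "density" that is later clustered and
#' ranked.
#'
#' @param structure A [protein_structure()] (kept for provenance; counting
#'   uses the clique members).
#' @param cliques Non-empty list from [find_cliques()].
#' @param params A [geometry_params()].
#' @return Object of class `density_grid` with fields `origin`, `step`,
#'   `shape`, `counts` (integer array) and `excluded` (logical array, all
#'   `FALSE` until [apply_vdw_exclusion()]).
#' @export
build_density_grid <- function(structure, cliques, params = geometry_params()) {
  if (length(cliques) == 0L) stop("no cliques: nothing to grid")
  members <- unique(do.call(rbind, lapply(cliques, `[[`, "member_atoms")))
  xyz <- atom_xyz(members)
  step <- params$grid_step
  lo <- apply(xyz, 2, min) - params$d_max
  hi <- apply(xyz, 2, max) + params$d_max
  shape <- as.integer(floor((hi - lo) / step)) + 1L
  if (prod(as.numeric(shape)) > params$max_voxels)
    stop(sprintf(paste0("grid of %d x %d x %d voxels exceeds the budget of %g; ",
                        "use a coarser grid_step"),
                 shape[1], shape[2], shape[3], params$max_voxels))
  counts <- array(0L, dim = shape)
  ax <- lapply(1:3, function(k) lo[k] + step * (seq_len(shape[k]) - 1))
  r2min <- params$d_min^2
  r2max <- params$d_max^2
  for (a in seq_len(nrow(xyz))) {
    p <- xyz[a, ]
    rng <- lapply(1:3, function(k) {
      i <- which(abs(ax[[k]] - p[k]) <= params$d_max)
      if (length(i)) range(i) else c(1L, 0L)
    })
    if (any(vapply(rng, function(r) r[1] > r[2], logical(1)))) next
    ii <- rng[[1]][1]:rng[[1]][2]
    jj <- rng[[2]][1]:rng[[2]][2]
    kk <- rng[[3]][1]:rng[[3]][2]
    dx2 <- (ax[[1]][ii] - p[1])^2
    dy2 <- (ax[[2]][jj] - p[2])^2
    dz2 <- (ax[[3]][kk] - p[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    sel <- d2 >= r2min & d2 <= r2max
    counts[ii, jj, kk] <- counts[ii, jj, kk] + as.vector(sel)
  }
  counts[counts < params$clique_min_size] <- 0L
  structure(list(origin = lo, step = step, shape = shape,
                 counts = counts,
                 excluded = array(FALSE, dim = shape),
                 coordinators = members),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Density grid %d x %d x %d (step %.3f A), %d non-zero voxels\n",
              x$shape[1], x$shape[2], x$shape[3], x$step, sum(x$counts > 0)))
  invisible(x)
}

#' Remove sterically forbidden cation positions
#'
#' Marks as excluded every voxel whose center lies within the van der Waals
#' radius of any heavy atom of the structure, and zeroes the density counts
#' there. Elements absent from the radii table raise an error naming the
#' element.
#'
#' @param grid A [build_density_grid()] result.
#' @param structure The same [protein_structure()] the grid was built over.
#' @param params A [geometry_params()].
#' @return The grid with `excluded` set and `counts` zeroed at excluded
#'   voxels.
#' @export
apply_vdw_exclusion <- function(grid, structure, params = geometry_params()) {
  at <- structure$atoms
  radii <- params$vdw_radii[at$element]
  if (any(is.na(radii))) {
    bad <- unique(at$element[is.na(radii)])
    stop("no van der Waals radius configured for element(s): ",
         paste(bad, collapse = ", "))
  }
  ax <- grid_axes(grid)
  excl <- grid$excluded
  for (a in seq_len(nrow(at))) {
    r <- radii[a]
    p <- c(at$x[a], at$y[a], at$z[a])
    rng <- lapply(1:3, function(k) {
      i <- which(abs(ax[[k]] - p[k]) <= r)
      if (length(i)) range(i) else c(1L, 0L)
    })
    if (any(vapply(rng, function(q) q[1] > q[2], logical(1)))) next
    ii <- rng[[1]][1]:rng[[1]][2]
    jj <- rng[[2]][1]:rng[[2]][2]
    kk <- rng[[3]][1]:rng[[3]][2]
    dx2 <- (ax[[1]][ii] - p[1])^2
    dy2 <- (ax[[2]][jj] - p[2])^2
    dz2 <- (ax[[3]][kk] - p[3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    excl[ii, jj, kk] <- excl[ii, jj, kk] | as.vector(d2 <= r^2)
  }
  grid$excluded <- excl
  grid$counts[excl] <- 0L
  grid
}

# 26-neighbourhood connected components over the non-zero voxels of a grid.
# Returns a list of integer matrices of (i, j, k) voxel indices.
connected_components_26 <- function(counts) {
  shape <- dim(counts)
  nz <- which(counts > 0L)
  if (length(nz) == 0L) return(list())
  inset <- array(FALSE, dim = shape)
  inset[nz] <- TRUE
  labelled <- array(FALSE, dim = shape)
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  comps <- list()
  for (seed in nz) {
    if (labelled[seed]) next
    frontier <- seed
    labelled[seed] <- TRUE
    member <- seed
    while (length(frontier)) {
      ijk <- arrayInd(frontier, shape)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
        sweep(ijk, 2, offs[r, ], `+`)))
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
            nb[, 2] >= 1 & nb[, 2] <= shape[2] &
            nb[, 3] >= 1 & nb[, 3] <= shape[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * shape[1] +
             (nb[, 3] - 1L) * shape[1] * shape[2]
      lin <- unique(lin[inset[lin] & !labelled[lin]])
      labelled[lin] <- TRUE
      member <- c(member, lin)
      frontier <- lin
    }
    comps[[length(comps) + 1L]] <- arrayInd(member, shape)
  }
  comps
}

# Exact diameter for small point sets; for large sets the diameter is taken
# over directional extreme points (axes plus face/body diagonals), which is
# exact for convex blobs and a tight lower bound otherwise.
point_set_diameter <- function(pts) {
  n <- nrow(pts)
  if (n <= 1L) return(0)
  if (n <= 2000L) return(max(stats::dist(pts)))
  dirs <- rbind(diag(3),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  idx <- unique(unlist(lapply(seq_len(nrow(dirs)), function(r) {
    s <- pts %*% dirs[r, ]
    c(which.min(s), which.max(s))
  })))
  max(stats::dist(pts[idx, , drop = FALSE]))
}

#' Cluster and rank predicted sites
#'
#' Groups the non-zero voxels of an exclusion-filtered density grid into
#' 26-neighbourhood connected components. Each component becomes one
#' predicted site whose peak position is the centroid of its maximal-count
#' voxels (for symmetric chelation shells this estimates the geometric
#' cation position to well within one grid step), whose `peak_density` is the
#' maximal count, and whose `extent` is the maximal pairwise distance between
#' component voxel centers. Sites are ranked by decreasing peak density,
#' ties broken by larger voxel count, then by lexicographically smaller peak
#' coordinates.
#'
#' @param grid A grid after [apply_vdw_exclusion()].
#' @param structure Optional [protein_structure()]; when supplied,
#'   coordinator atoms within `[d_min, d_max]` of each peak are recorded as
#'   supporting atoms.
#' @param params A [geometry_params()].
#' @return Object of class `predicted_sites`: a data.frame with one row per
#'   site (`rank`, `peak_x/y/z`, `peak_density`, `extent`, `voxel_count`)
#'   and a `supporting_atoms` attribute (list of atom data.frames).
#' @export
rank_sites <- function(grid, structure = NULL, params = geometry_params()) {
  comps <- connected_components_26(grid$counts)
  empty <- data.frame(rank = integer(), peak_x = numeric(), peak_y = numeric(),
                      peak_z = numeric(), peak_density = integer(),
                      extent = numeric(), voxel_count = integer())
  if (length(comps) == 0L)
    return(structure(empty, class = c("predicted_sites", "data.frame"),
                     supporting_atoms = list()))
  ax <- grid_axes(grid)
  rows <- lapply(comps, function(ijk) {
    cts <- grid$counts[ijk]
    pts <- cbind(ax[[1]][ijk[, 1]], ax[[2]][ijk[, 2]], ax[[3]][ijk[, 3]])
    pk <- max(cts)
    peak <- colMeans(pts[cts == pk, , drop = FALSE])
    list(peak = peak, peak_density = pk,
         extent = point_set_diameter(pts), voxel_count = nrow(ijk))
  })
  df <- data.frame(
    peak_x = vapply(rows, function(r) r$peak[1], 0),
    peak_y = vapply(rows, function(r) r$peak[2], 0),
    peak_z = vapply(rows, function(r) r$peak[3], 0),
    peak_density = vapply(rows, function(r) as.integer(r$peak_density), 0L),
    extent = vapply(rows, function(r) r$extent, 0),
    voxel_count = vapply(rows, function(r) as.integer(r$voxel_count), 0L)
  )
  ord <- order(-df$peak_density, -df$voxel_count, df$peak_x, df$peak_y, df$peak_z)
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  supp <- vector("list", nrow(df))
  if (!is.null(structure)) {
    coord <- select_coordinators(structure, params)
    if (nrow(coord)) {
      cxyz <- atom_xyz(coord)
      for (s in seq_len(nrow(df))) {
        d <- sqrt(colSums((t(cxyz) - c(df$peak_x[s], df$peak_y[s], df$peak_z[s]))^2))
        supp[[s]] <- coord[d >= params$d_min & d <= params$d_max, , drop = FALSE]
      }
    }
  }
  structure(df, class = c("predicted_sites", "data.frame"),
            supporting_atoms = supp)
}

#' Static coordination shell around a point
#'
#' Counts the coordinator-eligible atoms (side-chain O/N/S, backbone carbonyl
#' oxygen, and water oxygens when waters are present in the structure) within
#' a cutoff of a given center. A static analogue of coordination-number
#' analysis of simulated metal sites.
#'
#' @param structure A [protein_structure()].
#' @param center Numeric length-3 position (Angstrom).
#' @param cutoff Positive radius (Angstrom).
#' @param params A [geometry_params()].
#' @return Object of class `coordination_shell` with `center`, `cutoff`,
#'   `chelator_atoms` and `n_coordinators`.
#' @export
coordination_shell <- function(structure, center, cutoff,
                               params = geometry_params()) {
  stopifnot(length(center) == 3, cutoff > 0)
  at <- structure$atoms
  eligible <- at$atom_name %in% setdiff(params$coordinator_atom_names, "O")
  eligible <- eligible | (at$atom_name == "O" &
                          at$residue_name %in% standard_residues() &
                          !at$is_hetero)
  eligible <- eligible | (at$residue_name %in% water_residues() &
                          at$element == "O")
  cand <- at[eligible, , drop = FALSE]
  if (nrow(cand)) {
    d <- sqrt(colSums((t(atom_xyz(cand)) - center)^2))
    cand <- cand[d <= cutoff, , drop = FALSE]
  }
  structure(list(center = center, cutoff = cutoff,
                 chelator_atoms = cand,
                 n_coordinators = nrow(cand)),
            class = "coordination_shell")
}

#' Predict metal-binding sites in a structure
#'
#' Full geometric pipeline: coordinator selection, clique detection, density
#' grid construction, van der Waals exclusion, and connected-component site
#' ranking. Deterministic for fixed inputs.
#'
#' @inheritParams select_coordinators
#' @return A `predicted_sites` data.frame (see [rank_sites()]); zero rows
#'   when no site is geometrically feasible.
#' @export
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' gen_toy_structure(seed = 7, path = pdb)
#' predict_metal_sites(load_structure(pdb), geometry_params(grid_step = 0.2))
predict_metal_sites <- function(structure, params = geometry_params()) {
  coord <- select_coordinators(structure, params)
  cliques <- find_cliques(coord, params)
  if (length(cliques) == 0L)
    return(rank_sites(structure(list(origin = c(0, 0, 0), step = params$grid_step,
                                     shape = c(1L, 1L, 1L),
                                     counts = array(0L, dim = c(1, 1, 1)),
                                     excluded = array(FALSE, dim = c(1, 1, 1))),
                                class = "density_grid"),
                      structure, params))
  grid <- build_density_grid(structure, cliques, params)
  grid <- apply_vdw_exclusion(grid, structure, params)
  rank_sites(grid, structure, params)
}

#' Write predicted sites to JSON
#'
#' @param sites A `predicted_sites` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sites_json <- function(sites, path) {
  supp <- attr(sites, "supporting_atoms")
  lst <- lapply(seq_len(nrow(sites)), function(i) {
    s <- as.list(sites[i, ])
    a <- supp[[i]]
    s$supporting_atoms <- if (is.null(a) || nrow(a) == 0) character(0) else
      paste0(a$chain_id, "/", a$residue_name, a$residue_seq, "/", a$atom_name)
    s
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a density grid as flat TSV
#'
#' One row per non-zero voxel: `x`, `y`, `z`, `count`.
#'
#' @param grid A `density_grid`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_density_tsv <- function(grid, path) {
  nz <- which(grid$counts > 0L)
  ijk <- arrayInd(nz, grid$shape)
  ax <- grid_axes(grid)
  df <- data.frame(x = ax[[1]][ijk[, 1]], y = ax[[2]][ijk[, 2]],
                   z = ax[[3]][ijk[, 3]], count = grid$counts[nz])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
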