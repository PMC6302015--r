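# Independent oracles used to cross-check the package's computations.
# These deliberately re-derive quantities by the most transparent route
# available (bisection, exhaustive enumeration, closed forms) and share no
# code with the implementation they check.

# Closed-form cumulative heat for n identical independent sites (the
# classic single-site ITC isotherm expression), kcal.
wiseman_cumulative_heat <- function(n, k, dh, m_t, x_t, v0) {
  a <- 1 + x_t / (n * m_t) + 1 / (n * k * m_t)
  (n * m_t * dh * v0 / 2) * (a - sqrt(a^2 - 4 * x_t / (n * m_t)))
}

# Plain bisection solve of L = x + P * B(x) on [0, L].
bisect_free_ligand <- function(total_ligand, total_protein, bfun,
                               iters = 200) {
  lo <- 0
  hi <- total_ligand
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (mid + total_protein * bfun(mid) > total_ligand) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Exhaustive maximal-clique enumeration for small point sets (n <= 12):
# every subset of size >= min_size whose pairs are all closer than cutoff,
# kept only if no strict superset also qualifies.
brute_max_cliques <- function(xyz, cutoff, min_size = 3) {
  n <- nrow(xyz)
  stopifnot(n <= 12)
  d <- as.matrix(dist(xyz))
  subsets <- list()
  for (m in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(m, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < min_size) next
    dd <- d[idx, idx, drop = FALSE]
    if (all(dd[upper.tri(dd)] < cutoff)) subsets[[length(subsets) + 1]] <- idx
  }
  is_max <- vapply(subsets, function(s) {
    !any(vapply(subsets, function(t)
      length(t) > length(s) && all(s %in% t), logical(1)))
  }, logical(1))
  subsets[is_max]
}

# Per-voxel coordinator count with the clique-size threshold applied.
brute_voxel_count <- function(point, coord_xyz, d_min, d_max, min_size) {
  d <- sqrt(colSums((t(coord_xyz) - point)^2))
  cnt <- sum(d >= d_min & d <= d_max)
  if (cnt >= min_size) cnt else 0L
}

# PDB ATOM line with explicit alt-loc support (fixed-column format).
pdb_atom_line <- function(serial, name, alt, resname, chain, resno, xyz,
                          occ = 1, element = substr(name, 1, 1),
                          record = "ATOM") {
  namef <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, namef, alt, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], occ, 0, element)
}

# Minimal atom table for direct protein_structure() construction.
make_atoms <- function(atom_name, residue_name, xyz,
                       residue_seq = seq_along(atom_name),
                       element = substr(atom_name, 1, 1),
                       is_hetero = FALSE) {
  data.frame(serial = seq_along(atom_name), atom_name = atom_name,
             residue_name = residue_name, chain_id = "A",
             residue_seq = residue_seq, alt_loc = "",
             occupancy = 1, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             element = element, is_hetero = is_hetero,
             stringsAsFactors = FALSE)
}

toy_structure_from_gen <- function(...) {
  pdb <- tempfile(fileext = ".pdb")
  toy <- gen_toy_structure(..., path = pdb)
  list(structure = load_structure(pdb), toy = toy, path = pdb)
}

site_peak <- function(sites, i = 1) {
  c(sites$peak_x[i], sites$peak_y[i], sites$peak_z[i])
}
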