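params_fast <- geometry_params(grid_step = 0.2)

test_that("coordinator selection follows the chelator-atom vocabulary", {
  xyz <- matrix(rnorm(9), ncol = 3)
  s <- protein_structure(make_atoms(c("CA", "OD1", "NZ"), "ASP", xyz,
                                    element = c("C", "O", "N")))
  sel <- select_coordinators(s)
  expect_equal(sel$atom_name, "OD1")

  # full Asp residue: backbone O plus both carboxylate oxygens qualify
  nm <- c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2")
  el <- c("N", "C", "C", "O", "C", "C", "O", "O")
  s2 <- protein_structure(make_atoms(nm, "ASP", matrix(seq_len(24), ncol = 3),
                                     residue_seq = rep(1, 8), element = el))
  ref <- names(which(sapply(nm, function(a)
    a %in% c("SG","ND1","NE2","OD1","OD2","OE1","OE2","OG","OG1","OH","O"))))
  expect_equal(select_coordinators(s2)$atom_name, ref)
  expect_equal(ref, c("O", "OD1", "OD2"))

  # Cys SG is a coordinator; hetero/water "O" is not
  s3 <- protein_structure(make_atoms(c("SG", "O"), c("CYS", "HOH"),
                                     matrix(1:6, ncol = 3),
                                     element = c("S", "O"),
                                     is_hetero = c(FALSE, TRUE)))
  expect_equal(select_coordinators(s3)$atom_name, "SG")
})

test_that("clique detection agrees with exhaustive enumeration", {
  # too few atoms / broken edge
  two <- protein_structure(make_atoms(c("OD1", "OD2"), "ASP",
                                      rbind(c(0, 0, 0), c(2, 0, 0)),
                                      residue_seq = c(1, 1), element = "O"))
  expect_length(find_cliques(select_coordinators(two)), 0)
  tri <- protein_structure(make_atoms(c("OD1", "OD2", "OE1"),
                                      c("ASP", "ASP", "GLU"),
                                      rbind(c(0, 0, 0), c(2, 0, 0), c(6.5, 0, 0)),
                                      element = "O"))
  expect_length(find_cliques(select_coordinators(tri)), 0)

  # regular tetrahedron with 2.5 A edges -> exactly one clique of size 4
  edge <- 2.5
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    edge / sqrt(8)
  s <- protein_structure(make_atoms(rep("OD1", 4), "ASP", tet, element = "O"))
  cl <- find_cliques(select_coordinators(s))
  expect_length(cl, 1)
  expect_equal(nrow(cl[[1]]$member_atoms), 4)

  # randomised cross-check against brute-force maximal cliques
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    xyz <- matrix(runif(3 * n, 0, 8), ncol = 3)
    s <- protein_structure(make_atoms(rep("OD1", n), "ASP", xyz, element = "O"))
    got <- find_cliques(select_coordinators(s))
    want <- brute_max_cliques(xyz, 6.0, 3)
    expect_length(got, length(want))
    got_sets <- lapply(got, function(cc) sort(cc$member_atoms$serial))
    want_sets <- lapply(want, sort)
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want_sets, paste, collapse = ","))
  }
})

test_that("adding atoms never removes an existing clique", {
  set.seed(21)
  xyz <- matrix(runif(15, 0, 6), ncol = 3)
  base <- protein_structure(make_atoms(rep("OD1", 5), "ASP", xyz, element = "O"))
  cl0 <- find_cliques(select_coordinators(base))
  xyz2 <- rbind(xyz, matrix(runif(6, 0, 6), ncol = 3))
  more <- protein_structure(make_atoms(rep("OD1", 7), "ASP", xyz2, element = "O"))
  cl1 <- find_cliques(select_coordinators(more))
  sets1 <- lapply(cl1, function(cc) cc$member_atoms$serial)
  for (cc in cl0) {
    s0 <- cc$member_atoms$serial
    expect_true(any(vapply(sets1, function(s1) all(s0 %in% s1), logical(1))))
  }
})

test_that("density counts match a brute-force per-atom distance count", {
  toy <- toy_structure_from_gen(geometry = "tetrahedral", shell_radius = 2.0,
                                decoys = 10, seed = 5)
  s <- toy$structure
  coord <- select_coordinators(s, params_fast)
  cl <- find_cliques(coord, params_fast)
  grid <- build_density_grid(s, cl, params_fast)
  cxyz <- cbind(coord$x, coord$y, coord$z)
  ax <- ionbind:::grid_axes(grid)
  set.seed(99)
  idx <- cbind(sample(grid$shape[1], 50, TRUE),
               sample(grid$shape[2], 50, TRUE),
               sample(grid$shape[3], 50, TRUE))
  for (r in seq_len(50)) {
    p <- c(ax[[1]][idx[r, 1]], ax[[2]][idx[r, 2]], ax[[3]][idx[r, 3]])
    expect_equal(grid$counts[idx[r, 1], idx[r, 2], idx[r, 3]],
                 brute_voxel_count(p, cxyz, params_fast$d_min,
                                   params_fast$d_max,
                                   params_fast$clique_min_size),
                 ignore_attr = TRUE)
  }
  # the voxel nearest the shell center sees all four chelators
  ctr_idx <- vapply(1:3, function(k) which.min(abs(ax[[k]] - 0)), 0L)
  expect_equal(grid$counts[ctr_idx[1], ctr_idx[2], ctr_idx[3]], 4L,
               ignore_attr = TRUE)
})

test_that("enlarging d_max never decreases a voxel count", {
  toy <- toy_structure_from_gen(geometry = "octahedral", shell_radius = 2.2,
                                decoys = 0, seed = 2)
  s <- toy$structure
  p1 <- geometry_params(grid_step = 0.25, d_max = 2.5)
  p2 <- geometry_params(grid_step = 0.25, d_max = 3.0)
  g1 <- build_density_grid(s, find_cliques(select_coordinators(s, p1), p1), p1)
  g2 <- build_density_grid(s, find_cliques(select_coordinators(s, p2), p2), p2)
  # same step; the wider-padded grid contains the narrow one at an offset
  off <- round((g1$origin - g2$origin) / p1$grid_step)
  sub <- g2$counts[off[1] + seq_len(g1$shape[1]),
                   off[2] + seq_len(g1$shape[2]),
                   off[3] + seq_len(g1$shape[3])]
  expect_true(all(sub >= g1$counts))
})

test_that("van der Waals exclusion is sound and local", {
  toy <- toy_structure_from_gen(geometry = "tetrahedral", shell_radius = 2.0,
                                decoys = 15, seed = 8)
  s <- toy$structure
  cl <- find_cliques(select_coordinators(s, params_fast), params_fast)
  g0 <- build_density_grid(s, cl, params_fast)
  g <- apply_vdw_exclusion(g0, s, params_fast)
  ax <- ionbind:::grid_axes(g)
  # a voxel at an atom position is excluded
  a1 <- c(s$atoms$x[1], s$atoms$y[1], s$atoms$z[1])
  i1 <- vapply(1:3, function(k) which.min(abs(ax[[k]] - a1[k])), 0L)
  expect_true(g$excluded[i1[1], i1[2], i1[3]])
  # center voxel survives: nearest chelator 2.0 A away, radius 1.52 A
  i0 <- vapply(1:3, function(k) which.min(abs(ax[[k]] - 0)), 0L)
  expect_false(g$excluded[i0[1], i0[2], i0[3]])
  expect_equal(g$counts[i0[1], i0[2], i0[3]], 4L, ignore_attr = TRUE)
  # soundness: no surviving voxel is inside any atom's VdW sphere
  nz <- which(g$counts > 0)
  ijk <- arrayInd(nz, g$shape)
  pts <- cbind(ax[[1]][ijk[, 1]], ax[[2]][ijk[, 2]], ax[[3]][ijk[, 3]])
  axyz <- cbind(s$atoms$x, s$atoms$y, s$atoms$z)
  radii <- bondi_radii()[s$atoms$element]
  for (a in seq_len(nrow(axyz))) {
    d <- sqrt(rowSums(sweep(pts, 2, axyz[a, ])^2))
    expect_true(all(d > radii[a]))
  }
  # unknown element -> configuration error naming it
  s2 <- s
  s2$atoms$element[1] <- "XX"
  expect_error(apply_vdw_exclusion(g0, s2, params_fast), "XX")
})

test_that("site ranking orders components by peak density then size", {
  counts <- array(0L, dim = c(30, 10, 10))
  counts[2:4, 2:4, 2:4] <- 3L; counts[3, 3, 3] <- 4L   # peak 4, 27 voxels
  counts[20:21, 2:3, 2:3] <- 3L                        # peak 3, 8 voxels
  g <- structure(list(origin = c(0, 0, 0), step = 0.5,
                      shape = c(30L, 10L, 10L), counts = counts,
                      excluded = array(FALSE, dim = c(30, 10, 10))),
                 class = "density_grid")
  sites <- rank_sites(g)
  expect_equal(sites$rank, c(1, 2))
  expect_equal(sites$peak_density, c(4L, 3L))
  expect_equal(sites$voxel_count, c(27L, 8L))
  expect_equal(site_peak(sites, 1), c(1, 1, 1) * 0.5 * 2)
  # extent equals the exact max pairwise distance of the first blob
  expect_equal(sites$extent[1], sqrt(3) * 2 * 0.5)
  # empty grid -> no sites
  g$counts[] <- 0L
  expect_equal(nrow(rank_sites(g)), 0)
})

test_that("coordination shells count chelator-eligible atoms within cutoff", {
  toy <- toy_structure_from_gen(geometry = "tetrahedral", shell_radius = 2.0,
                                decoys = 10, seed = 4)
  s <- toy$structure
  expect_equal(coordination_shell(s, c(0, 0, 0), 2.5)$n_coordinators, 4)
  expect_equal(coordination_shell(s, c(0, 0, 0), 1.0)$n_coordinators, 0)
  expect_equal(coordination_shell(s, c(500, 500, 500), 3)$n_coordinators, 0)

  # water oxygens count in shells (but never as site-search coordinators)
  sw <- s
  wat <- make_atoms("O", "HOH", matrix(c(0, 0, 2.2), ncol = 3),
                    residue_seq = 999L, element = "O", is_hetero = TRUE)
  sw$atoms <- rbind(sw$atoms, wat)
  expect_equal(coordination_shell(sw, c(0, 0, 0), 2.5)$n_coordinators, 5)
  expect_false("HOH" %in% select_coordinators(sw)$residue_name)
})

test_that("the full pipeline finds the planted site and nothing else", {
  toy <- toy_structure_from_gen(geometry = "tetrahedral", shell_radius = 2.0,
                                decoys = 25, seed = 13, center = c(4, -2, 7))
  sites <- predict_metal_sites(toy$structure, params_fast)
  expect_equal(nrow(sites), 1)
  expect_lt(sqrt(sum((site_peak(sites) - toy$toy$center)^2)), 0.2)
  supp <- attr(sites, "supporting_atoms")[[1]]
  expect_equal(nrow(supp), 4)

  # structure of only carbons: no coordinators, no sites
  cs <- protein_structure(make_atoms(rep("CB", 5), "ALA",
                                     matrix(rnorm(15, sd = 3), ncol = 3),
                                     element = "C"))
  expect_equal(nrow(predict_metal_sites(cs, params_fast)), 0)

  # coordinators all farther apart than the clique distance: no sites
  far <- protein_structure(make_atoms(rep("OD1", 4), "ASP",
                                      rbind(c(0, 0, 0), c(8, 0, 0),
                                            c(0, 8, 0), c(0, 0, 8)),
                                      element = "O"))
  expect_equal(nrow(predict_metal_sites(far, params_fast)), 0)
})

test_that("predictions are equivariant under rigid motions", {
  toy <- toy_structure_from_gen(geometry = "octahedral", shell_radius = 2.1,
                                decoys = 20, seed = 31)
  s <- toy$structure
  p <- geometry_params(grid_step = 0.2)
  base <- predict_metal_sites(s, p)
  th <- 0.6
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
  shift <- c(2.3, -1.1, 4.8)
  s2 <- s
  s2$atoms[, c("x", "y", "z")] <-
    sweep(as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot), 2, shift, `+`)
  moved <- predict_metal_sites(s2, p)
  # the top-ranked site is preserved and its peak moves with the structure;
  # fragmentation of marginal low-count fringes may depend on the lattice
  expect_equal(moved$peak_density[1], base$peak_density[1])
  want <- as.numeric(rot %*% site_peak(base) + shift)
  expect_lt(sqrt(sum((site_peak(moved) - want)^2)), p$grid_step)
})

test_that("oversized grids hit the voxel budget with a helpful error", {
  toy <- toy_structure_from_gen(geometry = "tetrahedral", decoys = 0, seed = 1)
  s <- toy$structure
  tiny <- geometry_params(grid_step = 0.1, max_voxels = 1000)
  cl <- find_cliques(select_coordinators(s, tiny), tiny)
  expect_error(build_density_grid(s, cl, tiny), "coarser")
})
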