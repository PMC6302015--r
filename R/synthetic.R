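#' Synthetic ITC dataset with recorded ground truth
#'
#' Simulates a titration under a known binding model and adds Gaussian
#' integration noise scaled to the isotherm amplitude, mirroring a titration
#' of a 25 uM protein cell by repeated 2 uL injections of a concentrated
#' ion solution. Bit-identical for a fixed seed.
#'
#' @param protocol A [titration_protocol()].
#' @param params The generating `itc_params` model.
#' @param noise_frac Noise standard deviation as a fraction of the maximal
#'   absolute molar heat (default 1%).
#' @param seed Integer seed.
#' @param path Optional TSV path; when given, the isotherm is written there
#'   and the generating truth to `<path>_truth.json`.
#' @return List with `isotherm` (an `isotherm` data.frame), `truth`
#'   (generating parameters, protocol and realised `noise_sd`).
#' @export
#' @examples
#' gen_itc_dataset(titration_protocol(), one_set_params(2.7, 5.2e5, -2.1),
#'                 seed = 1)$truth$noise_sd
gen_itc_dataset <- function(protocol, params, noise_frac = 0.01, seed = 1L,
                            path = NULL) {
  stopifnot(noise_frac >= 0)
  iso <- simulate_isotherm(protocol, params, noise_sd = 0)
  noise_sd <- noise_frac * max(abs(iso$heat))
  if (noise_sd > 0) {
    set.seed(seed)
    iso$heat <- iso$heat + stats::rnorm(nrow(iso), sd = noise_sd)
  }
  truth <- list(model_kind = class(params)[1], params = unclass(params),
                noise_frac = noise_frac, noise_sd = noise_sd, seed = seed,
                protocol = unclass(protocol))
  if (!is.null(path)) {
    write_isotherm_tsv(iso, path)
    jsonlite::write_json(truth, paste0(tools::file_path_sans_ext(path),
                                       "_truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(isotherm = iso, truth = truth)
}

#' Synthetic equilibrium-dialysis dataset
#'
#' Generates paired-chamber totals for a protein binding a metal with Hill
#' behaviour: the buffer-side total equals the free-metal grid, and the
#' protein-side total is free + protein * Hill(free) plus Gaussian noise
#' proportional to the bound signal at each well (a fractional error on the
#' measured binding, the quantity the curve reports). Defaults reproduce a
#' 2-150 uM free-zinc design around a ~5 uM protein.
#'
#' @param b_max Maximal stoichiometry (mol/mol).
#' @param k_half Half-saturation free concentration, M.
#' @param h Hill coefficient.
#' @param protein_conc Protein concentration, M.
#' @param free_grid Free-metal grid, M; default 8 log-spaced points over
#'   2-150 uM.
#' @param noise_frac Per-well noise sd as a fraction of that well's bound
#'   concentration (default 5%); applied to the protein-side total.
#' @param seed Integer seed.
#' @param path Optional TSV path (truth goes to `<path>_truth.json`).
#' @return List with `wells` (data.frame in uM, ready for
#'   [read_wells_tsv()] round-trips) and `truth`.
#' @export
gen_dialysis_dataset <- function(b_max = 1.5, k_half = 4.7e-6, h = 1,
                                 protein_conc = 5e-6, free_grid = NULL,
                                 noise_frac = 0.05, seed = 1L, path = NULL) {
  if (is.null(free_grid))
    free_grid <- exp(seq(log(2e-6), log(150e-6), length.out = 8))
  stopifnot(all(free_grid > 0), noise_frac >= 0, protein_conc > 0)
  bound_conc <- protein_conc * hill_curve(free_grid, b_max, k_half, h)
  protein_side <- free_grid + bound_conc
  if (noise_frac > 0 && any(bound_conc > 0)) {
    set.seed(seed)
    protein_side <- protein_side +
      stats::rnorm(length(free_grid), sd = noise_frac * bound_conc)
  }
  wells <- data.frame(protein_side_total_uM = protein_side * 1e6,
                      buffer_side_total_uM = free_grid * 1e6,
                      protein_uM = protein_conc * 1e6)
  truth <- list(b_max = b_max, k_half = k_half, h = h,
                protein_conc = protein_conc, noise_frac = noise_frac,
                seed = seed)
  if (!is.null(path)) {
    write_wells_tsv(wells, path)
    jsonlite::write_json(truth, paste0(tools::file_path_sans_ext(path),
                                       "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(wells = wells, truth = truth)
}

#' Synthetic thermal melt curve
#'
#' Two-state sigmoid plus linear baselines plus Gaussian noise, emulating a
#' 1 K/min thermal scan. For `kind = "lambda"` the defaults trace the
#' red shift of a tryptophan emission peak from a 338 nm native baseline to
#' a 352 nm denatured baseline; for `kind = "scattering"` the curve is a
#' flat baseline with a sigmoidal rise centred at the aggregation onset.
#'
#' @param kind `"lambda"`, `"ratio"` or `"scattering"`.
#' @param t_m Mid-transition (or aggregation onset) temperature, degrees C;
#'   must lie inside `t_range`.
#' @param width Transition width (Boltzmann slope), degrees C.
#' @param baselines Length-2 numeric: native and denatured baseline levels
#'   (`NULL` picks a default per kind).
#' @param baseline_slopes Length-2 numeric baseline slopes per degree C.
#' @param t_range Scan range, degrees C.
#' @param step Temperature sampling, degrees C.
#' @param noise_frac Noise sd as a fraction of the baseline separation.
#' @param seed Integer seed.
#' @param path Optional TSV path (truth to `<path>_truth.json`).
#' @return List with `curve` (a [melt_curve()]) and `truth`.
#' @export
#' @examples
#' fit_boltzmann(gen_melt_curve("lambda", t_m = 40, seed = 3)$curve)$t_m
gen_melt_curve <- function(kind = c("lambda", "ratio", "scattering"),
                           t_m = 40, width = 3, baselines = NULL,
                           baseline_slopes = c(0, 0), t_range = c(15, 95),
                           step = 0.5, noise_frac = 0.01, seed = 1L,
                           path = NULL) {
  kind <- match.arg(kind)
  stopifnot(t_m > t_range[1], t_m < t_range[2], width >= 0, noise_frac >= 0)
  if (is.null(baselines))
    baselines <- switch(kind, lambda = c(338, 352), ratio = c(0.55, 0.95),
                        scattering = c(0, 1))
  temp <- seq(t_range[1], t_range[2], by = step)
  y <- if (width == 0) {
    ifelse(temp < t_m, baselines[1] + baseline_slopes[1] * temp,
           baselines[2] + baseline_slopes[2] * temp)
  } else {
    boltzmann_model(temp, baselines[1], baseline_slopes[1],
                    baselines[2], baseline_slopes[2], t_m, width)
  }
  noise_sd <- noise_frac * abs(baselines[2] - baselines[1])
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  curve <- melt_curve(temp, y, kind = kind)
  truth <- list(kind = kind, t_m = t_m, width = width,
                baselines = baselines, baseline_slopes = baseline_slopes,
                noise_frac = noise_frac, noise_sd = noise_sd, seed = seed)
  if (!is.null(path)) {
    write_melt_tsv(curve, path)
    jsonlite::write_json(truth, paste0(tools::file_path_sans_ext(path),
                                       "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(curve = curve, truth = truth)
}

toy_geometry_vectors <- function(geometry) {
  switch(geometry,
    tetrahedral = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                        c(-1, -1, 1)) / sqrt(3),
    octahedral = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1)),
    stop("unknown geometry: ", geometry))
}

format_pdb_atom <- function(serial, name, resname, chain, resno, xyz,
                            element, record = "ATOM") {
  namef <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, namef, resname, chain, resno,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

#' Synthetic toy structure with an ideal metal-chelation shell
#'
#' Writes a minimal but valid PDB: carboxylate oxygens (ASP OD1, one per
#' residue, so coordinator selection is exercised rather than bypassed)
#' placed at ideal tetrahedral or octahedral geometry around a recorded
#' center, plus random decoy carbon atoms (ALA CB) kept at least 5 Angstrom
#' from the center. Deterministic per seed. Used as ground-truthed
#' substrate for the site-prediction pipeline.
#'
#' @param geometry `"tetrahedral"` (4 vertices) or `"octahedral"` (6).
#' @param n_chelators Number of chelating oxygens, between 3 and the vertex
#'   count of `geometry`; default the full shell.
#' @param shell_radius Chelator distance from the center, Angstrom
#'   (1.8-3.0).
#' @param decoys Number of decoy carbons (placed 5-12 Angstrom out).
#' @param center Length-3 numeric true cation position.
#' @param seed Integer seed (controls decoy placement).
#' @param path Optional PDB output path (truth to `<path>_truth.json`).
#' @return List with `pdb_text` (character vector of PDB lines), `center`,
#'   `chelator_xyz`, `geometry`, `n_chelators`, `shell_radius`, `decoys`.
#' @export
#' @examples
#' toy <- gen_toy_structure(seed = 1)
#' head(toy$pdb_text, 3)
gen_toy_structure <- function(geometry = c("tetrahedral", "octahedral"),
                              n_chelators = NULL, shell_radius = 2.0,
                              decoys = 20L, center = c(0, 0, 0), seed = 1L,
                              path = NULL) {
  geometry <- match.arg(geometry)
  vecs <- toy_geometry_vectors(geometry)
  if (is.null(n_chelators)) n_chelators <- nrow(vecs)
  if (n_chelators < 3 || n_chelators > nrow(vecs))
    stop("n_chelators must be between 3 and ", nrow(vecs), " for ", geometry,
         " geometry")
  if (shell_radius < 1.8 || shell_radius > 3.0)
    stop("shell_radius must be within [1.8, 3.0] Angstrom")
  stopifnot(length(center) == 3, decoys >= 0)
  chel <- sweep(vecs[seq_len(n_chelators), , drop = FALSE] * shell_radius,
                2, center, `+`)
  set.seed(seed)
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n_chelators)) {
    serial <- serial + 1L
    lines <- c(lines, format_pdb_atom(serial, "OD1", "ASP", "A", i,
                                      chel[i, ], "O"))
  }
  dxyz <- NULL
  if (decoys > 0) {
    u <- matrix(stats::rnorm(3 * decoys), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- stats::runif(decoys, 5, 12)
    dxyz <- sweep(u * r, 2, center, `+`)
    for (i in seq_len(decoys)) {
      serial <- serial + 1L
      lines <- c(lines, format_pdb_atom(serial, "CB", "ALA", "A",
                                        n_chelators + i, dxyz[i, ], "C"))
    }
  }
  lines <- c(lines, "END")
  truth <- list(geometry = geometry, n_chelators = n_chelators,
                shell_radius = shell_radius, decoys = decoys,
                center = center, seed = seed)
  if (!is.null(path)) {
    writeLines(lines, path)
    jsonlite::write_json(truth, paste0(tools::file_path_sans_ext(path),
                                       "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(list(pdb_text = lines, center = center, chelator_xyz = chel,
                 decoy_xyz = dxyz, geometry = geometry,
                 n_chelators = n_chelators, shell_radius = shell_radius,
                 decoys = decoys, truth = truth))
}
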