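#' Titration protocol for a fixed-volume (overflow) calorimeter cell
#'
#' Describes one ITC experiment: cell volume and starting protein
#' concentration, syringe ligand concentration, the injection schedule and
#' the temperature. Defaults mirror a standard small-volume titration of a
#' 25 uM protein cell with repeated 2 uL injections. Syringe refills are
#' represented simply by continuing the injection schedule with the same
#' syringe concentration.
#'
#' @param cell_volume Active cell volume V0, L.
#' @param cell_protein_conc Starting protein concentration in the cell, M.
#' @param syringe_ligand_conc Ligand concentration in the syringe, M.
#' @param injection_volumes Vector of injection volumes, L (>= 2 entries).
#' @param temperature Kelvin.
#' @param competitor_label Optional metadata string describing a competing
#'   ion present at constant concentration (e.g. `"Ca 1 mM"`); competition
#'   data are fitted as apparent constants under the same models.
#' @return Object of class `titration_protocol`.
#' @export
#' @examples
#' titration_protocol(syringe_ligand_conc = 500e-6)
titration_protocol <- function(cell_volume = 200e-6,
                               cell_protein_conc = 25e-6,
                               syringe_ligand_conc = 500e-6,
                               injection_volumes = rep(2e-6, 40),
                               temperature = 298.15,
                               competitor_label = NULL) {
  stopifnot(cell_volume > 0, cell_protein_conc > 0, syringe_ligand_conc > 0,
            all(injection_volumes > 0), length(injection_volumes) >= 2,
            temperature > 0)
  structure(list(cell_volume = cell_volume,
                 cell_protein_conc = cell_protein_conc,
                 syringe_ligand_conc = syringe_ligand_conc,
                 injection_volumes = as.numeric(injection_volumes),
                 temperature = temperature,
                 competitor_label = competitor_label),
            class = "titration_protocol")
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat(sprintf(paste0("Titration: %.0f uL cell, %.1f uM protein, ",
                     "%.0f uM titrant, %d injections (%.1f uL median)\n"),
              x$cell_volume * 1e6, x$cell_protein_conc * 1e6,
              x$syringe_ligand_conc * 1e6, length(x$injection_volumes),
              stats::median(x$injection_volumes) * 1e6))
  if (!is.null(x$competitor_label))
    cat("  competitor:", x$competitor_label, "\n")
  invisible(x)
}

#' Cell composition after each injection
#'
#' Applies the discrete overflow-cell dilution bookkeeping: each injection of
#' volume dV displaces an equal volume of the homogeneous cell content, so
#' the protein total is scaled by `(1 - dV/V0)` per injection and the ligand
#' total follows `X_i = X_{i-1} (1 - dV/V0) + X_syr dV/V0`.
#'
#' @param protocol A [titration_protocol()].
#' @param i Optional injection index (1-based). When omitted, totals after
#'   every injection are returned.
#' @return A list with `total_protein` and `total_ligand` (M); scalars when
#'   `i` is given, vectors otherwise.
#' @export
cell_composition <- function(protocol, i = NULL) {
  dv <- protocol$injection_volumes
  v0 <- protocol$cell_volume
  dil <- cumprod(1 - dv / v0)
  mt <- protocol$cell_protein_conc * dil
  xt <- numeric(length(dv))
  xprev <- 0
  for (k in seq_along(dv)) {
    xt[k] <- xprev * (1 - dv[k] / v0) + protocol$syringe_ligand_conc * dv[k] / v0
    xprev <- xt[k]
  }
  if (is.null(i)) return(list(total_protein = mt, total_ligand = xt))
  if (i < 1 || i > length(dv)) stop("injection index out of range")
  list(total_protein = mt[i], total_ligand = xt[i])
}

#' Simulate an ITC binding isotherm
#'
#' Computes, for each injection, the equilibrium free-ligand concentration
#' from mass balance, the cumulative cell heat
#' `Q(i) = V0 * Mt(i) * H(x_i)` (H = enthalpy-weighted occupancy per mole of
#' protein), and the per-injection heat with the displaced-volume
#' correction
#' `dQ(i) = Q(i) - Q(i-1) + (dV_i/V0) * (Q(i) + Q(i-1)) / 2`,
#' reported per mole of injectant (kcal/mol). Optional additive Gaussian
#' noise emulates integration error of the titration peaks.
#'
#' @param protocol A [titration_protocol()].
#' @param params An `itc_params` model object.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   reported molar heats (kcal/mol injectant); 0 disables noise.
#' @param seed Optional integer seed used when `noise_sd > 0`.
#' @return Object of class `isotherm`: data.frame with columns `injection`,
#'   `dv_uL`, `molar_ratio`, `heat` (kcal/mol injectant) and
#'   `free_ligand` (M); cumulative heats in attribute `Q_kcal_per_L`.
#' @export
#' @examples
#' p <- titration_protocol(syringe_ligand_conc = 750e-6)
#' iso <- simulate_isotherm(p, one_set_params(2.7, 5.2e5, -2.1))
#' head(iso)
simulate_isotherm <- function(protocol, params, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  comp <- cell_composition(protocol)
  fns <- compile_model(params)
  dv <- protocol$injection_volumes
  v0 <- protocol$cell_volume
  n <- length(dv)
  x <- numeric(n)
  xprev <- NULL
  for (k in seq_len(n)) {
    x[k] <- free_ligand_compiled(comp$total_ligand[k], comp$total_protein[k],
                                 fns, start = xprev)
    xprev <- x[k]
  }
  # Q in kcal per litre of cell volume times V0 -> kcal
  q <- v0 * comp$total_protein * enthalpy_per_protein(params, x)
  qprev <- c(0, q[-n])
  dq <- q - qprev + (dv / v0) * (q + qprev) / 2
  heat <- dq / (dv * protocol$syringe_ligand_conc)  # kcal per mol injectant
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    heat <- heat + stats::rnorm(n, sd = noise_sd)
  }
  out <- data.frame(injection = seq_len(n),
                    dv_uL = dv * 1e6,
                    molar_ratio = comp$total_ligand / comp$total_protein,
                    heat = heat,
                    free_ligand = x)
  structure(out, class = c("isotherm", "data.frame"),
            Q_kcal_per_L = q / v0, protocol = protocol)
}
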