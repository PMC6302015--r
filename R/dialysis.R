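#' Bound-per-protein from an equilibrium-dialysis well
#'
#' In two-chamber equilibrium dialysis the free metal concentration is the
#' same on both sides of the membrane at equilibrium, so the buffer-side
#' total *is* the free concentration and the bound concentration is the
#' protein-side total minus it. Negative computed bound values (measurement
#' noise near zero binding) are clipped to zero and flagged.
#'
#' @param protein_side_total Total metal on the protein side, M.
#' @param buffer_side_total Total metal on the protein-free side, M.
#' @param protein_conc Protein concentration on the protein side, M (> 0).
#' @return data.frame with `free_metal` (M), `bound_per_protein`
#'   (mol/mol) and logical `clipped`. Vectorised over wells.
#' @export
#' @examples
#' bound_from_well(17.5e-6, 10e-6, 5e-6)  # 1.5 bound at 10 uM free
bound_from_well <- function(protein_side_total, buffer_side_total,
                            protein_conc) {
  if (any(protein_conc <= 0)) stop("protein concentration must be positive")
  if (any(protein_side_total < 0 | buffer_side_total < 0))
    stop("negative total concentrations")
  bound_conc <- protein_side_total - buffer_side_total
  clipped <- bound_conc < 0
  if (any(clipped))
    warning(sum(clipped), " well(s) with protein-side total below buffer-side",
            " total; bound clipped to 0")
  bound_conc[clipped] <- 0
  data.frame(free_metal = buffer_side_total,
             bound_per_protein = bound_conc / protein_conc,
             clipped = clipped)
}

#' Hill binding function
#'
#' `bound = b_max * f^h / (k_half^h + f^h)`; equals `b_max/2` at
#' `f = k_half` for any Hill coefficient.
#'
#' @param f Free ligand concentration(s).
#' @param b_max Maximal stoichiometry.
#' @param k_half Half-saturation free concentration (same units as `f`).
#' @param h Hill coefficient (> 0).
#' @return Numeric vector.
#' @export
hill_curve <- function(f, b_max, k_half, h = 1) {
  b_max * f^h / (k_half^h + f^h)
}

#' Fit the Hill equation to a binding curve
#'
#' Least-squares fit of `b_max`, `k_half` and the Hill coefficient `h` (all
#' positive, optimised on the log scale), multi-started over
#' `h in {0.5, 1, 2, 4}`. The Hill coefficient is a free parameter and is
#' reported alongside the half-saturation concentration.
#'
#' @param curve data.frame with columns `free_metal` and
#'   `bound_per_protein` (as produced by [bound_from_well()]), at least 4
#'   points.
#' @param fix_h Optional numeric; when supplied the Hill coefficient is held
#'   at this value instead of being fitted.
#' @param seed Integer seed (reserved; the default start set is
#'   deterministic).
#' @return Object of class `hill_fit`: `b_max`, `k_half`, `h`,
#'   `param_errors`, `rss`, `n_points`, `converged`.
#' @export
#' @examples
#' f <- c(2, 5, 10, 25, 60, 150) * 1e-6
#' curve <- data.frame(free_metal = f,
#'                     bound_per_protein = hill_curve(f, 1.5, 4.7e-6, 1))
#' fit_hill(curve)
fit_hill <- function(curve, fix_h = NULL, seed = 1L) {
  f <- curve$free_metal
  b <- curve$bound_per_protein
  ok <- is.finite(f) & is.finite(b) & f > 0
  f <- f[ok]; b <- b[ok]
  if (length(f) < 4) stop("need at least 4 wells with positive free metal")
  bmax0 <- max(b) * 1.05 + 1e-12
  kh0 <- {
    half <- which(b >= max(b) / 2)
    if (length(half)) f[half[1]] else stats::median(f)
  }
  resid_fn <- function(theta) {
    bm <- exp(theta[1]); kh <- exp(theta[2])
    hh <- if (is.null(fix_h)) exp(theta[3]) else fix_h
    r <- hill_curve(f, bm, kh, hh) - b
    r[!is.finite(r)] <- 1e6
    r
  }
  h_starts <- if (is.null(fix_h)) c(0.5, 1, 2, 4) else 1
  best <- NULL
  for (h0 in h_starts) {
    th0 <- c(log(bmax0), log(kh0))
    if (is.null(fix_h)) th0 <- c(th0, log(h0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(b_max = NA_real_, k_half = NA_real_, h = NA_real_,
                          param_errors = NULL, rss = NA_real_,
                          n_points = length(f), converged = FALSE),
                     class = "hill_fit"))
  th <- best$par
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(th)))
  vals <- exp(th)
  errs <- vals * se
  nm <- c("b_max", "k_half", if (is.null(fix_h)) "h")
  names(errs) <- nm
  structure(list(b_max = vals[1], k_half = vals[2],
                 h = if (is.null(fix_h)) vals[3] else fix_h,
                 param_errors = errs, rss = best$deviance,
                 n_points = length(f),
                 converged = best$info %in% 1:3),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: b_max %.3g, k_half %.3g M, h %.3g (rss %.3g, %d wells)%s\n",
              x$b_max, x$k_half, x$h, x$rss, x$n_points,
              if (isTRUE(x$converged)) "" else " [NOT converged]"))
  invisible(x)
}
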