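# --- internal: theta <-> params mappings (positive quantities on log scale) ---

theta_to_params <- function(theta, model_kind, n_sites = 3L) {
  switch(model_kind,
    one_set = one_set_params(exp(theta[1]), exp(theta[2]), theta[3]),
    two_sets = two_sets_params(exp(theta[1]), exp(theta[2]), theta[3],
                               exp(theta[4]), exp(theta[5]), theta[6]),
    sequential = sequential_params(exp(theta[seq_len(n_sites)]),
                                   theta[n_sites + seq_len(n_sites)]),
    stop("unknown model kind: ", model_kind))
}

params_to_theta <- function(params) {
  if (inherits(params, "one_set"))
    return(c(log(params$n), log(params$k_a), params$dh))
  if (inherits(params, "two_sets"))
    return(c(log(params$n1), log(params$k_a1), params$dh1,
             log(params$n2), log(params$k_a2), params$dh2))
  c(log(params$k_list), params$dh_list)
}

theta_names <- function(model_kind, n_sites = 3L) {
  switch(model_kind,
    one_set = c("n", "k_a", "dh"),
    two_sets = c("n1", "k_a1", "dh1", "n2", "k_a2", "dh2"),
    sequential = c(paste0("k_a", seq_len(n_sites)),
                   paste0("dh", seq_len(n_sites))))
}

# fast noiseless per-injection molar heats for a fixed composition
predict_heats <- function(comp, protocol, params) {
  fns <- compile_model(params)
  dv <- protocol$injection_volumes
  v0 <- protocol$cell_volume
  n <- length(dv)
  x <- numeric(n)
  h <- numeric(n)
  xprev <- NULL
  for (k in seq_len(n)) {
    x[k] <- free_ligand_compiled(comp$total_ligand[k], comp$total_protein[k],
                                 fns, start = xprev)
    xprev <- x[k]
    h[k] <- fns$H(x[k])
  }
  q <- v0 * comp$total_protein * h
  qprev <- c(0, q[-n])
  dq <- q - qprev + (dv / v0) * (q + qprev) / 2
  dq / (dv * protocol$syringe_ligand_conc)
}

# crude shape heuristics used to seed the optimiser
isotherm_start_hints <- function(iso) {
  h <- iso$heat
  amp0 <- mean(h[seq_len(min(3, length(h)))])
  n0 <- 1
  if (abs(amp0) > 0) {
    below <- which(abs(h) <= abs(amp0) / 2)
    if (length(below)) n0 <- iso$molar_ratio[below[1]]
  }
  list(amp0 = amp0, n0 = min(max(n0, 0.3), 10))
}

#' Fit a binding model to an ITC isotherm
#'
#' Non-linear least squares (Levenberg-Marquardt, via minpack.lm) of the
#' one-set-of-sites, two-sets-of-sites or sequential binding model to
#' per-injection molar heats. Site numbers and association constants are
#' optimised on the log scale; association constants are multi-started over
#' a log-spaced 1e3-1e9 M^-1 range because the sequential likelihood is
#' multi-modal. Parameter standard errors come from the local quadratic
#' approximation at the optimum. For the two-sets model the fitted site
#' classes are reported in ascending affinity order.
#'
#' @param isotherm An `isotherm` data.frame (columns `molar_ratio`, `heat`;
#'   from [simulate_isotherm()] or [read_isotherm_tsv()]).
#' @param protocol The [titration_protocol()] that produced it.
#' @param model_kind `"one_set"`, `"two_sets"` or `"sequential"`.
#' @param n_sites Number of sequential sites (sequential model only).
#' @param n_starts Number of optimiser starts.
#' @param seed Integer seed for the randomised starts.
#' @return Object of class `fit_result`: `model_kind`, `params` (an
#'   `itc_params`), `param_errors`, `rss`, `n_points`, `converged`,
#'   `n_starts`.
#' @export
#' @examples
#' p <- titration_protocol(syringe_ligand_conc = 750e-6)
#' iso <- simulate_isotherm(p, one_set_params(2.7, 5.2e5, -2.1))
#' fit_isotherm(iso, p, "one_set", n_starts = 4)$params
fit_isotherm <- function(isotherm, protocol,
                         model_kind = c("one_set", "two_sets", "sequential"),
                         n_sites = 3L, n_starts = 8L, seed = 1L) {
  model_kind <- match.arg(model_kind)
  obs <- isotherm$heat
  npar <- length(theta_names(model_kind, n_sites))
  if (length(obs) < 2 * npar)
    stop("need at least ", 2 * npar, " injections to fit ", model_kind)
  failed <- function() structure(list(model_kind = model_kind, params = NULL,
                                      param_errors = NULL, rss = NA_real_,
                                      n_points = length(obs), converged = FALSE,
                                      n_starts = n_starts),
                                 class = "fit_result")
  if (stats::sd(obs) == 0) return(failed())
  comp <- cell_composition(protocol)
  resid_fn <- function(theta) {
    p <- tryCatch(theta_to_params(theta, model_kind, n_sites),
                  error = function(e) NULL)
    if (is.null(p)) return(rep(1e6, length(obs)))
    pred <- tryCatch(predict_heats(comp, protocol, p),
                     error = function(e) rep(NA_real_, length(obs)))
    r <- pred - obs
    r[!is.finite(r)] <- 1e6
    r
  }
  hints <- isotherm_start_hints(isotherm)
  set.seed(seed)
  logk_grid <- log(10) * seq(3, 9, length.out = max(n_starts, 2))
  starts <- lapply(seq_len(n_starts), function(s) {
    amp <- if (abs(hints$amp0) > 1e-8) hints$amp0 else -1
    switch(model_kind,
      one_set = c(log(hints$n0), logk_grid[s], amp),
      two_sets = c(log(max(hints$n0 * 0.3, 0.2)),
                   log(10) * stats::runif(1, 3, 9), amp,
                   log(max(hints$n0 * 0.7, 0.2)),
                   log(10) * stats::runif(1, 3, 9), amp),
      sequential = {
        lk <- log(10) * stats::runif(n_sites, 3, 9)
        c(lk, rep(amp, n_sites))
      })
  })
  # one deterministic mid-range start in addition to the randomised ones
  if (model_kind == "two_sets")
    starts[[1]] <- c(log(max(hints$n0 * 0.3, 0.2)), log(1e5), hints$amp0,
                     log(max(hints$n0 * 0.7, 0.2)), log(1e7), hints$amp0)
  if (model_kind == "sequential")
    starts[[1]] <- c(log(c(1e6, 1e5, 1e6)), rep(hints$amp0, n_sites))
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-11, ptol = 1e-11)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(failed())
  theta <- best$par
  params <- theta_to_params(theta, model_kind, n_sites)
  se <- tryCatch({
    co <- summary(best)$coefficients
    co[, "Std. Error"]
  }, error = function(e) rep(NA_real_, length(theta)))
  # delta method back to the natural scale for log-parameterised quantities
  nat <- c(params_to_theta(params))
  islog <- switch(model_kind,
                  one_set = c(TRUE, TRUE, FALSE),
                  two_sets = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE),
                  sequential = c(rep(TRUE, n_sites), rep(FALSE, n_sites)))
  errs <- ifelse(islog, exp(nat) * se, se)
  names(errs) <- theta_names(model_kind, n_sites)
  if (model_kind == "two_sets" && params$k_a1 > params$k_a2) {
    params <- two_sets_params(params$n2, params$k_a2, params$dh2,
                              params$n1, params$k_a1, params$dh1)
    errs <- errs[c(4:6, 1:3)]
    names(errs) <- theta_names("two_sets")
  }
  structure(list(model_kind = model_kind, params = params,
                 param_errors = errs, rss = best$deviance,
                 n_points = length(obs),
                 converged = best$info %in% 1:3,
                 n_starts = n_starts),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("ITC fit (%s): rss %.4g over %d points, %s\n",
              x$model_kind, x$rss, x$n_points,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$params)) str(unclass(x$params), give.attr = FALSE)
  invisible(x)
}

#' Derived thermodynamic state of a binding equilibrium
#'
#' Converts an association constant and enthalpy into the full set of
#' standard-state quantities at a given temperature:
#' `Kd = 1/Ka`, `dG = -R T ln(Ka)` (kcal/mol, R = 1.98720e-3 kcal/K/mol) and
#' `dS = 1000 (dH - dG) / T` (cal/K/mol).
#'
#' @param k_a Association constant, M^-1 (> 0).
#' @param dh Enthalpy, kcal/mol.
#' @param temperature Kelvin (> 0); default 25 C.
#' @return Object of class `thermo_state` with `k_a`, `k_d`, `dg`, `dh`,
#'   `ds`, `temperature`.
#' @export
#' @examples
#' derive_thermo(3.320e4, -3.0)  # dG ~ -6.2 kcal/mol, dS ~ 10.6 cal/K/mol
derive_thermo <- function(k_a, dh, temperature = 298.15) {
  if (k_a <= 0) stop("k_a must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  dg <- -R_KCAL * temperature * log(k_a)
  ds <- 1000 * (dh - dg) / temperature
  structure(list(k_a = k_a, k_d = 1 / k_a, dg = dg, dh = dh, ds = ds,
                 temperature = temperature),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("Ka %.4g /M  Kd %.4g M  dG %.2f kcal/mol  dH %.2f kcal/mol  dS %.2f cal/K/mol (T %.2f K)\n",
              x$k_a, x$k_d, x$dg, x$dh, x$ds, x$temperature))
  invisible(x)
}
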