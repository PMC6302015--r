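#' Log-normal spectral band shape
#'
#' Four-parameter asymmetric band used for protein fluorescence emission
#' spectra (Siano-Metzler form, applied on the wavelength axis):
#' with `a = (lambda - lambda_max) * (asym^2 - 1) / (width * asym)`,
#' `I = i_max * exp(-(ln 2 / ln^2 asym) * ln^2(1 + a))` where `1 + a > 0`
#' and 0 elsewhere. `width` is the full width at half maximum and
#' `asym > 1` the asymmetry; as `asym -> 1` the band tends to a Gaussian of
#' the same FWHM.
#'
#' @param wavelength Wavelengths, nm.
#' @param lambda_max Peak position, nm.
#' @param i_max Peak intensity.
#' @param width FWHM, nm (> 0).
#' @param asym Asymmetry (> 1).
#' @return Intensities at `wavelength`.
#' @export
lognormal_band <- function(wavelength, lambda_max, i_max, width, asym) {
  stopifnot(width > 0, asym > 1)
  a <- (wavelength - lambda_max) * (asym^2 - 1) / (width * asym)
  out <- numeric(length(wavelength))
  ok <- (1 + a) > 0
  out[ok] <- i_max * exp(-(log(2) / log(asym)^2) * log(1 + a[ok])^2)
  out
}

#' Fit a log-normal band to an emission spectrum
#'
#' Least-squares fit of peak position, peak intensity, band width and
#' asymmetry; the reported `lambda_max` and `i_max` are read from the fitted
#' curve, not from the raw wavelength grid, so they are not quantised to the
#' scan step. A peak at the edge of the scanned range is flagged as
#' unreliable.
#'
#' @param wavelengths Strictly increasing wavelength grid, nm (>= 10 points).
#' @param intensities Non-negative intensities.
#' @return Object of class `spectrum_fit`: `lambda_max`, `i_max`, `width`,
#'   `asymmetry`, `rss`, `converged`, `reliable`.
#' @export
#' @examples
#' wl <- seq(300, 420, 1)
#' fit_lognormal_spectrum(wl, lognormal_band(wl, 338, 1, 55, 1.35))
fit_lognormal_spectrum <- function(wavelengths, intensities) {
  stopifnot(length(wavelengths) >= 10,
            all(diff(wavelengths) > 0),
            length(intensities) == length(wavelengths))
  if (any(intensities < 0)) stop("negative intensities")
  ipk <- which.max(intensities)
  lmax0 <- wavelengths[ipk]
  imax0 <- intensities[ipk]
  half <- intensities >= imax0 / 2
  w0 <- max(diff(range(wavelengths[half])), diff(range(wavelengths)) / 10)
  resid_fn <- function(theta) {
    r <- lognormal_band(wavelengths, theta[1], exp(theta[2]), exp(theta[3]),
                        1 + exp(theta[4])) - intensities
    r[!is.finite(r)] <- 1e6
    r
  }
  best <- NULL
  for (t4 in log(c(0.05, 0.3, 0.8))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(lmax0, log(imax0), log(w0), t4),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best))
    return(structure(list(lambda_max = NA_real_, i_max = NA_real_,
                          width = NA_real_, asymmetry = NA_real_,
                          rss = NA_real_, converged = FALSE, reliable = FALSE),
                     class = "spectrum_fit"))
  th <- best$par
  stepw <- stats::median(diff(wavelengths))
  reliable <- th[1] > min(wavelengths) + stepw &&
              th[1] < max(wavelengths) - stepw
  structure(list(lambda_max = th[1], i_max = exp(th[2]),
                 width = exp(th[3]), asymmetry = 1 + exp(th[4]),
                 rss = best$deviance,
                 converged = best$info %in% 1:3,
                 reliable = reliable),
            class = "spectrum_fit")
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("Spectrum fit: lambda_max %.2f nm, i_max %.4g, FWHM %.1f nm, asym %.3f%s\n",
              x$lambda_max, x$i_max, x$width, x$asymmetry,
              if (isTRUE(x$reliable)) "" else " [peak near range edge]"))
  invisible(x)
}

#' Melt-curve container
#'
#' Temperature-indexed observable from a thermal scan: a fluorescence peak
#' position (`"lambda"`, nm), a two-wavelength intensity ratio (`"ratio"`,
#' e.g. I350/I330) or static light scattering (`"scattering"`, a.u.).
#'
#' @param temperature Strictly increasing temperatures, degrees C.
#' @param value Observable values.
#' @param kind One of `"lambda"`, `"ratio"`, `"scattering"`.
#' @return Object of class `melt_curve` (a data.frame with a `kind`
#'   attribute).
#' @export
melt_curve <- function(temperature, value,
                       kind = c("lambda", "ratio", "scattering")) {
  kind <- match.arg(kind)
  stopifnot(all(diff(temperature) > 0), length(value) == length(temperature))
  structure(data.frame(temperature = temperature, value = value),
            class = c("melt_curve", "data.frame"), kind = kind)
}

boltzmann_model <- function(temp, a_n, b_n, a_d, b_d, t_m, slope) {
  nat <- a_n + b_n * temp
  den <- a_d + b_d * temp
  nat + (den - nat) / (1 + exp((t_m - temp) / slope))
}

#' Boltzmann fit of a thermal unfolding curve
#'
#' Two-state sigmoid with (optionally sloping) native and denatured
#' baselines:
#' `obs(T) = N(T) + (D(T) - N(T)) / (1 + exp((t_m - T)/slope))`.
#' The mid-transition temperature `t_m` is where the observable crosses the
#' midpoint of the two baselines; `slope` (> 0, degrees C) sets the
#' transition width.
#'
#' @param curve A [melt_curve()] (any kind with a sigmoidal transition;
#'   classically the lambda-max trace).
#' @param sloping_baselines Fit linear baseline slopes (default) or hold
#'   them flat.
#' @return Object of class `unfolding_result` with `t_m`, `slope`,
#'   `baselines` (native/denatured intercepts and slopes), `rss`,
#'   `method = "boltzmann"`, `converged`.
#' @export
#' @examples
#' tt <- seq(15, 95, 0.5)
#' cv <- melt_curve(tt, boltzmann_model(tt, 338, 0, 352, 0, 40, 3), "lambda")
#' fit_boltzmann(cv)$t_m
fit_boltzmann <- function(curve, sloping_baselines = TRUE) {
  temp <- curve$temperature
  y <- curve$value
  n <- length(temp)
  stopifnot(n >= 10)
  k <- max(3L, n %/% 10)
  a_n0 <- mean(head(y, k)); a_d0 <- mean(tail(y, k))
  tm0 <- {
    mid <- (a_n0 + a_d0) / 2
    cross <- which(diff(sign(y - mid)) != 0)
    if (length(cross)) temp[cross[1]] else stats::median(temp)
  }
  resid_fn <- function(theta) {
    b_n <- if (sloping_baselines) theta[2] else 0
    b_d <- if (sloping_baselines) theta[4] else 0
    r <- boltzmann_model(temp, theta[1], b_n, theta[3], b_d,
                         theta[5], exp(theta[6])) - y
    r[!is.finite(r)] <- 1e6
    r
  }
  best <- NULL
  for (sl0 in c(1, 3, 8)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(a_n0, 0, a_d0, 0, tm0, log(sl0)),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$deviance)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  no_fit <- is.null(best) ||
    best$par[5] < min(temp) || best$par[5] > max(temp)
  if (no_fit)
    return(structure(list(t_m = NA_real_, slope = NA_real_, baselines = NULL,
                          rss = if (is.null(best)) NA_real_ else best$deviance,
                          method = "boltzmann", t_agg = NULL,
                          converged = FALSE, flag = "no-transition"),
                     class = "unfolding_result"))
  th <- best$par
  structure(list(t_m = th[5], slope = exp(th[6]),
                 baselines = list(
                   native = c(intercept = th[1],
                              slope = if (sloping_baselines) th[2] else 0),
                   denatured = c(intercept = th[3],
                                 slope = if (sloping_baselines) th[4] else 0)),
                 rss = best$deviance, method = "boltzmann", t_agg = NULL,
                 converged = best$info %in% 1:3, flag = NULL),
            class = "unfolding_result")
}

moving_average <- function(y, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2 == 0) window <- window + 1L
  n <- length(y)
  half <- window %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(y[lo:hi])
  }, numeric(1))
}

derivative_tm <- function(curve, window, signed, flag_label) {
  temp <- curve$temperature
  y <- curve$value
  stopifnot(length(y) >= 20)
  ys <- moving_average(y, window)
  n <- length(ys)
  d <- (ys[c(2:n, n)] - ys[c(1, 1:(n - 1))]) /
       (temp[c(2:n, n)] - temp[c(1, 1:(n - 1))])
  flat <- diff(range(ys)) <= 1e-6 * max(abs(ys), 1)
  # the derivative trace is smoothed with the same window before the
  # extremum is read: an unsmoothed argmax is dominated by point noise
  score <- moving_average(if (signed) d else abs(d), window)
  if (flat || max(score) <= 0)
    return(structure(list(t_m = NA_real_, slope = NA_real_, baselines = NULL,
                          rss = NA_real_, method = flag_label$method,
                          t_agg = NULL, converged = FALSE,
                          flag = flag_label$flag),
                     class = "unfolding_result"))
  idx <- which(score == max(score))[1]  # ties -> lowest temperature
  structure(list(t_m = temp[idx], slope = NA_real_, baselines = NULL,
                 rss = NA_real_, method = flag_label$method, t_agg = NULL,
                 converged = TRUE, flag = NULL),
            class = "unfolding_result")
}

#' Mid-transition temperature from the first derivative of a ratio trace
#'
#' Smooths the intensity-ratio melt curve with a moving average, takes the
#' central-difference first derivative, smooths that derivative with the
#' same window, and returns the temperature of the maximal absolute
#' derivative (sign-agnostic, so either ratio orientation works). Ties
#' resolve to the lowest temperature; a flat curve yields a no-transition
#' flag instead of a temperature.
#'
#' @param curve A [melt_curve()] (>= 20 points).
#' @param window Moving-average window in points (odd; default 5).
#' @return An `unfolding_result` with `method = "derivative"`.
#' @export
tm_from_ratio_derivative <- function(curve, window = 5L) {
  derivative_tm(curve, window, signed = FALSE,
                flag_label = list(method = "derivative",
                                  flag = "no-transition"))
}

#' Aggregation onset temperature from a light-scattering trace
#'
#' Same smoothing and differentiation contract as
#' [tm_from_ratio_derivative()], but the aggregation temperature is the
#' temperature of the maximal (signed, rising) derivative of the scattering
#' signal; a trace without a rise yields a no-aggregation flag.
#'
#' @inheritParams tm_from_ratio_derivative
#' @return An `unfolding_result` with `method = "scattering"` and `t_agg`
#'   set.
#' @export
tagg_from_scattering <- function(curve, window = 5L) {
  out <- derivative_tm(curve, window, signed = TRUE,
                       flag_label = list(method = "scattering",
                                         flag = "no-aggregation"))
  out$t_agg <- out$t_m
  out
}

#' @export
print.unfolding_result <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat(sprintf("Melt analysis (%s): %s\n", x$method, x$flag))
  } else if (x$method == "scattering") {
    cat(sprintf("Aggregation onset: t_agg %.2f C (%s)\n", x$t_agg, x$method))
  } else {
    cat(sprintf("Unfolding: t_m %.2f C (%s)\n", x$t_m, x$method))
  }
  invisible(x)
}
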