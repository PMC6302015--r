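#' Binding-model parameter objects
#'
#' Constructors for the three binding models used to describe titration
#' calorimetry of multi-site cation binding:
#'
#' * `one_set_params(n, k_a, dh)` — `n` identical independent sites per
#'   protein with association constant `k_a` (M^-1) and molar enthalpy `dh`
#'   (kcal/mol).
#' * `two_sets_params(n1, k_a1, dh1, n2, k_a2, dh2)` — two independent
#'   classes of sites.
#' * `sequential_params(k_list, dh_list)` — stepwise macroscopic association
#'   constants `K1..Kk` (M^-1) and per-step enthalpies (kcal/mol) of a
#'   binding polynomial; trailing constants may be zero to disable steps.
#'
#' @param n,n1,n2 Sites per protein (> 0).
#' @param k_a,k_a1,k_a2 Association constants (M^-1, > 0).
#' @param dh,dh1,dh2 Enthalpies (kcal/mol).
#' @param k_list Ordered stepwise association constants (M^-1); first > 0,
#'   later entries >= 0.
#' @param dh_list Stepwise enthalpies (kcal/mol), same length as `k_list`.
#' @return An object of class `itc_params` with subclass `one_set`,
#'   `two_sets` or `sequential`.
#' @name itc_params
NULL

#' @rdname itc_params
#' @export
one_set_params <- function(n, k_a, dh) {
  stopifnot(n > 0, k_a > 0, is.finite(dh))
  structure(list(n = n, k_a = k_a, dh = dh),
            class = c("one_set", "itc_params"))
}

#' @rdname itc_params
#' @export
two_sets_params <- function(n1, k_a1, dh1, n2, k_a2, dh2) {
  stopifnot(n1 > 0, k_a1 > 0, n2 > 0, k_a2 > 0,
            is.finite(dh1), is.finite(dh2))
  structure(list(n1 = n1, k_a1 = k_a1, dh1 = dh1,
                 n2 = n2, k_a2 = k_a2, dh2 = dh2),
            class = c("two_sets", "itc_params"))
}

#' @rdname itc_params
#' @export
sequential_params <- function(k_list, dh_list) {
  stopifnot(length(k_list) >= 1, length(k_list) == length(dh_list),
            k_list[1] > 0, all(k_list >= 0), all(is.finite(dh_list)))
  structure(list(k_list = as.numeric(k_list), dh_list = as.numeric(dh_list)),
            class = c("sequential", "itc_params"))
}

#' @export
print.itc_params <- function(x, ...) {
  cat("ITC binding model:", class(x)[1], "\n")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Bound ligand per protein at a given free-ligand concentration
#'
#' Evaluates the model's binding function B(x): the average number of ligand
#' ions bound per protein molecule at free ligand concentration `x`.
#' For identical independent sites B(x) = n K x / (1 + K x); for two sets the
#' sum of two such terms; for the sequential model the logarithmic derivative
#' of the binding polynomial, B(x) = sum_i i b_i x^i / (1 + sum_i b_i x^i)
#' with b_i = K1...Ki.
#'
#' @param params An `itc_params` object.
#' @param x Free ligand concentration(s), M.
#' @return Numeric vector, same length as `x`.
#' @export
bound_per_protein <- function(params, x) UseMethod("bound_per_protein")

#' @export
bound_per_protein.one_set <- function(params, x) {
  params$n * params$k_a * x / (1 + params$k_a * x)
}

#' @export
bound_per_protein.two_sets <- function(params, x) {
  params$n1 * params$k_a1 * x / (1 + params$k_a1 * x) +
    params$n2 * params$k_a2 * x / (1 + params$k_a2 * x)
}

#' @export
bound_per_protein.sequential <- function(params, x) {
  beta <- cumprod(params$k_list)
  i <- seq_along(beta)
  vapply(x, function(xx) {
    terms <- beta * xx^i
    sum(i * terms) / (1 + sum(terms))
  }, numeric(1))
}

# dB/dx, analytic, used by the safeguarded Newton mass-balance solver
bound_deriv <- function(params, x) UseMethod("bound_deriv")

#' @export
bound_deriv.one_set <- function(params, x) {
  params$n * params$k_a / (1 + params$k_a * x)^2
}

#' @export
bound_deriv.two_sets <- function(params, x) {
  params$n1 * params$k_a1 / (1 + params$k_a1 * x)^2 +
    params$n2 * params$k_a2 / (1 + params$k_a2 * x)^2
}

#' @export
bound_deriv.sequential <- function(params, x) {
  beta <- cumprod(params$k_list)
  i <- seq_along(beta)
  vapply(x, function(xx) {
    terms <- beta * xx^i
    P <- 1 + sum(terms)
    dP <- sum(i * beta * xx^pmax(i - 1, 0))
    N <- sum(i * terms)
    dN <- sum(i^2 * beta * xx^pmax(i - 1, 0))
    (dN * P - N * dP) / P^2
  }, numeric(1))
}

# Compile a model into plain closures (B, dB, H) for tight inner loops:
# avoids S3 dispatch inside the Newton mass-balance solver during fitting.
compile_model <- function(params) {
  if (inherits(params, "one_set")) {
    n <- params$n; k <- params$k_a; dh <- params$dh
    return(list(
      B = function(x) n * k * x / (1 + k * x),
      dB = function(x) n * k / (1 + k * x)^2,
      H = function(x) n * dh * k * x / (1 + k * x)))
  }
  if (inherits(params, "two_sets")) {
    n1 <- params$n1; k1 <- params$k_a1; h1 <- params$dh1
    n2 <- params$n2; k2 <- params$k_a2; h2 <- params$dh2
    return(list(
      B = function(x) n1 * k1 * x / (1 + k1 * x) + n2 * k2 * x / (1 + k2 * x),
      dB = function(x) n1 * k1 / (1 + k1 * x)^2 + n2 * k2 / (1 + k2 * x)^2,
      H = function(x) n1 * h1 * k1 * x / (1 + k1 * x) +
                      n2 * h2 * k2 * x / (1 + k2 * x)))
  }
  beta <- cumprod(params$k_list)
  cumdh <- cumsum(params$dh_list)
  i <- seq_along(beta)
  im1 <- pmax(i - 1, 0)
  list(
    B = function(x) {
      terms <- beta * x^i
      sum(i * terms) / (1 + sum(terms))
    },
    dB = function(x) {
      terms <- beta * x^i
      P <- 1 + sum(terms)
      dterms <- i * beta * x^im1
      (sum(i * dterms) * P - sum(i * terms) * sum(dterms)) / P^2
    },
    H = function(x) {
      terms <- beta * x^i
      sum(cumdh * terms) / (1 + sum(terms))
    })
}

free_ligand_compiled <- function(total_ligand, total_protein, fns,
                                 tol = 1e-13, start = NULL) {
  if (total_ligand <= 0) return(0)
  f <- function(x) x + total_protein * fns$B(x) - total_ligand
  lo <- 0; hi <- total_ligand
  if (f(hi) < 0) stop("mass-balance root not bracketed (non-monotone model?)")
  x <- if (!is.null(start) && start > lo && start < hi) start else total_ligand / 2
  for (iter in 1:100) {
    fx <- f(x)
    if (fx > 0) hi <- x else lo <- x
    xn <- x - fx / (1 + total_protein * fns$dB(x))
    if (!is.finite(xn) || xn <= lo || xn >= hi) xn <- (lo + hi) / 2
    if (abs(xn - x) <= tol * max(xn, total_ligand * 1e-6)) return(xn)
    x <- xn
  }
  x
}

#' Free-ligand concentration from mass balance
#'
#' Solves the mass-balance equation
#' `total_ligand = x + total_protein * B(x)` for the free ligand
#' concentration `x` in `[0, total_ligand]`, where `B` is the model's
#' bound-per-protein function. The left side is strictly increasing in `x`,
#' so the root is unique; a safeguarded Newton iteration (bisection
#' fallback) converges to a relative tolerance of 1e-12 or better.
#'
#' @param total_ligand Total ligand concentration in the cell, M (>= 0).
#' @param total_protein Total protein concentration, M (>= 0).
#' @param params An `itc_params` object.
#' @param tol Relative tolerance on `x`.
#' @param start Optional starting guess (warm start across injections).
#' @return Free ligand concentration, M.
#' @export
free_ligand <- function(total_ligand, total_protein, params,
                        tol = 1e-13, start = NULL) {
  stopifnot(total_ligand >= 0, total_protein >= 0)
  free_ligand_compiled(total_ligand, total_protein, compile_model(params),
                       tol = tol, start = start)
}

# Heat content per mole of protein (kcal/mol protein) at free ligand x:
# the enthalpy-weighted occupancy of the model's species.
enthalpy_per_protein <- function(params, x) UseMethod("enthalpy_per_protein")

#' @export
enthalpy_per_protein.one_set <- function(params, x) {
  params$n * params$dh * params$k_a * x / (1 + params$k_a * x)
}

#' @export
enthalpy_per_protein.two_sets <- function(params, x) {
  params$n1 * params$dh1 * params$k_a1 * x / (1 + params$k_a1 * x) +
    params$n2 * params$dh2 * params$k_a2 * x / (1 + params$k_a2 * x)
}

#' @export
enthalpy_per_protein.sequential <- function(params, x) {
  beta <- cumprod(params$k_list)
  cumdh <- cumsum(params$dh_list)
  i <- seq_along(beta)
  vapply(x, function(xx) {
    terms <- beta * xx^i
    sum(cumdh * terms) / (1 + sum(terms))
  }, numeric(1))
}
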