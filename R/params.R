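#' Aging-model parameter set
#'
#' Bundles the seven constants of the copper aging model into a validated
#' object. The defaults are the reference values estimated from the
#' long-term European incubation dataset (outdoor aging, 0--360 days, 19
#' soils) with the temperature composite and the first hydrolysis constant
#' of Cu held fixed.
#'
#' @param B Dimensionless precipitation/nucleation coefficient; scales the
#'   CuOH+ fraction. Must be >= 0.
#' @param C Kinetic exponent scale (days) of the fast precipitation process,
#'   entering as `t^(C/t)`. Must be >= 0; the reference fit is 0 (the fast
#'   process is complete on the model's time scale).
#' @param N Diffusion pre-factor (per day), the composite `D0 / (alpha^2 l^2)`
#'   of the plane-sheet diffusion solution. Must be >= 0.
#' @param F Dimensionless occlusion coefficient multiplying the organic
#'   carbon fraction. Must be >= 0.
#' @param G Kinetic exponent scale (days) of the occlusion process, entering
#'   as `t^(G/t)`. Must be >= 0; reference fit 0.
#' @param K Arrhenius temperature composite `-Ea/R` in kelvin. Must be <= 0
#'   (activation energy is non-negative); the reference value -4330 K
#'   corresponds to Ea = 36 kJ/mol (see [arrhenius_k()]).
#' @param pK0 First hydrolysis constant of Cu (dimensionless). Fixed at 7.7
#'   (bulk solution value) by default; freeing it in the fit typically pulls
#'   it toward ~6.65 because soil surfaces promote hydrolysis.
#'
#' @return An object of class `aging_params`: a named list with the seven
#'   constants.
#' @examples
#' p <- aging_params()            # reference parameter set
#' p2 <- aging_params(B = 0, F = 0, N = 100)  # pure-diffusion variant
#' @export
aging_params <- function(B = 1.14, C = 0, N = 214.91, F = 2.85, G = 0,
                         K = -4330, pK0 = 7.7) {
  p <- list(B = B, C = C, N = N, F = F, G = G, K = K, pK0 = pK0)
  validate_aging_params(p)
  structure(p, class = "aging_params")
}

#' @rdname aging_params
#' @param x List or named vector with some or all of the seven parameter
#'   names; missing entries take the reference defaults.
#' @export
as_aging_params <- function(x) {
  if (inherits(x, "aging_params")) return(x)
  x <- as.list(x)
  known <- c("B", "C", "N", "F", "G", "K", "pK0")
  bad <- setdiff(names(x), known)
  if (length(bad) > 0)
    stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  do.call(aging_params, x)
}

validate_aging_params <- function(p) {
  for (nm in c("B", "C", "N", "F", "G", "K", "pK0")) {
    v <- p[[nm]]
    if (is.null(v) || length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  for (nm in c("B", "C", "N", "F", "G"))
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative")
  if (p$K > 0)
    stop("parameter 'K' (= -Ea/R) must be <= 0")
  invisible(p)
}

#' @export
print.aging_params <- function(x, ...) {
  cat("Copper aging model parameters\n")
  cat(sprintf("  B   = %-10.6g  (precipitation/nucleation)\n", x$B))
  cat(sprintf("  C   = %-10.6g  (fast-process kinetics, days)\n", x$C))
  cat(sprintf("  N   = %-10.6g  (diffusion pre-factor, 1/day)\n", x$N))
  cat(sprintf("  F   = %-10.6g  (occlusion)\n", x$F))
  cat(sprintf("  G   = %-10.6g  (occlusion kinetics, days)\n", x$G))
  cat(sprintf("  K   = %-10.6g  (-Ea/R, kelvin)\n", x$K))
  cat(sprintf("  pK0 = %-10.6g  (first hydrolysis constant of Cu)\n", x$pK0))
  invisible(x)
}

#' @export
as.list.aging_params <- function(x, ...) unclass(x)

#' Arrhenius temperature composite K = -Ea/R
#'
#' Converts an activation energy to the temperature composite used in the
#' diffusion term of the aging model. For the mean activation energy of
#' 36 kJ/mol estimated from short-term Cu aging, the composite rounds to
#' -4330 K, the value carried by [aging_params()].
#'
#' @param ea_kj_per_mol Activation energy in kJ/mol (>= 0).
#' @param gas_constant Molar gas constant in J/mol/K.
#' @return `-Ea/R` in kelvin (a non-positive number).
#' @examples
#' round(arrhenius_k(36))  # -4330
#' @export
arrhenius_k <- function(ea_kj_per_mol, gas_constant = 8.314) {
  stopifnot(is.numeric(ea_kj_per_mol), all(ea_kj_per_mol >= 0),
            gas_constant > 0)
  -ea_kj_per_mol * 1000 / gas_constant
}
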