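#' van't Hoff fit of a binding-constant temperature ladder
#'
#' Regresses \eqn{\ln K_b} on \eqn{1/T} following the van't Hoff relation
#' \deqn{\ln K_b = -\Delta H / (R T) + \Delta S / R}
#' so that the enthalpy change is \eqn{\Delta H = -slope \cdot R} and the
#' entropy change \eqn{\Delta S = intercept \cdot R}, with
#' R = 8.314 J/mol/K. Results are reported in kJ. \eqn{K_b} is treated as
#' dimensionless inside the logarithm (implicit 1 mol/L standard state).
#' With exactly two temperatures the line is exact and a `two_point` flag is
#' set.
#'
#' @param temperature numeric vector of temperatures in K (>= 2 distinct).
#' @param kb positive binding constants, one per temperature.
#' @return A list with `delta_h` (kJ/mol), `delta_s` (kJ/mol/K),
#'   `r_squared`, `two_point` and the underlying `lm`.
#' @examples
#' fit_vant_hoff(c(300, 310), c(100, 200))
#' @export
fit_vant_hoff <- function(temperature, kb) {
  temperature <- as.numeric(temperature)
  kb <- as.numeric(kb)
  if (length(temperature) != length(kb))
    stop("temperature and kb must have the same length")
  if (length(temperature) < 2)
    stop("at least two temperatures required")
  if (anyDuplicated(temperature))
    stop("degenerate ladder: duplicate temperatures")
  if (any(!is.finite(kb)) || any(kb <= 0))
    stop("invalid constant: kb must be positive")
  if (any(temperature <= 0)) stop("temperatures must be positive (kelvin)")

  x <- 1 / temperature
  y <- log(kb)
  model <- stats::lm(y ~ x)
  co <- stats::coef(model)
  two_point <- length(temperature) == 2
  r_squared <- if (two_point) 1
               else if (stats::var(y) == 0) NA_real_
               else suppressWarnings(summary(model))$r.squared
  list(delta_h = -unname(co[2]) * R_GAS / 1000,
       delta_s = unname(co[1]) * R_GAS / 1000,
       r_squared = r_squared, two_point = two_point, model = model)
}

#' Gibbs free energy of binding
#'
#' Gibbs-Helmholtz relation \eqn{\Delta G = \Delta H - T \Delta S},
#' vectorised over temperature.
#'
#' @param delta_h enthalpy change, kJ/mol.
#' @param delta_s entropy change, kJ/mol/K.
#' @param temperature temperature(s) in K (> 0).
#' @return \eqn{\Delta G} in kJ/mol, one value per temperature.
#' @examples
#' gibbs_free_energy(133.024, 0.487, c(303, 318))
#' @export
gibbs_free_energy <- function(delta_h, delta_s, temperature) {
  if (any(temperature <= 0)) stop("temperature must be positive (kelvin)")
  delta_h - temperature * delta_s
}

#' Classify the dominant binding force from thermodynamic signs
#'
#' Ross-type sign rules mapping (delta H, delta S) to the dominant
#' intermolecular force: both positive, hydrophobic interaction; both
#' negative, hydrogen bonding / van der Waals; enthalpy near zero with
#' positive entropy, electrostatic; anything else, mixed. "Near zero" means
#' `|delta_h| <= h_tol` (default 4 kJ/mol).
#'
#' @param delta_h enthalpy change, kJ/mol.
#' @param delta_s entropy change, kJ/mol/K.
#' @param h_tol half-width of the near-zero enthalpy band, kJ/mol.
#' @return One of `"hydrophobic"`, `"hbond_vdw"`, `"electrostatic"`,
#'   `"mixed"`.
#' @export
classify_forces <- function(delta_h, delta_s, h_tol = 4) {
  stopifnot(is.numeric(delta_h), is.numeric(delta_s), h_tol >= 0)
  if (abs(delta_h) <= h_tol && delta_s > 0) "electrostatic"
  else if (delta_h > h_tol && delta_s > 0) "hydrophobic"
  else if (delta_h < -h_tol && delta_s < 0) "hbond_vdw"
  else "mixed"
}

#' Thermodynamic characterisation of a binding-constant ladder
#'
#' Chains the van't Hoff fit, the Gibbs free energy at each input
#' temperature, and the binding-force classification into one result:
#' which temperatures make binding spontaneous (negative delta G), whether
#' complex formation is endothermic, and which force class dominates.
#'
#' @param binding_fits a list of `binding_fit` objects (from
#'   [fit_double_log()] or [binding_record()]) at two or more temperatures.
#' @param h_tol passed to [classify_forces()].
#' @return An object of class `thermo_result` with `delta_h`, `delta_s`,
#'   `delta_g_by_T` (named by temperature), `r_squared`, `force_class`,
#'   `endothermic` and `spontaneous_at`.
#' @examples
#' fits <- list(binding_record(2.55, temperature = 303),
#'              binding_record(3.18, temperature = 310),
#'              binding_record(3.95, temperature = 318))
#' thermo_pipeline(fits)
#' @export
thermo_pipeline <- function(binding_fits, h_tol = 4) {
  if (inherits(binding_fits, "binding_fit")) binding_fits <- list(binding_fits)
  stopifnot(all(vapply(binding_fits, inherits, TRUE, "binding_fit")))
  temps <- unname(vapply(binding_fits, function(f) f$temperature, 0))
  kbs <- unname(vapply(binding_fits, function(f) f$kb, 0))
  if (anyNA(temps)) stop("every binding fit needs a temperature")
  if (length(unique(temps)) < 2)
    stop("at least two temperatures required")

  ord <- order(temps)
  temps <- temps[ord]
  kbs <- kbs[ord]
  vh <- fit_vant_hoff(temps, kbs)
  dg <- gibbs_free_energy(vh$delta_h, vh$delta_s, temps)
  names(dg) <- as.character(temps)

  structure(list(delta_h = vh$delta_h, delta_s = vh$delta_s,
                 delta_g_by_T = dg, r_squared = vh$r_squared,
                 two_point = vh$two_point,
                 force_class = classify_forces(vh$delta_h, vh$delta_s, h_tol),
                 endothermic = vh$delta_h > 0,
                 spontaneous_at = temps[dg < 0],
                 kb_by_T = stats::setNames(kbs, as.character(temps))),
            class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat("van't Hoff thermodynamics of binding\n")
  cat(sprintf("  dH = %.3f kJ/mol (%s), dS = %.4f kJ/mol/K, R^2 = %.4f%s\n",
              x$delta_h, if (x$endothermic) "endothermic" else "exothermic",
              x$delta_s, x$r_squared,
              if (isTRUE(x$two_point)) " [two-point fit]" else ""))
  for (tt in names(x$delta_g_by_T))
    cat(sprintf("  dG(%s K) = %.3f kJ/mol\n", tt, x$delta_g_by_T[[tt]]))
  cat(sprintf("  dominant force: %s; spontaneous at %s\n", x$force_class,
              if (length(x$spontaneous_at))
                paste(x$spontaneous_at, "K", collapse = ", ")
              else "no studied temperature"))
  invisible(x)
}

#' @export
coef.thermo_result <- function(object, ...) {
  c(delta_H = object$delta_h, delta_S = object$delta_s)
}
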