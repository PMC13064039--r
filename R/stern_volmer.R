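#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer relation \eqn{F_0/F = 1 + K_{SV}[Q]} by ordinary
#' least squares of \eqn{F_0/F} on the quencher concentration, returning the
#' quenching constant \eqn{K_{SV}} (the slope) and the bimolecular quenching
#' rate constant \eqn{K_q = K_{SV}/\tau_0}, where \eqn{\tau_0} is the
#' unquenched fluorophore lifetime (1e-8 s for serum albumin by default).
#'
#' By default the intercept is left free and a diagnostic warning is raised
#' when it departs from 1 by more than `intercept_tol`; `fix_intercept =
#' TRUE` instead constrains the line through (0, 1) by regressing
#' \eqn{F_0/F - 1} on `[Q]` without intercept. Corrected intensities are used
#' when the series has been through [correct_series()].
#'
#' @param series a [titration_series()] with at least 3 points, all F > 0.
#' @param tau0 unquenched lifetime in seconds.
#' @param fix_intercept logical; constrain the intercept to 1.
#' @param intercept_tol relative deviation of the free intercept from 1 that
#'   triggers a diagnostics warning (default 5%).
#' @return An object of class `sv_fit` with components `ksv` (L/mol), `kq`
#'   (L/mol/s), `tau0`, `intercept`, `r_squared`, `slope_se`, `temperature`,
#'   `n_points` and the underlying `lm` fit.
#' @examples
#' s <- generate_titration(synthetic_config(ksv = 1.07e4))$series_by_T[[1]]
#' fit_stern_volmer(s)
#' @export
fit_stern_volmer <- function(series, tau0 = 1e-8, fix_intercept = FALSE,
                             intercept_tol = 0.05) {
  stopifnot(inherits(series, "titration_series"))
  f <- intensities(series)
  q <- series$quencher_conc
  if (length(q) < 3) stop("insufficient titration: need at least 3 points")
  if (any(f == 0)) stop("zero intensity: F must be positive at every point")
  if (!is.numeric(tau0) || tau0 <= 0) stop("tau0 must be positive")

  f0 <- f[q == 0]
  y <- f0 / f
  if (fix_intercept) {
    model <- stats::lm(I(y - 1) ~ 0 + q)
    ksv <- unname(stats::coef(model)[1])
    slope_se <- suppressWarnings(summary(model))$coefficients[1, 2]
    # R^2 of the constrained line against the observed F0/F
    ss_res <- sum((y - (1 + ksv * q))^2)
    ss_tot <- sum((y - mean(y))^2)
    r_squared <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
    intercept <- 1
  } else {
    model <- stats::lm(y ~ q)
    sm <- suppressWarnings(summary(model)) # noise-free data fit perfectly
    co <- sm$coefficients
    intercept <- unname(co[1, 1])
    ksv <- unname(co[2, 1])
    slope_se <- unname(co[2, 2])
    r_squared <- if (stats::var(y) == 0) NA_real_ else sm$r.squared
    if (abs(intercept - 1) > intercept_tol)
      warning(sprintf(
        "Stern-Volmer intercept %.4f departs from 1 by more than %g%%; check F0 or correction",
        intercept, 100 * intercept_tol))
  }

  structure(list(ksv = ksv, kq = ksv / tau0, tau0 = tau0,
                 intercept = intercept, r_squared = r_squared,
                 slope_se = slope_se, temperature = series$temperature,
                 n_points = length(q), fix_intercept = fix_intercept,
                 label = series$label, model = model,
                 data = data.frame(quencher_conc = q, ratio = y)),
            class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit (%g K, %d points%s)\n", x$temperature,
              x$n_points, if (x$fix_intercept) ", intercept fixed at 1" else ""))
  cat(sprintf("  K_SV = %.4g L/mol (slope SE %.3g), K_q = %.4g L/mol/s (tau0 = %g s)\n",
              x$ksv, x$slope_se, x$kq, x$tau0))
  cat(sprintf("  intercept = %.4f, R^2 = %.4f\n", x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.sv_fit <- function(object, ...) {
  c(K_SV = object$ksv, K_q = object$kq, intercept = object$intercept)
}

#' @export
summary.sv_fit <- function(object, ...) {
  structure(list(fit = object, lm_summary = summary(object$model)),
            class = "summary.sv_fit")
}

#' @export
print.summary.sv_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying regression of F0/F on [Q]:\n")
  print(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
predict.sv_fit <- function(object, newdata = NULL, ...) {
  q <- if (is.null(newdata)) object$data$quencher_conc
       else if (is.list(newdata)) newdata$quencher_conc
       else as.numeric(newdata)
  object$intercept + object$ksv * q
}

#' @export
residuals.sv_fit <- function(object, ...) {
  object$data$ratio - predict(object)
}

#' @export
plot.sv_fit <- function(x, ...) {
  graphics::plot(x$data$quencher_conc, x$data$ratio,
                 xlab = "[Q] (mol/L)", ylab = expression(F[0] / F),
                 main = sprintf("Stern-Volmer plot, %g K", x$temperature), ...)
  graphics::abline(a = x$intercept, b = x$ksv, lty = 2)
  invisible(x)
}

#' Classify the quenching mechanism from a temperature ladder of fits
#'
#' Static quenching (ground-state complex formation) shows a Stern-Volmer
#' constant that decreases with temperature and an apparent quenching rate
#' constant above the diffusion-controlled maximum (2e10 L/mol/s); dynamic
#' (collisional) quenching shows the opposite signatures. The rule set:
#'
#' * `ksv` strictly decreasing with T and every `kq > kq_limit` -> `static`
#' * `ksv` strictly increasing and every `kq <= kq_limit` -> `dynamic`
#' * a monotone trend whose `kq` pattern contradicts it -> `mixed`
#' * non-monotonic `ksv` (ties included) -> `indeterminate`
#' * a single temperature classifies on `kq` alone (`static` above the
#'   limit, otherwise `indeterminate`), with trend `"single-T"`.
#'
#' Fits may be supplied in any order; sorting by temperature is internal.
#'
#' @param fits a list of [fit_stern_volmer()] results (or a single fit).
#' @param kq_limit diffusion-controlled maximum quenching rate constant,
#'   L/mol/s.
#' @return An object of class `mechanism_call` with `mechanism`,
#'   `ksv_trend`, `kq_exceeds_limit`, `limit` and the per-temperature table.
#' @export
classify_mechanism <- function(fits, kq_limit = 2e10) {
  if (inherits(fits, "sv_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "sv_fit")))
  temps <- vapply(fits, function(f) f$temperature, 0)
  if (anyDuplicated(temps))
    stop("invalid temperature ladder: duplicate temperatures")
  ord <- order(temps)
  temps <- temps[ord]
  ksv <- vapply(fits, function(f) f$ksv, 0)[ord]
  kq <- vapply(fits, function(f) f$kq, 0)[ord]

  all_exceed <- all(kq > kq_limit)
  none_exceed <- all(kq <= kq_limit)
  if (length(ksv) == 1) {
    trend <- "single-T"
    mechanism <- if (all_exceed) "static" else "indeterminate"
  } else {
    d <- diff(ksv)
    trend <- if (all(d < 0)) "decreasing"
             else if (all(d > 0)) "increasing"
             else "non-monotonic"
    mechanism <- switch(trend,
      "decreasing" = if (all_exceed) "static" else "mixed",
      "increasing" = if (none_exceed) "dynamic" else "mixed",
      "non-monotonic" = "indeterminate")
  }
  structure(list(mechanism = mechanism, ksv_trend = trend,
                 kq_exceeds_limit = all_exceed, limit = kq_limit,
                 table = data.frame(temperature = temps, ksv = ksv, kq = kq)),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("Quenching mechanism: %s (K_SV trend %s; K_q %s limit %.3g L/mol/s)\n",
              x$mechanism, x$ksv_trend,
              if (x$kq_exceeds_limit) "exceeds" else "within", x$limit))
  print(x$table, row.names = FALSE)
  invisible(x)
}
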