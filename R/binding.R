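#' Double-logarithmic (modified Stern-Volmer) binding fit
#'
#' Estimates the binding constant \eqn{K_b} and the number of binding sites
#' \eqn{n} from the linearised binding relation
#' \deqn{\log_{10}\frac{F_0 - F}{F} = \log_{10} K_b + n \log_{10} [Q]}
#' by ordinary least squares: the intercept gives \eqn{\log_{10} K_b} and
#' the slope the stoichiometry \eqn{n}. Base-10 logarithms throughout.
#'
#' The reference point (`[Q] = 0`) is structurally excluded (its logarithm
#' is undefined), and points with `F >= F0` are excluded rather than
#' clipped, since their quenched fraction is non-positive; every excluded
#' point is listed with a reason so the bookkeeping is conservative.
#' Corrected intensities are used when present.
#'
#' @param series a [titration_series()] with at least 3 usable points after
#'   exclusions.
#' @return An object of class `binding_fit` with `log_kb`, `kb` (L/mol),
#'   `n_sites`, `r_squared`, `slope_se`, `temperature`, `n_points_used`,
#'   `excluded` (data frame of point, reason) and the underlying `lm`.
#' @examples
#' s <- generate_titration(synthetic_config(mode = "double_log", kb = 350))
#' fit_double_log(s$series_by_T[[1]])
#' @export
fit_double_log <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  f <- intensities(series)
  q <- series$quencher_conc
  if (any(f == 0)) stop("zero intensity: F must be positive at every point")
  f0 <- f[q == 0]

  reason <- rep(NA_character_, length(q))
  reason[q == 0] <- "reference point ([Q] = 0)"
  reason[q > 0 & f >= f0] <- "non-positive quenched fraction"
  use <- is.na(reason)
  if (sum(use) < 3)
    stop("insufficient informative points: need at least 3 with [Q] > 0 and F < F0")

  x <- log10(q[use])
  y <- log10((f0 - f[use]) / f[use])
  model <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(model)) # noise-free data fit perfectly
  co <- sm$coefficients
  log_kb <- unname(co[1, 1])
  n_sites <- unname(co[2, 1])
  slope_se <- unname(co[2, 2])
  r_squared <- if (stats::var(y) == 0) NA_real_ else sm$r.squared

  structure(list(log_kb = log_kb, kb = 10^log_kb, n_sites = n_sites,
                 r_squared = r_squared, slope_se = slope_se,
                 temperature = series$temperature,
                 n_points_used = sum(use),
                 excluded = data.frame(quencher_conc = q[!use],
                                       reason = reason[!use]),
                 label = series$label, model = model,
                 data = data.frame(log_q = x, log_ratio = y)),
            class = "binding_fit")
}

#' Build a binding-fit record from published constants
#'
#' Wraps an externally obtained \eqn{\log_{10} K_b} (for example a value
#' printed in a results table) in the same `binding_fit` structure the
#' fitting function returns, so comparative analyses such as [assign_site()]
#' and [metal_modulation()] can consume published and freshly fitted
#' constants interchangeably.
#'
#' @param log_kb base-10 logarithm of the binding constant.
#' @param n_sites number of binding sites, if known.
#' @param temperature temperature in K, if known.
#' @param r_squared goodness of fit, if known.
#' @return An object of class `binding_fit` (without regression internals).
#' @export
binding_record <- function(log_kb, n_sites = NA_real_, temperature = NA_real_,
                           r_squared = NA_real_) {
  stopifnot(is.numeric(log_kb), length(log_kb) == 1, is.finite(log_kb))
  structure(list(log_kb = log_kb, kb = 10^log_kb, n_sites = n_sites,
                 r_squared = r_squared, slope_se = NA_real_,
                 temperature = temperature, n_points_used = NA_integer_,
                 excluded = data.frame(quencher_conc = numeric(0),
                                       reason = character(0)),
                 label = "", model = NULL, data = NULL),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit%s\n",
              if (is.finite(x$temperature)) sprintf(" (%g K)", x$temperature) else ""))
  cat(sprintf("  log10 K_b = %.4g  (K_b = %.4g L/mol),  n = %.4g\n",
              x$log_kb, x$kb, x$n_sites))
  if (!is.null(x$model))
    cat(sprintf("  R^2 = %.4f, slope SE %.3g, %d points used, %d excluded\n",
                x$r_squared, x$slope_se, x$n_points_used, nrow(x$excluded)))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) {
  c(log_Kb = object$log_kb, Kb = object$kb, n = object$n_sites)
}

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  if (is.null(object$data)) stop("record has no regression data")
  lq <- if (is.null(newdata)) object$data$log_q
        else log10(if (is.list(newdata)) newdata$quencher_conc else as.numeric(newdata))
  object$log_kb + object$n_sites * lq
}

#' @export
residuals.binding_fit <- function(object, ...) {
  if (is.null(object$data)) stop("record has no regression data")
  object$data$log_ratio - predict(object)
}

#' @export
plot.binding_fit <- function(x, ...) {
  if (is.null(x$data)) stop("record has no regression data")
  graphics::plot(x$data$log_q, x$data$log_ratio,
                 xlab = expression(log[10] * "[Q]"),
                 ylab = expression(log[10] * ((F[0] - F) / F)),
                 main = "Double-logarithmic binding plot", ...)
  graphics::abline(a = x$log_kb, b = x$n_sites, lty = 2)
  invisible(x)
}

#' Interpret stoichiometry and affinity of a binding fit
#'
#' Reports the nearest integer ligand:protein ratio `1:round(n)` when the
#' fitted number of binding sites is within `tol` of an integer, otherwise a
#' non-integer verdict, and labels the affinity band of the binding
#' constant: below 1e4 L/mol weak-to-moderate, 1e4 to 1e6 moderate-to-strong,
#' above 1e6 strong.
#'
#' @param fit a `binding_fit` (from [fit_double_log()] or [binding_record()]).
#' @param tol tolerance on `|n - round(n)|` for an integer call.
#' @return A list with `stoichiometry` (text), `n_sites`, `affinity`, `kb`.
#' @export
interpret_stoichiometry <- function(fit, tol = 0.15) {
  stopifnot(inherits(fit, "binding_fit"))
  n <- fit$n_sites
  r <- round(n)
  stoichiometry <- if (r >= 1 && abs(n - r) <= tol) {
    sprintf("1:%d", r)
  } else {
    sprintf("non-integer (n = %.2f)", n)
  }
  affinity <- if (fit$kb < 1e4) "weak-to-moderate"
              else if (fit$kb <= 1e6) "moderate-to-strong"
              else "strong"
  list(stoichiometry = stoichiometry, n_sites = n, affinity = affinity,
       kb = fit$kb, tol = tol)
}
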