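#' Inner filter effect correction
#'
#' Corrects a measured fluorescence intensity for attenuation of the
#' excitation and emission beams by absorbing species in the cuvette
#' (the inner filter effect), using the Lakowicz relation
#' \deqn{F_{corr} = F_{obs} \times 10^{(A_{ex} + A_{em})/2}}
#' with decadic absorbances. The correction is the identity at zero
#' absorbance, symmetric in its two absorbance arguments, and never
#' decreases the intensity.
#'
#' @param f_obs measured fluorescence intensity (arbitrary units).
#' @param a_ex absorbance at the excitation wavelength (>= 0).
#' @param a_em absorbance at the emission wavelength (>= 0).
#' @return Corrected intensity, same shape as `f_obs`.
#' @examples
#' correct_inner_filter(100, 0.42, 0) # 100 * 10^0.21
#' @export
correct_inner_filter <- function(f_obs, a_ex, a_em) {
  if (any(a_ex < 0, na.rm = TRUE) || any(a_em < 0, na.rm = TRUE))
    stop("invalid absorbance: negative value")
  f_obs * 10^((a_ex + a_em) / 2)
}

#' Apply inner filter correction to a whole titration series
#'
#' Applies [correct_inner_filter()] pointwise, storing the result alongside
#' the original observed intensities (`f_cor` next to `f_obs`). Downstream
#' fits use the corrected intensities when present.
#'
#' When some or all points lack absorbance measurements, behaviour is
#' controlled by `pass_through`: with `pass_through = TRUE` such points are
#' passed through uncorrected with a warning; without it a series with a
#' mixture of measured and missing absorbances is an error, and a series
#' with no absorbances at all is also refused so silent non-correction
#' cannot happen by accident.
#'
#' @param series a [titration_series()].
#' @param pass_through logical; allow points without absorbances through
#'   uncorrected (with a warning).
#' @return The series with `f_cor` filled in (or unchanged under full
#'   pass-through).
#' @export
correct_series <- function(series, pass_through = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  n <- length(series$quencher_conc)
  ax <- series$a_ex
  ae <- series$a_em
  have <- if (is.null(ax) || is.null(ae)) rep(FALSE, n) else !(is.na(ax) | is.na(ae))

  if (all(have)) {
    series$f_cor <- correct_inner_filter(series$f_obs, ax, ae)
    return(series)
  }
  if (!pass_through) {
    if (any(have))
      stop("inconsistent absorbance columns: some points lack A_ex/A_em; ",
           "measure all points or set pass_through = TRUE")
    stop("series carries no absorbance data; set pass_through = TRUE to ",
         "analyse uncorrected intensities")
  }
  if (!any(have)) {
    warning("no absorbance data: intensities passed through uncorrected")
    return(series)
  }
  f_cor <- series$f_obs
  f_cor[have] <- correct_inner_filter(series$f_obs[have], ax[have], ae[have])
  warning(sprintf("%d point(s) lack absorbances and were passed through uncorrected",
                  sum(!have)))
  series$f_cor <- f_cor
  series
}
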