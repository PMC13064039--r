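#' Construct a synchronous fluorescence series
#'
#' Synchronous spectra are scanned with a fixed excitation-emission offset
#' (delta lambda); an offset of 60 nm reports the tryptophan
#' microenvironment and 15 nm the tyrosine microenvironment. The series
#' holds one spectrum per quencher level.
#'
#' @param delta_lambda scan offset in nm (15 or 60 by default; other values
#'   allowed via `allowed`).
#' @param spectra list of [new_spectrum()] objects of kind
#'   `"synchronous_nm"`, one per quencher level.
#' @param quencher_concs quencher concentrations in mol/L, one per spectrum.
#' @param allowed admissible offsets.
#' @return An object of class `synchronous_series`.
#' @export
synchronous_series <- function(delta_lambda, spectra, quencher_concs,
                               allowed = c(15, 60)) {
  if (!delta_lambda %in% allowed)
    stop("delta_lambda must be one of: ", paste(allowed, collapse = ", "))
  stopifnot(length(spectra) == length(quencher_concs),
            all(vapply(spectra, inherits, TRUE, "band_spectrum")))
  if (!all(vapply(spectra, function(s) s$axis_kind, "") == "synchronous_nm"))
    stop("all spectra must be of kind synchronous_nm")
  ord <- order(quencher_concs)
  structure(list(delta_lambda = delta_lambda, spectra = spectra[ord],
                 quencher_concs = as.numeric(quencher_concs)[ord]),
            class = "synchronous_series")
}

modality_report <- function(residue, shift, direction, interpretation,
                            trend = NULL, window = NULL) {
  structure(list(residue = residue, shift = shift, direction = direction,
                 interpretation = interpretation, trend = trend,
                 window = window),
            class = "modality_report")
}

#' @export
print.modality_report <- function(x, ...) {
  cat(sprintf("%s: shift %+.3g (%s) - %s\n", x$residue, x$shift, x$direction,
              x$interpretation))
  invisible(x)
}

#' Residue-resolved peak shift from a synchronous titration
#'
#' Locates the band maximum in the zero-quencher and highest-quencher
#' synchronous spectra and reports the signed shift between them. A shift
#' beyond the resolution threshold signals a polarity change of the
#' microenvironment around the reporting residue (tryptophan for a 60 nm
#' offset, tyrosine for 15 nm). A per-point trend of peak positions across
#' the whole titration is attached.
#'
#' @param series a [synchronous_series()] with at least 2 spectra.
#' @param window `(lo, hi)` window on the synchronous (excitation) axis, nm.
#' @param threshold shift-resolution threshold in nm; default half the grid
#'   step.
#' @return A `modality_report` with `residue`, `shift`, `direction`,
#'   `interpretation` and a `trend` data frame.
#' @export
synchronous_shift <- function(series, window = c(270, 320), threshold = NULL) {
  stopifnot(inherits(series, "synchronous_series"))
  if (length(series$spectra) < 2)
    stop("need at least two spectra (reference and treated)")
  residue <- if (series$delta_lambda == 60) "Trp"
             else if (series$delta_lambda == 15) "Tyr"
             else sprintf("offset-%g-nm", series$delta_lambda)
  peaks <- lapply(series$spectra, locate_peak, window = window)
  sh <- peak_shift(peaks[[1]], peaks[[length(peaks)]], threshold)
  interpretation <- if (sh$direction == "none")
    sprintf("no detectable microenvironment change near %s", residue)
  else
    sprintf("microenvironment change near %s", residue)
  trend <- data.frame(
    quencher_conc = series$quencher_concs,
    position = vapply(peaks, function(p) p$position, 0),
    height = vapply(peaks, function(p) p$height, 0))
  modality_report(residue, sh$shift, sh$direction, interpretation,
                  trend = trend, window = window)
}

#' FTIR amide band shifts between free and complexed protein
#'
#' Locates the amide I (1600-1700 cm^-1, mainly C=O stretch) and amide II
#' (1500-1600 cm^-1) band maxima in the free-protein and complex spectra
#' and reports the per-band signed shifts. The amide I band tracks protein
#' secondary structure, so a shift beyond the resolution threshold is
#' interpreted as a secondary-structure change upon binding.
#'
#' @param free,complexed `band_spectrum` objects of kind
#'   `"ftir_wavenumber"` covering 1500-1700 cm^-1.
#' @param threshold shift threshold in cm^-1; default half the grid step.
#' @return A list of two `modality_report`s named `amideI` and `amideII`.
#' @export
amide_band_shift <- function(free, complexed, threshold = NULL) {
  stopifnot(inherits(free, "band_spectrum"), inherits(complexed, "band_spectrum"))
  if (free$axis_kind != "ftir_wavenumber" || complexed$axis_kind != "ftir_wavenumber")
    stop("incomparable spectra: both inputs must be ftir_wavenumber spectra")
  for (s in list(free, complexed)) {
    if (min(s$axis) > 1500 || max(s$axis) < 1700)
      stop("band window not covered: spectra must span 1500-1700 cm^-1")
  }
  windows <- list(amideI = c(1600, 1700), amideII = c(1500, 1600))
  out <- lapply(names(windows), function(band) {
    w <- windows[[band]]
    p_free <- locate_peak(free, w)
    p_cplx <- locate_peak(complexed, w)
    sh <- peak_shift(p_free, p_cplx, threshold)
    interpretation <- if (band == "amideI") {
      if (sh$direction == "none") "no detectable secondary-structure change"
      else "secondary-structure change"
    } else {
      if (sh$direction == "none") "amide II band stationary"
      else "amide II band shifted"
    }
    modality_report(band, sh$shift, sh$direction, interpretation, window = w)
  })
  names(out) <- names(windows)
  out
}

#' UV-vis titration features and molar absorptivity
#'
#' Extracts, per spectrum, the positions and heights of the two protein
#' absorption bands: the strong band near 220 nm (peptide backbone /
#' alpha-helix) and the modest aromatic band near 280 nm (pi-pi*
#' transitions of Trp, Tyr, Phe). Across the titration it reports the trend
#' of the 220 nm band (position shift and intensity change between the
#' first and last points), and computes the molar absorptivity of the
#' aromatic band by Beer-Lambert,
#' \eqn{\epsilon = A(\lambda_{max}) / (c \cdot l)}.
#'
#' @param spectra list of `band_spectrum` objects of kind `"uv_nm"`,
#'   ordered (or orderable via `meta$quencher_conc`) by quencher level.
#' @param protein_conc protein concentration in mol/L (> 0).
#' @param path_cm optical path length in cm (> 0).
#' @param windows list with `helix` and `aromatic` windows in nm.
#' @param intensity_tol relative intensity change counting as a real change.
#' @return An object of class `uv_features`: per-spectrum `table`,
#'   `band220_trend`, `epsilon` (M^-1 cm^-1, from the last spectrum) and a
#'   `changes_present` flag used by [corroborate_mechanism()].
#' @export
uv_titration_features <- function(spectra, protein_conc, path_cm = 1,
                                  windows = list(helix = c(210, 235),
                                                 aromatic = c(260, 300)),
                                  intensity_tol = 0.05) {
  if (inherits(spectra, "band_spectrum")) spectra <- list(spectra)
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, TRUE, "band_spectrum")))
  if (!all(vapply(spectra, function(s) s$axis_kind, "") == "uv_nm"))
    stop("all spectra must be of kind uv_nm")
  if (!is.numeric(protein_conc) || protein_conc <= 0 ||
      !is.numeric(path_cm) || path_cm <= 0)
    stop("invalid Beer-Lambert input: protein_conc and path_cm must be positive")

  concs <- vapply(spectra, function(s) s$meta$quencher_conc %||% NA_real_, 0)
  if (!anyNA(concs)) {
    ord <- order(concs)
    spectra <- spectra[ord]
    concs <- concs[ord]
  }
  p220 <- lapply(spectra, locate_peak, window = windows$helix)
  p280 <- lapply(spectra, locate_peak, window = windows$aromatic)
  tab <- data.frame(
    quencher_conc = concs,
    pos_220 = vapply(p220, function(p) p$position, 0),
    a_220 = vapply(p220, function(p) p$height, 0),
    pos_280 = vapply(p280, function(p) p$position, 0),
    a_280 = vapply(p280, function(p) p$height, 0))
  tab$epsilon <- tab$a_280 / (protein_conc * path_cm)

  n <- length(spectra)
  if (n >= 2) {
    sh <- peak_shift(p220[[1]], p220[[n]])
    base <- tab$a_220[1]
    rel <- if (base > 0) (tab$a_220[n] - base) / base
           else if (tab$a_220[n] > 0) Inf else 0
    intensity_trend <- if (rel > intensity_tol) "increasing"
                       else if (rel < -intensity_tol) "decreasing"
                       else "stable"
    position_trend <- switch(sh$direction,
                             red = "red shift", blue = "blue shift",
                             none = "stationary")
    changes <- sh$direction != "none" || intensity_trend != "stable"
    band220 <- list(shift = sh$shift, direction = sh$direction,
                    position_trend = position_trend,
                    intensity_trend = intensity_trend,
                    relative_intensity_change = rel)
  } else {
    band220 <- list(shift = NA_real_, direction = NA_character_,
                    position_trend = NA_character_,
                    intensity_trend = NA_character_,
                    relative_intensity_change = NA_real_)
    changes <- NA
  }
  structure(list(table = tab, band220_trend = band220,
                 epsilon = tab$epsilon[n], protein_conc = protein_conc,
                 path_cm = path_cm, changes_present = changes),
            class = "uv_features")
}

#' @export
print.uv_features <- function(x, ...) {
  cat(sprintf("UV-vis titration features (%d spectra): epsilon(~280 nm) = %.4g M^-1 cm^-1\n",
              nrow(x$table), x$epsilon))
  if (!is.na(x$changes_present))
    cat(sprintf("  220 nm band: %s, intensity %s\n",
                x$band220_trend$position_trend, x$band220_trend$intensity_trend))
  invisible(x)
}

#' Cross-check the quenching mechanism against UV-vis evidence
#'
#' Static quenching forms a ground-state complex and therefore perturbs the
#' protein absorption spectrum; dynamic quenching does not. The rule:
#' spectral changes present with a static call, or absent with a dynamic
#' call, are `"consistent"`; changes present with a dynamic call are
#' `"inconsistent"`; any other combination is `"ambiguous"`.
#'
#' @param uv_features a [uv_titration_features()] result.
#' @param mechanism a `mechanism_call` from [classify_mechanism()] (or the
#'   mechanism string).
#' @return A list with `call`, `changes_present` and `mechanism`.
#' @export
corroborate_mechanism <- function(uv_features, mechanism) {
  stopifnot(inherits(uv_features, "uv_features"))
  mech <- if (inherits(mechanism, "mechanism_call")) mechanism$mechanism
          else as.character(mechanism)
  changes <- uv_features$changes_present
  call <- if (is.na(changes)) "ambiguous"
          else if (changes && mech == "static") "consistent"
          else if (changes && mech == "dynamic") "inconsistent"
          else if (!changes && mech == "dynamic") "consistent"
          else "ambiguous"
  list(call = call, changes_present = changes, mechanism = mech)
}
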