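#' Construct a titration series
#'
#' A titration series is the central input of the quenching pipeline: the
#' fluorescence intensity of a fixed amount of protein measured at a ladder of
#' quencher (ligand) concentrations at one temperature. The point at zero
#' quencher concentration supplies the unquenched reference intensity F0 and
#' must be present exactly once; F0 is never extrapolated.
#'
#' @param quencher_conc numeric, quencher concentrations in mol/L (>= 0;
#'   exactly one value must be 0).
#' @param f_obs numeric, observed fluorescence intensities (arbitrary units,
#'   >= 0), same length as `quencher_conc`.
#' @param a_ex,a_em optional numeric, absorbance of the solution at the
#'   excitation and emission wavelengths (dimensionless, >= 0). `NA` entries
#'   mark points without an absorbance measurement.
#' @param temperature numeric scalar, temperature in kelvin (> 0).
#' @param lambda_ex,lambda_em excitation and emission wavelengths in nm.
#' @param label free-text label for the series.
#' @return An object of class `titration_series`: a list with the sorted
#'   concentration ladder, intensities, optional absorbances and metadata.
#'   Points are stored in ascending concentration order.
#' @seealso [read_titration_csv()], [correct_series()], [fit_stern_volmer()],
#'   [fit_double_log()]
#' @examples
#' ts <- titration_series(c(0, 2e-5, 4e-5), c(641, 520, 430), temperature = 303)
#' ts
#' @export
titration_series <- function(quencher_conc, f_obs, a_ex = NULL, a_em = NULL,
                             temperature, lambda_ex = 279, lambda_em = 341,
                             label = "") {
  quencher_conc <- as.numeric(quencher_conc)
  f_obs <- as.numeric(f_obs)
  n <- length(quencher_conc)
  if (length(f_obs) != n)
    stop("quencher_conc and f_obs must have the same length")
  if (anyNA(quencher_conc) || anyNA(f_obs))
    stop("invalid measurement: missing concentration or intensity")
  if (any(quencher_conc < 0) || any(f_obs < 0))
    stop("invalid measurement: negative concentration or intensity")
  for (nm in c("a_ex", "a_em")) {
    a <- get(nm)
    if (!is.null(a)) {
      a <- as.numeric(a)
      if (length(a) != n) stop(nm, " must match the number of points")
      if (any(a < 0, na.rm = TRUE)) stop("invalid absorbance: negative value")
      assign(nm, a)
    }
  }
  if (anyDuplicated(quencher_conc))
    stop("ambiguous titration point: duplicate quencher concentrations")
  if (sum(quencher_conc == 0) != 1)
    stop("no reference point: the series must contain exactly one [Q] = 0 measurement")
  if (!is.numeric(temperature) || length(temperature) != 1 ||
      !is.finite(temperature) || temperature <= 0)
    stop("temperature must be a positive scalar (kelvin)")

  ord <- order(quencher_conc)
  structure(
    list(
      quencher_conc = quencher_conc[ord],
      f_obs = f_obs[ord],
      a_ex = if (is.null(a_ex)) NULL else a_ex[ord],
      a_em = if (is.null(a_em)) NULL else a_em[ord],
      f_cor = NULL,
      temperature = as.numeric(temperature),
      lambda_ex = lambda_ex,
      lambda_em = lambda_em,
      label = label
    ),
    class = "titration_series"
  )
}

#' Unquenched reference intensity of a titration series
#'
#' Returns the intensity at zero quencher concentration, using the
#' inner-filter-corrected value when the series has been corrected.
#'
#' @param series a [titration_series()].
#' @return Numeric scalar, F0.
#' @export
f_zero <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  intensities(series)[series$quencher_conc == 0]
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series%s: %d points, T = %g K, lex/lem = %g/%g nm\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$quencher_conc), x$temperature, x$lambda_ex, x$lambda_em))
  cat(sprintf("  [Q] %g to %g mol/L, F0 = %g%s%s\n",
              min(x$quencher_conc), max(x$quencher_conc), f_zero(x),
              if (!is.null(x$a_ex)) ", absorbances attached" else "",
              if (!is.null(x$f_cor)) ", inner-filter corrected" else ""))
  invisible(x)
}

#' @export
as.data.frame.titration_series <- function(x, ...) {
  d <- data.frame(quencher_conc = x$quencher_conc, f_obs = x$f_obs)
  if (!is.null(x$a_ex)) d$a_ex <- x$a_ex
  if (!is.null(x$a_em)) d$a_em <- x$a_em
  if (!is.null(x$f_cor)) d$f_cor <- x$f_cor
  d
}

#' @export
length.titration_series <- function(x) length(x$quencher_conc)

conc_unit_factor <- function(unit) {
  switch(unit,
         "uM" = 1e-6, "nM" = 1e-9, "mM" = 1e-3, "M" = 1,
         stop("unknown concentration unit: ", unit))
}

parse_hash_metadata <- function(lines) {
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (!grepl(":", ln)) next
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    meta[[key]] <- val
  }
  meta
}

#' Read a titration series from CSV
#'
#' The CSV dialect has optional metadata header lines prefixed `#`
#' (`temperature_K`, `lambda_ex_nm`, `lambda_em_nm`, `label`), then a header
#' row `conc_uM,F[,A_ex,A_em][,temperature_K]`. Concentrations are converted
#' from the file unit (micromolar by default) to mol/L. Rows are sorted by
#' ascending concentration; exactly one row must have zero concentration.
#'
#' @param path path to the CSV file.
#' @param unit_config list; `conc` names the unit of the concentration column
#'   (one of `"uM"`, `"nM"`, `"mM"`, `"M"`; default `"uM"`).
#' @param temperature fallback temperature in K when the file carries none.
#' @return A [titration_series()].
#' @seealso [write_titration_csv()]
#' @export
read_titration_csv <- function(path, unit_config = list(conc = "uM"),
                               temperature = NULL) {
  lines <- readLines(path)
  meta <- parse_hash_metadata(lines)
  body <- lines[!grepl("^\\s*#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE)
  if (!all(c("conc_uM", "F") %in% names(tab)))
    stop("titration CSV must have columns conc_uM and F")
  fac <- conc_unit_factor(unit_config$conc %||% "uM")
  temp <- if (!is.null(tab$temperature_K)) unique(tab$temperature_K)
          else if (!is.null(meta$temperature_K)) as.numeric(meta$temperature_K)
          else temperature
  if (is.null(temp)) stop("temperature_K missing from file and arguments")
  if (length(temp) != 1) stop("temperature_K column is not constant")
  titration_series(
    quencher_conc = tab$conc_uM * fac,
    f_obs = tab$F,
    a_ex = tab$A_ex,
    a_em = tab$A_em,
    temperature = temp,
    lambda_ex = as.numeric(meta$lambda_ex_nm %||% 279),
    lambda_em = as.numeric(meta$lambda_em_nm %||% 341),
    label = meta$label %||% ""
  )
}

#' Write a titration series to CSV
#'
#' Writes the same dialect [read_titration_csv()] accepts, at full double
#' precision so read/write round-trips are numerically exact.
#'
#' @param series a [titration_series()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  num <- function(x) sprintf("%.17g", x)
  hdr <- c(
    sprintf("# temperature_K: %.17g", series$temperature),
    sprintf("# lambda_ex_nm: %g", series$lambda_ex),
    sprintf("# lambda_em_nm: %g", series$lambda_em),
    if (nzchar(series$label)) sprintf("# label: %s", series$label)
  )
  cols <- c("conc_uM", "F")
  rows <- cbind(num(series$quencher_conc / 1e-6), num(series$f_obs))
  if (!is.null(series$a_ex) && !is.null(series$a_em)) {
    cols <- c(cols, "A_ex", "A_em")
    rows <- cbind(rows, num(series$a_ex), num(series$a_em))
  }
  writeLines(c(hdr, paste(cols, collapse = ","),
               apply(rows, 1, paste, collapse = ",")), path)
  invisible(path)
}
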