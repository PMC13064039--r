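SPECTRUM_KINDS <- c("emission_nm", "synchronous_nm", "uv_nm", "ftir_wavenumber")

#' Construct a spectrum
#'
#' A spectrum is an (axis, intensity) pair on a strictly monotone grid, with
#' an axis kind that records what was scanned: an emission wavelength grid,
#' a synchronous-scan excitation grid, a UV-vis wavelength grid (all nm), or
#' an FTIR wavenumber grid (cm^-1). Spectra are stored in ascending axis
#' order.
#'
#' @param axis numeric grid, strictly monotone.
#' @param intensity numeric, same length as `axis`, non-negative.
#' @param axis_kind one of `"emission_nm"`, `"synchronous_nm"`, `"uv_nm"`,
#'   `"ftir_wavenumber"`.
#' @param meta list of metadata; `quencher_conc` (mol/L) or `label` are the
#'   common entries.
#' @return An object of class `band_spectrum`.
#' @seealso [locate_peak()], [peak_shift()]
#' @export
new_spectrum <- function(axis, intensity, axis_kind, meta = list()) {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  axis_kind <- match.arg(axis_kind, SPECTRUM_KINDS)
  if (length(axis) != length(intensity))
    stop("axis and intensity must have the same length")
  d <- diff(axis)
  if (length(axis) < 2 || !(all(d > 0) || all(d < 0)))
    stop("axis must be strictly monotone")
  if (any(intensity < 0)) stop("negative intensities are not allowed")
  if (d[1] < 0) {
    axis <- rev(axis)
    intensity <- rev(intensity)
  }
  structure(list(axis = axis, intensity = intensity, axis_kind = axis_kind,
                 meta = meta),
            class = "band_spectrum")
}

#' @export
print.band_spectrum <- function(x, ...) {
  cat(sprintf("Spectrum (%s): %d points, axis %g to %g%s\n",
              x$axis_kind, length(x$axis), min(x$axis), max(x$axis),
              if (!is.null(x$meta$quencher_conc))
                sprintf(", [Q] = %g mol/L", x$meta$quencher_conc) else ""))
  invisible(x)
}

#' Locate the maximum of a band within a window
#'
#' Finds the discrete maximum of the spectrum inside `window` and refines its
#' position by the vertex of a quadratic through the maximum and its two
#' neighbours; at a window edge the grid value itself is returned. Ties
#' between equal maxima break toward the lower axis value. A flat window
#' returns its leftmost point flagged `"flat region"`.
#'
#' @param spectrum a [new_spectrum()] object.
#' @param window numeric length-2, `(lo, hi)` in axis units; must contain at
#'   least three grid points.
#' @return An object of class `peak_result` with `position`, `height`,
#'   `window`, `flags`, `axis_kind` and the local `grid_step`.
#' @export
locate_peak <- function(spectrum, window) {
  stopifnot(inherits(spectrum, "band_spectrum"), length(window) == 2)
  lo <- min(window); hi <- max(window)
  idx <- which(spectrum$axis >= lo & spectrum$axis <= hi)
  if (length(idx) == 0)
    stop("window outside axis")
  if (length(idx) < 3)
    stop("window outside axis: fewer than 3 grid points in window")
  x <- spectrum$axis[idx]
  y <- spectrum$intensity[idx]
  flags <- character(0)

  if (diff(range(y)) == 0) {
    flags <- "flat region"
    pos <- x[1]
    h <- y[1]
  } else {
    i <- which.max(y) # ties resolve to the first = lowest axis value
    if (i == 1 || i == length(y)) {
      flags <- "window edge"
      pos <- x[i]
      h <- y[i]
    } else {
      xs <- x[(i - 1):(i + 1)]
      ys <- y[(i - 1):(i + 1)]
      p <- unname(solve(cbind(1, xs, xs^2), ys))
      if (p[3] == 0) { # degenerate (collinear) triple: keep the grid maximum
        pos <- x[i]
        h <- y[i]
      } else {
        pos <- -p[2] / (2 * p[3])
        h <- p[1] + p[2] * pos + p[3] * pos^2
      }
    }
  }
  structure(list(position = pos, height = h, window = c(lo, hi),
                 flags = flags, axis_kind = spectrum$axis_kind,
                 grid_step = stats::median(diff(x))),
            class = "peak_result")
}

#' @export
print.peak_result <- function(x, ...) {
  cat(sprintf("Peak at %.4g (height %.4g) in window [%g, %g] (%s)%s\n",
              x$position, x$height, x$window[1], x$window[2], x$axis_kind,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Signed shift between two peaks
#'
#' Computes `treated - reference` for two peaks located on the same axis
#' kind and labels its direction. On wavelength (nm) axes a positive shift
#' is a red shift and a negative one a blue shift; on the wavenumber axis
#' the labels invert, since lower wavenumber means lower energy. Shifts
#' smaller than the resolution threshold (default: half the grid step) are
#' labelled `"none"`.
#'
#' @param reference,treated `peak_result` objects from [locate_peak()].
#' @param threshold resolution threshold in axis units; default half the
#'   larger of the two grid steps.
#' @return A list with `shift`, `direction` (`"red"`, `"blue"`, `"none"`)
#'   and the threshold used.
#' @export
peak_shift <- function(reference, treated, threshold = NULL) {
  stopifnot(inherits(reference, "peak_result"), inherits(treated, "peak_result"))
  if (reference$axis_kind != treated$axis_kind)
    stop("incomparable spectra: axis kinds differ")
  if (is.null(threshold))
    threshold <- 0.5 * max(reference$grid_step, treated$grid_step)
  shift <- treated$position - reference$position
  direction <- if (abs(shift) < threshold) {
    "none"
  } else if (reference$axis_kind == "ftir_wavenumber") {
    if (shift < 0) "red" else "blue"
  } else {
    if (shift > 0) "red" else "blue"
  }
  list(shift = shift, direction = direction, threshold = threshold,
       axis_kind = reference$axis_kind)
}

#' Read spectra from CSV
#'
#' The dialect: metadata lines prefixed `#` (at least `axis_kind`), then a
#' header row whose first column is the axis and whose remaining columns are
#' one spectrum per titration point. Numeric column headers are read as
#' quencher concentrations in micromolar; other headers become labels.
#'
#' @param path path to the CSV file.
#' @return A list of [new_spectrum()] objects, in file column order.
#' @seealso [write_spectra_csv()]
#' @export
read_spectra_csv <- function(path) {
  lines <- readLines(path)
  meta <- parse_hash_metadata(lines)
  if (is.null(meta$axis_kind)) stop("spectra CSV lacks '# axis_kind:' header")
  body <- lines[!grepl("^\\s*#", lines)]
  tab <- utils::read.csv(text = paste(body, collapse = "\n"),
                         check.names = FALSE)
  axis <- tab[[1]]
  lapply(names(tab)[-1], function(nm) {
    conc <- suppressWarnings(as.numeric(nm))
    new_spectrum(axis, tab[[nm]], meta$axis_kind,
                 meta = if (is.na(conc)) list(label = nm)
                        else list(quencher_conc = conc * 1e-6))
  })
}

#' Write spectra to CSV
#'
#' Inverse of [read_spectra_csv()]; all spectra must share the same axis and
#' axis kind. Column headers are quencher concentrations in micromolar when
#' available, labels otherwise.
#'
#' @param spectra list of [new_spectrum()] objects on a common axis.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(length(spectra) >= 1)
  kind <- spectra[[1]]$axis_kind
  axis <- spectra[[1]]$axis
  for (s in spectra) {
    if (s$axis_kind != kind || !identical(s$axis, axis))
      stop("all spectra must share one axis and axis kind")
  }
  hdr <- vapply(spectra, function(s) {
    if (!is.null(s$meta$quencher_conc)) sprintf("%.17g", s$meta$quencher_conc / 1e-6)
    else s$meta$label %||% "spectrum"
  }, "")
  mat <- vapply(spectra, function(s) s$intensity, numeric(length(axis)))
  out <- cbind(sprintf("%.17g", axis),
               apply(mat, 2, function(col) sprintf("%.17g", col)))
  writeLines(c(sprintf("# axis_kind: %s", kind),
               paste(c("axis", hdr), collapse = ","),
               apply(out, 1, paste, collapse = ",")), path)
  invisible(path)
}
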