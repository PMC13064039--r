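load_corrected_series <- function(path, pass_through = FALSE) {
  s <- read_titration_csv(path)
  has_abs <- !is.null(s$a_ex) && !is.null(s$a_em) &&
    !anyNA(s$a_ex) && !anyNA(s$a_em)
  if (has_abs) correct_series(s)
  else correct_series(s, pass_through = TRUE)
}

sv_fit_row <- function(f) {
  list(temperature = f$temperature, ksv = f$ksv, kq = f$kq,
       r_squared = f$r_squared, slope_se = f$slope_se,
       intercept = f$intercept, n_points = f$n_points)
}

binding_fit_row <- function(f) {
  list(temperature = f$temperature, log_kb = f$log_kb, kb = f$kb,
       n_sites = f$n_sites, r_squared = f$r_squared, slope_se = f$slope_se,
       n_points_used = f$n_points_used,
       excluded = if (nrow(f$excluded)) f$excluded else NULL)
}

# display-rounded string in the style of a results table (3 significant digits)
display <- function(x) formatC(x, digits = 3, format = "fg", flag = "#")

#' Run the full study report
#'
#' Orchestrates the whole pipeline over a YAML configuration listing input
#' CSV files per analysis block, and emits a structured report mirroring a
#' complete binding study: a Stern-Volmer quenching table with the
#' mechanism call, a binding table with stoichiometry and affinity, the
#' van't Hoff thermodynamic block, spectral-modality findings, the
#' site-marker call and the metal-ion modulation table. Blocks absent from
#' the configuration are skipped with a warning recorded in the report;
#' a block whose inputs fail is recorded as failed and the run continues.
#'
#' Config schema (all blocks optional, at least one required):
#' \preformatted{
#' quenching:                    # also feeds binding/thermo if they list no series
#'   series: [t303.csv, t310.csv, t318.csv]
#'   tau0: 1.0e-8
#'   kq_limit: 2.0e10
#' binding:
#'   series: [t303.csv, t310.csv, t318.csv]
#' modality:
#'   sync60: s60.csv
#'   sync15: s15.csv
#'   ftir_free: free.csv
#'   ftir_complex: complex.csv
#'   uv: uv.csv
#'   protein_conc_M: 2.0e-6
#'   path_cm: 1
#' sites:
#'   blank: blank.csv
#'   probes:
#'     - {condition: phenylbutazone, role: site_I_probe, path: pbz.csv}
#'     - {condition: diazepam, role: site_II_probe, path: dzp.csv}
#' metals:
#'   blank: blank.csv
#'   ions:
#'     - {condition: Na+, path: na.csv}
#' }
#' Relative paths resolve against the config file's directory.
#'
#' @param config_path path to the YAML configuration.
#' @param out_path optional path for the JSON report.
#' @param summary_path optional path for a human-readable markdown summary
#'   assembling the study's conclusion sentences from the classification
#'   outputs.
#' @return The report (class `study_report`), invisibly when written to
#'   file. Apart from the timestamp the report is a deterministic function
#'   of its inputs.
#' @export
run_report <- function(config_path, out_path = NULL, summary_path = NULL) {
  cfg <- yaml::read_yaml(config_path)
  known <- c("quenching", "binding", "modality", "sites", "metals")
  if (length(cfg) == 0 || !any(known %in% names(cfg)))
    stop("empty config: no analysis blocks found")
  root <- dirname(normalizePath(config_path))
  resolve <- function(p) if (file.exists(p)) p else file.path(root, p)

  st <- new.env(parent = emptyenv()) # mutable block-to-block state
  st$warnings <- character(0)
  st$inputs <- character(0)
  st$sv_fits <- NULL
  st$bind_fits <- NULL
  note <- function(msg) {
    st$warnings <- c(st$warnings, msg)
    message(msg)
  }
  track <- function(paths) {
    st$inputs <- c(st$inputs, paths)
    paths
  }
  run_block <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      note(sprintf("[%s] %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      note(sprintf("[%s] failed: %s", name, conditionMessage(e)))
      NULL
    })
  }

  report <- list(schema_version = "1.0",
                 software = list(package = "quenchbind",
                                 version = as.character(utils::packageVersion("quenchbind"))),
                 generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  # -- quenching ---------------------------------------------------------
  if (!is.null(cfg$quenching)) {
    report$quenching <- run_block("quenching", {
      paths <- track(vapply(cfg$quenching$series, resolve, ""))
      series <- lapply(paths, load_corrected_series)
      tau0 <- cfg$quenching$tau0 %||% 1e-8
      fits <- lapply(series, fit_stern_volmer, tau0 = tau0)
      st$sv_fits <- fits
      mech <- if (length(fits) >= 1)
        classify_mechanism(fits, kq_limit = cfg$quenching$kq_limit %||% 2e10)
      list(tau0 = tau0, fits = lapply(fits, sv_fit_row),
           mechanism = if (!is.null(mech))
             list(mechanism = mech$mechanism, ksv_trend = mech$ksv_trend,
                  kq_exceeds_limit = mech$kq_exceeds_limit, limit = mech$limit))
    })
  } else note("[quenching] block missing: skipped")

  # -- binding + thermodynamics -----------------------------------------
  bind_cfg <- cfg$binding %||% (if (!is.null(cfg$quenching))
    list(series = cfg$quenching$series))
  if (!is.null(bind_cfg)) {
    report$binding <- run_block("binding", {
      paths <- track(vapply(bind_cfg$series, resolve, ""))
      fits <- lapply(lapply(paths, load_corrected_series), fit_double_log)
      st$bind_fits <- fits
      rows <- lapply(fits, binding_fit_row)
      stoich <- interpret_stoichiometry(fits[[length(fits)]])
      list(fits = rows,
           stoichiometry = stoich$stoichiometry, affinity = stoich$affinity)
    })
    if (!is.null(st$bind_fits) && length(st$bind_fits) >= 2) {
      report$thermo <- run_block("thermo", {
        th <- thermo_pipeline(st$bind_fits)
        list(delta_h = th$delta_h, delta_s = th$delta_s,
             delta_g_by_T = as.list(th$delta_g_by_T),
             r_squared = th$r_squared, force_class = th$force_class,
             endothermic = th$endothermic,
             spontaneous_at = th$spontaneous_at)
      })
    } else if (!is.null(st$bind_fits)) {
      note("[thermo] needs binding fits at >= 2 temperatures: skipped")
    }
  } else note("[binding] block missing: skipped")

  # -- modality ----------------------------------------------------------
  if (!is.null(cfg$modality)) {
    report$modality <- run_block("modality", {
      m <- cfg$modality
      out <- list()
      read_sync <- function(path, dl) {
        spectra <- read_spectra_csv(track(resolve(path)))
        concs <- vapply(spectra, function(s) s$meta$quencher_conc %||% NA_real_, 0)
        synchronous_series(dl, spectra, concs)
      }
      if (!is.null(m$sync60)) {
        r <- synchronous_shift(read_sync(m$sync60, 60))
        out$sync60 <- list(residue = r$residue, shift = r$shift,
                           direction = r$direction,
                           interpretation = r$interpretation)
      }
      if (!is.null(m$sync15)) {
        r <- synchronous_shift(read_sync(m$sync15, 15))
        out$sync15 <- list(residue = r$residue, shift = r$shift,
                           direction = r$direction,
                           interpretation = r$interpretation)
      }
      if (!is.null(m$ftir_free) && !is.null(m$ftir_complex)) {
        free <- read_spectra_csv(track(resolve(m$ftir_free)))[[1]]
        cplx <- read_spectra_csv(track(resolve(m$ftir_complex)))[[1]]
        ab <- amide_band_shift(free, cplx)
        out$ftir <- lapply(ab, function(r)
          list(band = r$residue, shift = r$shift, direction = r$direction,
               interpretation = r$interpretation))
      }
      if (!is.null(m$uv)) {
        uvs <- read_spectra_csv(track(resolve(m$uv)))
        feats <- uv_titration_features(uvs,
                                       protein_conc = m$protein_conc_M %||% 2e-6,
                                       path_cm = m$path_cm %||% 1)
        out$uv <- list(epsilon = feats$epsilon,
                       band220 = feats$band220_trend,
                       changes_present = feats$changes_present)
        if (!is.null(st$sv_fits)) {
          mech <- classify_mechanism(st$sv_fits)
          out$uv$corroboration <- corroborate_mechanism(feats, mech)$call
        }
      }
      if (length(out) == 0) stop("modality block lists no inputs")
      out
    })
  } else note("[modality] block missing: skipped")

  # -- competition -------------------------------------------------------
  fit_condition <- function(path, condition, role) {
    condition_fit(condition, role,
                  fit_double_log(load_corrected_series(resolve(path))))
  }
  if (!is.null(cfg$sites)) {
    report$sites <- run_block("sites", {
      track(resolve(cfg$sites$blank))
      fits <- c(list(fit_condition(cfg$sites$blank, "blank", "blank")),
                lapply(cfg$sites$probes, function(p) {
                  track(resolve(p$path))
                  fit_condition(p$path, p$condition, p$role)
                }))
      sc <- assign_site(fits)
      list(assigned_site = sc$assigned_site,
           delta_log_kb = as.list(sc$delta_log_kb_by_condition),
           threshold = sc$threshold)
    })
  } else note("[sites] block missing: skipped")

  if (!is.null(cfg$metals)) {
    report$metals <- run_block("metals", {
      track(resolve(cfg$metals$blank))
      fits <- c(list(fit_condition(cfg$metals$blank, "blank", "blank")),
                lapply(cfg$metals$ions, function(p) {
                  track(resolve(p$path))
                  fit_condition(p$path, p$condition, "metal")
                }))
      mm <- metal_modulation(fits)
      list(threshold = mm$threshold,
           ions = lapply(seq_len(nrow(mm$table)), function(i)
             as.list(mm$table[i, ])))
    })
  } else note("[metals] block missing: skipped")

  inputs <- unique(st$inputs)
  report$provenance <- list(
    config = normalizePath(config_path),
    inputs = stats::setNames(as.list(unname(tools::md5sum(inputs))),
                             basename(inputs)))
  report$warnings <- st$warnings
  class(report) <- "study_report"

  if (!is.null(out_path))
    jsonlite::write_json(unclass(report), out_path, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  if (!is.null(summary_path))
    writeLines(report_summary_lines(report), summary_path)
  if (is.null(out_path)) report else invisible(report)
}

report_summary_lines <- function(report) {
  lines <- c("# Binding study summary", "")
  if (!is.null(report$quenching$mechanism))
    lines <- c(lines, sprintf(
      "- Fluorescence quenching follows a %s mechanism (K_SV trend %s; K_q %s the diffusion limit %.2g L/mol/s).",
      report$quenching$mechanism$mechanism,
      report$quenching$mechanism$ksv_trend,
      if (isTRUE(report$quenching$mechanism$kq_exceeds_limit)) "exceeds" else "is within",
      report$quenching$mechanism$limit))
  if (!is.null(report$binding))
    lines <- c(lines, sprintf(
      "- Binding stoichiometry %s with %s affinity (log10 Kb = %s at the highest temperature).",
      report$binding$stoichiometry, report$binding$affinity,
      display(report$binding$fits[[length(report$binding$fits)]]$log_kb)))
  if (!is.null(report$thermo))
    lines <- c(lines, sprintf(
      "- Thermodynamics: dH = %s kJ/mol (%s), dS = %s kJ/mol/K; binding is %s and dominated by %s forces.",
      display(report$thermo$delta_h),
      if (isTRUE(report$thermo$endothermic)) "endothermic" else "exothermic",
      display(report$thermo$delta_s),
      if (length(report$thermo$spontaneous_at)) "spontaneous (dG < 0)" else "non-spontaneous",
      report$thermo$force_class))
  if (!is.null(report$sites))
    lines <- c(lines, sprintf("- Site-marker competition assigns the ligand to %s.",
                              report$sites$assigned_site))
  if (!is.null(report$metals)) {
    for (ion in report$metals$ions)
      lines <- c(lines, sprintf("- %s: binding %s (ratio %s).",
                                ion$condition, ion$label, display(ion$ratio)))
  }
  if (length(report$warnings))
    lines <- c(lines, "", "## Warnings", paste("-", report$warnings))
  lines
}

#' @export
print.study_report <- function(x, ...) {
  writeLines(report_summary_lines(x))
  invisible(x)
}
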