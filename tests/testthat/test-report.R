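write_study_inputs <- function(dir) {
  cfg <- synthetic_config(mode = "double_log", n_sites = 1,
                          delta_h = 133.024, delta_s = 0.487)
  bundle <- generate_spectra(cfg, band_params = list(sync60 = list(drift_nm = 2)))
  series_paths <- vapply(names(bundle$series_by_T), function(tt) {
    p <- file.path(dir, sprintf("titration_%s.csv", tt))
    write_titration_csv(bundle$series_by_T[[tt]], p)
    p
  }, "")

  # quenching needs a shared-K_SV ladder that decreases with temperature
  sv_paths <- vapply(seq_along(c(1.07e4, 0.82e4, 0.48e4)), function(i) {
    ksv <- c(1.07e4, 0.82e4, 0.48e4)[i]
    tt <- c(303, 310, 318)[i]
    p <- file.path(dir, sprintf("quench_%d.csv", tt))
    write_titration_csv(sv_series(ksv = ksv, temperature = tt), p)
    p
  }, "")

  write_spectra_csv(bundle$spectra$sync60$spectra, file.path(dir, "sync60.csv"))
  write_spectra_csv(bundle$spectra$sync15$spectra, file.path(dir, "sync15.csv"))
  write_spectra_csv(list(bundle$spectra$ftir_free), file.path(dir, "ftir_free.csv"))
  write_spectra_csv(list(bundle$spectra$ftir_complex),
                    file.path(dir, "ftir_complex.csv"))
  write_spectra_csv(bundle$spectra$uv, file.path(dir, "uv.csv"))

  probes <- list(blank = 350, phenylbutazone = 10^1.91, diazepam = 10^2.50,
                 na = 10^2.27, ca = 10^4.15, fe = 10^2.58)
  for (nm in names(probes)) {
    b <- generate_titration(synthetic_config(mode = "double_log",
                                             kb = probes[[nm]], n_sites = 1,
                                             temperatures = 303))
    write_titration_csv(b$series_by_T[[1]], file.path(dir, paste0(nm, ".csv")))
  }

  yaml::write_yaml(list(
    quenching = list(series = as.list(basename(sv_paths))),
    binding = list(series = as.list(basename(series_paths))),
    modality = list(sync60 = "sync60.csv", sync15 = "sync15.csv",
                    ftir_free = "ftir_free.csv",
                    ftir_complex = "ftir_complex.csv",
                    uv = "uv.csv", protein_conc_M = 2e-6, path_cm = 1),
    sites = list(blank = "blank.csv", probes = list(
      list(condition = "phenylbutazone", role = "site_I_probe",
           path = "phenylbutazone.csv"),
      list(condition = "diazepam", role = "site_II_probe",
           path = "diazepam.csv"))),
    metals = list(blank = "blank.csv", ions = list(
      list(condition = "Na+", path = "na.csv"),
      list(condition = "Ca2+", path = "ca.csv"),
      list(condition = "Fe3+", path = "fe.csv")))
  ), file.path(dir, "study.yaml"))
  file.path(dir, "study.yaml")
}

test_that("full study report assembles every analysis block", {
  dir <- withr::local_tempdir()
  cfg_path <- write_study_inputs(dir)
  out <- file.path(dir, "report.json")
  summary_md <- file.path(dir, "report.md")
  suppressMessages(
    report <- run_report(cfg_path, out_path = out, summary_path = summary_md))

  expect_equal(report$quenching$mechanism$mechanism, "static")
  expect_equal(report$binding$stoichiometry, "1:1")
  expect_equal(report$thermo$force_class, "hydrophobic")
  expect_true(report$thermo$endothermic)
  expect_equal(report$thermo$spontaneous_at, c(303, 310, 318))
  expect_equal(report$modality$sync60$direction, "red")
  expect_equal(report$modality$ftir$amideI$interpretation,
               "secondary-structure change")
  expect_equal(report$modality$uv$corroboration, "consistent")
  expect_equal(report$sites$assigned_site, "site_I")
  labels <- vapply(report$metals$ions, function(x) x$label, "")
  names(labels) <- vapply(report$metals$ions, function(x) x$condition, "")
  expect_equal(labels[["Na+"]], "reduced")
  expect_equal(labels[["Ca2+"]], "enhanced")
  expect_equal(labels[["Fe3+"]], "unchanged")

  # report assembly passes numbers through unchanged
  expect_equal(report$quenching$fits[[1]]$ksv,
               fit_stern_volmer(read_titration_csv(
                 file.path(dir, "quench_303.csv")))$ksv)

  expect_true(file.exists(out))
  md <- readLines(summary_md)
  expect_true(any(grepl("static", md)))
  expect_true(any(grepl("hydrophobic", md)))
})

test_that("partial configs run with warnings; empty configs are refused", {
  dir <- withr::local_tempdir()
  write_titration_csv(sv_series(), file.path(dir, "only.csv"))
  yaml::write_yaml(list(quenching = list(series = list("only.csv"))),
                   file.path(dir, "q.yaml"))
  suppressMessages(rep <- run_report(file.path(dir, "q.yaml")))
  expect_false(is.null(rep$quenching))
  expect_null(rep$modality)
  expect_true(any(grepl("modality", rep$warnings)))

  yaml::write_yaml(list(), file.path(dir, "empty.yaml"))
  expect_error(suppressMessages(run_report(file.path(dir, "empty.yaml"))),
               "empty config")
})

test_that("identical inputs produce byte-identical JSON apart from the timestamp", {
  dir <- withr::local_tempdir()
  cfg_path <- write_study_inputs(dir)
  o1 <- file.path(dir, "r1.json")
  o2 <- file.path(dir, "r2.json")
  suppressMessages(run_report(cfg_path, out_path = o1))
  suppressMessages(run_report(cfg_path, out_path = o2))
  strip <- function(p) grep("\"generated\"", readLines(p), invert = TRUE,
                            value = TRUE)
  expect_identical(strip(o1), strip(o2))
})
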