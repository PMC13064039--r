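test_that("configuration validation catches inconsistent setups", {
  expect_error(synthetic_config(quencher_grid = c(1e-5, 2e-5)),
               "must include 0")
  expect_error(synthetic_config(noise_rel_sigma = 0.5), "noise_rel_sigma")
  expect_error(synthetic_config(mode = "double_log"), "inconsistent config")
  expect_error(synthetic_config(mode = "double_log", kb = 350,
                                delta_h = 100, delta_s = 0.4),
               "not both")
  expect_error(synthetic_config(mode = "stern_volmer", kb = 350),
               "inconsistent config")
  expect_error(synthetic_config(mode = "double_log", delta_h = 100),
               "together")
})

test_that("generation is bit-identical under a fixed seed", {
  cfg <- synthetic_config(ksv = 1.07e4, noise_rel_sigma = 0.02, seed = 99L)
  b1 <- generate_titration(cfg)
  b2 <- generate_titration(cfg)
  expect_identical(b1, b2)
  b3 <- generate_titration(synthetic_config(ksv = 1.07e4,
                                            noise_rel_sigma = 0.02, seed = 100L))
  expect_false(identical(b1$series_by_T, b3$series_by_T))
  # truth records the generating parameters
  expect_equal(b1$truth$ksv, 1.07e4)
  expect_equal(b1$truth$seed, 99L)
})

test_that("generator and RNG leave the caller's random stream untouched", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generate_titration(synthetic_config(noise_rel_sigma = 0.01)))
  expect_identical(runif(3), before)
})

test_that("each generator is the exact inverse of its paired analysis", {
  # Stern-Volmer pair
  sv <- generate_titration(synthetic_config(ksv = 1.07e4, temperatures = 303))
  expect_lt(abs(fit_stern_volmer(sv$series_by_T[[1]])$ksv - 1.07e4) / 1.07e4,
            1e-10)

  # double-log pair
  dl <- generate_titration(synthetic_config(mode = "double_log", kb = 8.85e3,
                                            n_sites = 1.06, temperatures = 318))
  fit <- fit_double_log(dl$series_by_T[[1]])
  expect_lt(abs(fit$kb - 8.85e3) / 8.85e3, 1e-8)
  expect_lt(abs(fit$n_sites - 1.06) / 1.06, 1e-8)

  # van't Hoff ladder pair
  vh <- generate_titration(synthetic_config(mode = "double_log", n_sites = 1,
                                            delta_h = 133.024, delta_s = 0.487))
  fits <- lapply(vh$series_by_T, fit_double_log)
  th <- thermo_pipeline(fits)
  expect_lt(abs(th$delta_h - 133.024) / 133.024, 1e-8)
  expect_lt(abs(th$delta_s - 0.487) / 0.487, 1e-8)

  # inner-filter distortion pair: correction restores the model exactly
  ife <- generate_titration(synthetic_config(
    ksv = 1.07e4, temperatures = 303,
    ife = list(epsilon_ligand_ex = 3400, a_protein_ex = 0.08, a_em = 0)))
  s <- ife$series_by_T[[1]]
  q <- s$quencher_conc
  expect_true(all(s$f_obs[q > 0] < (1000 / (1 + 1.07e4 * q))[q > 0]))
  expect_equal(max(s$a_ex), 0.42, tolerance = 1e-12) # 0.08 + 3400 * 1e-4
  corrected <- correct_series(s)
  expect_equal(corrected$f_cor, 1000 / (1 + 1.07e4 * q), tolerance = 1e-12)
  expect_lt(abs(fit_stern_volmer(corrected)$ksv - 1.07e4) / 1.07e4, 1e-10)
})

test_that("seeded replicate spread of log Kb is modest at 1% noise", {
  # well-conditioned regime: quenched fractions stay far above the noise
  # floor at every titration point, so the double-log intercept is stable
  ests <- vapply(1:200, function(i) {
    b <- generate_titration(synthetic_config(
      mode = "double_log", kb = 5e4, n_sites = 1, temperatures = 303,
      noise_rel_sigma = 0.01, seed = 20000 + i))
    fit_double_log(b$series_by_T[[1]])$log_kb
  }, 0)
  expect_lt(sd(ests), 0.1)

  # weak binding leaves the intercept noise-amplified: spread grows as the
  # smallest quenched fraction approaches the noise level
  weak <- vapply(1:50, function(i) {
    b <- generate_titration(synthetic_config(
      mode = "double_log", kb = 8.85e3, n_sites = 1, temperatures = 303,
      noise_rel_sigma = 0.01, seed = 40000 + i))
    fit_double_log(b$series_by_T[[1]])$log_kb
  }, 0)
  expect_gt(sd(weak), sd(ests))
})

test_that("synthetic spectra reproduce programmed band features", {
  cfg <- synthetic_config(ksv = 1.07e4, temperatures = 303)
  b <- generate_spectra(cfg, band_params = list(sync60 = list(drift_nm = 2)))

  # emission band stays at 341 nm at every titration point
  for (s in b$spectra$emission)
    expect_equal(locate_peak(s, c(300, 400))$position, 341, tolerance = 1e-6)
  # peak heights follow the quenching attenuation
  h <- vapply(b$spectra$emission, function(s) max(s$intensity), 0)
  q <- cfg$quencher_grid
  expect_equal(h / h[1], 1 / (1 + 1.07e4 * q), tolerance = 1e-9)

  r60 <- synchronous_shift(b$spectra$sync60)
  expect_equal(r60$shift, 2, tolerance = 0.05)
  expect_equal(r60$direction, "red")
  r15 <- synchronous_shift(b$spectra$sync15, window = c(280, 320))
  expect_equal(r15$direction, "none")

  ab <- amide_band_shift(b$spectra$ftir_free, b$spectra$ftir_complex)
  expect_equal(ab$amideI$shift, -4, tolerance = 0.1)

  expect_error(generate_spectra(cfg, band_params = list(ftir = list(width = -1))),
               "invalid band")
})
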