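make_sync <- function(delta_lambda, drift, concs = seq(0, 1e-4, 2.5e-5),
                      center = 285, grid = seq(250, 330, 0.5)) {
  spectra <- lapply(seq_along(concs), function(i)
    gauss_spectrum(center + drift * (concs[i] / max(concs)), width = 10,
                   grid = grid, height = 1000 / (1 + 1e4 * concs[i]),
                   kind = "synchronous_nm",
                   meta = list(quencher_conc = concs[i])))
  synchronous_series(delta_lambda, spectra, concs)
}

test_that("synchronous shifts report residue, sign and interpretation", {
  trp <- synchronous_shift(make_sync(60, drift = 2))
  expect_equal(trp$residue, "Trp")
  expect_equal(trp$shift, 2, tolerance = 0.05)
  expect_equal(trp$direction, "red")
  expect_match(trp$interpretation, "microenvironment change near Trp")

  tyr <- synchronous_shift(make_sync(15, drift = 0, center = 300))
  expect_equal(tyr$residue, "Tyr")
  expect_equal(tyr$shift, 0, tolerance = 1e-6)
  expect_equal(tyr$direction, "none")
  expect_match(tyr$interpretation, "no detectable")

  blue <- synchronous_shift(make_sync(60, drift = -3))
  expect_equal(blue$direction, "blue")
})

test_that("programmed drift is recovered within one grid step", {
  for (d in c(-4, -1, 1, 2.5, 5)) {
    r <- synchronous_shift(make_sync(60, drift = d))
    expect_lt(abs(r$shift - d), 0.5)
  }
})

ftir_pair <- function(a1_free = 1646, a1_cplx = 1642, grid = seq(1450, 1750, 1)) {
  mk <- function(c1) new_spectrum(
    grid, exp(-(grid - c1)^2 / (2 * 16^2)) + 0.75 * exp(-(grid - 1548)^2 / (2 * 16^2)),
    "ftir_wavenumber")
  list(free = mk(a1_free), cplx = mk(a1_cplx))
}

test_that("amide band shifts detect secondary-structure change", {
  p <- ftir_pair()
  rep <- amide_band_shift(p$free, p$cplx)
  expect_equal(rep$amideI$shift, -4, tolerance = 0.1)
  expect_match(rep$amideI$interpretation, "secondary-structure change")
  expect_equal(rep$amideII$direction, "none")

  same <- amide_band_shift(p$free, p$free)
  expect_equal(same$amideI$shift, 0, tolerance = 1e-9)
  expect_match(same$amideI$interpretation, "no detectable")

  # antisymmetry under swapping free and complexed
  swapped <- amide_band_shift(p$cplx, p$free)
  expect_equal(swapped$amideI$shift, -rep$amideI$shift, tolerance = 1e-9)

  trunc <- new_spectrum(seq(1450, 1650, 1), rep(1, 201), "ftir_wavenumber")
  expect_error(amide_band_shift(trunc, trunc), "band window not covered")
})

make_uv <- function(concs = seq(0, 1e-4, 2.5e-5), drift220 = 0,
                    gain220 = 3000, gain280 = 320, base280 = 0.08) {
  grid <- seq(190, 350, 1)
  qmax <- max(concs, 1e-12)
  lapply(seq_along(concs), function(i) {
    q <- concs[i]
    y <- (0.6 + gain220 * q) * exp(-(grid - (220 + drift220 * q / qmax))^2 / (2 * 9^2)) +
      (base280 + gain280 * q) * exp(-(grid - 279)^2 / (2 * 16^2))
    new_spectrum(grid, y, "uv_nm", meta = list(quencher_conc = q))
  })
}

test_that("UV features: molar absorptivity and 220 nm band trends", {
  # single spectrum with A(279) = 0.112 at 2 uM protein, 1 cm path
  s <- make_uv(concs = 0, gain220 = 0, base280 = 0.112)
  feats <- uv_titration_features(s, protein_conc = 2e-6, path_cm = 1)
  expect_equal(feats$epsilon, 56000, tolerance = 1e-3)

  zero <- uv_titration_features(
    list(new_spectrum(seq(190, 350, 1), rep(0, 161), "uv_nm")),
    protein_conc = 2e-6)
  expect_equal(zero$epsilon, 0)

  # rising intensity + red drift of the 220 nm band across a titration
  feats2 <- uv_titration_features(make_uv(drift220 = 2), protein_conc = 2e-6)
  expect_equal(feats2$band220_trend$position_trend, "red shift")
  expect_equal(feats2$band220_trend$intensity_trend, "increasing")
  expect_true(feats2$changes_present)

  expect_error(uv_titration_features(make_uv(), protein_conc = 0),
               "invalid Beer-Lambert input")
})

test_that("epsilon obeys Beer-Lambert scaling", {
  s <- make_uv(concs = 0, gain220 = 0, base280 = 0.2)
  e1 <- uv_titration_features(s, protein_conc = 2e-6)$epsilon
  # doubling the absorbance doubles epsilon
  s2 <- make_uv(concs = 0, gain220 = 0, base280 = 0.4)
  expect_equal(uv_titration_features(s2, protein_conc = 2e-6)$epsilon, 2 * e1,
               tolerance = 1e-9)
  # doubling the concentration halves it
  expect_equal(uv_titration_features(s, protein_conc = 4e-6)$epsilon, e1 / 2,
               tolerance = 1e-9)
})

test_that("UV evidence corroborates the mechanism call by rule", {
  changing <- uv_titration_features(make_uv(), protein_conc = 2e-6)
  still <- uv_titration_features(make_uv(gain220 = 0, gain280 = 0, drift220 = 0),
                                 protein_conc = 2e-6)
  expect_equal(corroborate_mechanism(changing, "static")$call, "consistent")
  expect_equal(corroborate_mechanism(changing, "dynamic")$call, "inconsistent")
  expect_equal(corroborate_mechanism(still, "dynamic")$call, "consistent")
  expect_equal(corroborate_mechanism(still, "static")$call, "ambiguous")
})
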