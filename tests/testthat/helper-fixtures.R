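# shared fixtures built in code

# noise-free Stern-Volmer titration on the standard 0-100 uM grid
sv_series <- function(ksv = 1.07e4, f0 = 1000, temperature = 303,
                      q = seq(0, 100e-6, by = 10e-6)) {
  titration_series(q, f0 / (1 + ksv * q), temperature = temperature)
}

# noise-free double-log titration: (F0 - F)/F = kb * [Q]^n
dl_series <- function(kb = 350, n = 1, f0 = 1000, temperature = 303,
                      q = seq(0, 100e-6, by = 10e-6)) {
  titration_series(q, f0 / (1 + kb * q^n), temperature = temperature)
}

# kb ladder generated from the van't Hoff relation (dh kJ/mol, ds kJ/mol/K)
vant_hoff_kb <- function(dh, ds, temps) {
  exp(-dh * 1000 / (8.314 * temps) + ds * 1000 / 8.314)
}

# Gaussian band spectrum on a regular grid
gauss_spectrum <- function(center, width = 10, grid = seq(250, 450, by = 1),
                           height = 1, kind = "emission_nm", meta = list()) {
  new_spectrum(grid, height * exp(-(grid - center)^2 / (2 * width^2)),
               kind, meta = meta)
}

# closed-form OLS slope, independent of lm
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

write_tmp_titration <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
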