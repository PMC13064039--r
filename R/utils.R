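# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# gas constant, J mol^-1 K^-1
R_GAS <- 8.314

# working intensities of a series: inner-filter-corrected when available
intensities <- function(series) series$f_cor %||% series$f_obs
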