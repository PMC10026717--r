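# in-code fixtures shared across test files

# minimal capture tibble with sensible defaults for unspecified columns
fish_tbl <- function(TL, W = NA_real_, age = NA_real_,
                     gear = "electrofishing", tract = "TOR2",
                     transect_id = NA_character_, recapture_of = NA_character_,
                     id = NULL, year = 2020L, W_imputed = FALSE) {
  n <- length(TL)
  if (is.null(id)) id <- sprintf("f%03d", seq_len(n))
  tibble::tibble(
    id = id,
    year = rep_len(year, n), tract = rep_len(tract, n),
    gear = rep_len(gear, n), TL = TL,
    W = rep_len(W, n), age = rep_len(age, n),
    transect_id = rep_len(transect_id, n),
    recapture_of = rep_len(recapture_of, n),
    W_imputed = rep_len(W_imputed, n)
  )
}

# noiseless population on exact Gompertz + allometric curves
noiseless_config <- function(n = 80, seed = 11) {
  synthetic_config(
    n = n, seed = seed,
    growth = list(TL_inf = 105.0, G = 0.216, t0 = 3.99, sigma_TL = 0),
    allometry = list(a = 10^-2.100, b = 3.055, sigma_logW = 0),
    missing_mass_frac = 0
  )
}

gompertz_mean <- function(t, TL_inf = 105.0, G = 0.216, t0 = 3.99) {
  TL_inf * exp(-exp(-G * (t - t0)))
}
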