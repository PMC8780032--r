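# Small designs and toy objects shared across tests.

tiny_design <- function(n_fruit = 6, noise_sd = 0, seed = 7L, ...) {
  simulation_design(n_fruit = n_fruit, noise_sd = noise_sd, seed = seed, ...)
}

toy_fruit <- function(ssc = 13, amps = rep(0.5, 12), skin = 0.02) {
  phantom_fruit("toy", ssc_stem = ssc, ssc_blossom = ssc,
                wet_weight = 10, dry_weight = 1.5,
                band_amplitudes = amps, skin_scatter = skin)
}

# Simulated population run through absorbance -> SNV -> SNV+2D.
simulated_snv2d <- function(n_fruit = 30, seed = 11L, ...) {
  pop <- simulate_population(simulation_design(n_fruit = n_fruit,
                                               seed = seed, ...))
  ab <- to_absorbance_set(pop$spectra, pop$references)
  list(pop = pop, absorbance = ab, snv2d = run_plan(ab, preprocess_plan()))
}

# Independent brute-force extremum oracle: wavelengths where a value beats
# both neighbours.
local_extrema_wl <- function(v, wl) {
  i <- 2:(length(v) - 1)
  hit <- (v[i] > v[i - 1] & v[i] > v[i + 1]) |
    (v[i] < v[i - 1] & v[i] < v[i + 1])
  wl[i][hit]
}

# Wide-format helper: aquagram profiles to band x group matrix.
profiles_wide <- function(profiles) {
  w <- stats::reshape(as.data.frame(profiles), direction = "wide",
                      idvar = "band_id", timevar = "group")
  names(w) <- sub("^value\\.", "", names(w))
  w[order(match(w$band_id, paste0("C", 1:12))), , drop = FALSE]
}
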