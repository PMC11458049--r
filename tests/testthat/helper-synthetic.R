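# shared helpers: small synthetic spectra built in code

# a random multi-band spectrum on the default grid, reproducible by seed
rand_band_spectrum <- function(seed, grid = default_grid()) {
  set.seed(seed)
  nb <- sample(2:4, 1)
  m <- band_model(centers = runif(nb, 215, 280),
                  sigmas = runif(nb, 3, 12),
                  peaks = runif(nb, 0.02, 0.1),
                  label = paste0("rand", seed))
  spectrum(grid, profile_absorbance(m, grid), label = m$label)
}

# canonical 25-run training concentration table (hyx, eph, thp in ug/mL)
canonical_training_runs <- function() {
  data.frame(
    hyx = c(6, 8, 10, 8, 6, 10, 10, 2, 8, 2, 6, 8, 8, 4, 2, 4, 6, 2, 2, 10, 4, 10, 6, 4, 4),
    eph = c(9, 15, 12, 9, 15, 15, 3, 12, 3, 9, 12, 12, 6, 3, 6, 9, 3, 3, 15, 6, 15, 9, 6, 6, 12),
    thp = c(10, 14, 10, 18, 18, 2, 14, 2, 10, 14, 14, 6, 2, 6, 10, 2, 2, 18, 6, 18, 10, 6, 6, 14, 18)
  )
}

# three independent synthetic component spectra restricted to the working
# window, as a rank-3 Beer-Lambert data generator for the multivariate tests
noiseless_window_dataset <- function(runs = canonical_training_runs()) {
  simulate_dataset(runs, default_profiles(), sim_config(noise_sd = 0),
                   window = c(210, 230))
}
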