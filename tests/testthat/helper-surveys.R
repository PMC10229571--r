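# Small survey configurations shared across test files.

tiny_config <- function(...) {
  survey_config(n_clusters = 3, lakes_per_cluster = 2, campaigns = 1, ...)
}

# noise-free generator settings: chamber records are exact ramps/steps
noiseless <- function(...) {
  tiny_config(noise_ch4_ppm = 0, noise_co2_ppm = 0, ...)
}
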