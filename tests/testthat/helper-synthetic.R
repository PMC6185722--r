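# helpers shared across test files

# noise-free incubation curve on the standard schedule
noisefree_curve <- function(k, eta, bat = 1, schedule = c(1:20, 22, 24, 27, 30, 34, 36, 41),
                            variance = 1e-5, n_rep = 4) {
  p <- turnover_params(k, eta)
  incubation_curve(times = schedule,
                   values = cumulative_mineralization(p, schedule,
                                                      soil_context("s", bat)),
                   variances = rep(variance, length(schedule)),
                   n_rep = n_rep, bgr_id = "synth", soil_id = "s")
}

# run the full generate -> prepare pipeline for a single treatment/soil
pipeline_curves <- function(k, eta, noise_sd = 0.005, seed = 1,
                            soils = data.frame(soil = "s", bat_factor = 1)) {
  spec <- synthetic_spec(params = data.frame(bgr = "X", k = k, eta = eta),
                         soils = soils, noise_sd = noise_sd, seed = seed)
  raw <- generate_incubation(spec)
  prepare_incubation(raw)
}
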