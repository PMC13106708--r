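# Shared small fixtures, built in code at test time.

blue_field <- function(duration = 900, irradiance = 8)
  light_field(spectral_band(430, irradiance), duration)

pulsed_red_field <- function(duration = 900, period = 140, irradiance = 8)
  light_field(spectral_band(660, irradiance,
                            modulation_sinusoid(period, 1,
                                                normalize = "max")),
              duration)

small_config <- function(seed = 1, n_cells = 60, duration = 900, ...)
  sim_config(n_cells = n_cells, duration = duration, seed = seed, ...)

# A hand-built trajectory with prescribed phases (time-by-cell matrix).
make_trajectory <- function(phases, dt = 1, mean_tilt = 0.35,
                            wobble_amplitude = 0.25, cell_density = 3e8) {
  phases <- as.matrix(phases)
  n_t <- nrow(phases)
  cfg <- sim_config(n_cells = ncol(phases), duration = max((n_t - 1) * dt, dt),
                    dt = dt, mixing_duration = 0, mean_tilt = mean_tilt,
                    wobble_amplitude = wobble_amplitude,
                    cell_density = cell_density)
  op <- t(apply(phases, 1, function(ph) {
    z <- mean(exp(1i * ph))
    c(Mod(z), Arg(z))
  }))
  structure(list(times = (seq_len(n_t) - 1) * dt, phases = phases,
                 R = op[, 1], Phi = op[, 2],
                 dph_activation = rep(1, n_t),
                 natural_periods = rep(140, ncol(phases)), config = cfg),
            class = "population_trajectory")
}

# A hand-built size-class series on the default grid.
make_size_class_series <- function(vc, times = seq_len(nrow(vc)) - 1,
                                   grid = size_class_grid()) {
  structure(list(times = times, volume_concentration = vc, grid = grid,
                 n_out_of_range = 0L),
            class = "size_class_series")
}

# Full default-scale simulate -> observe -> Ratio -> spectrum -> peak chain.
full_chain <- function(seed, field, genotype_label = "WT", sim = list()) {
  args <- utils::modifyList(list(seed = seed, duration = field$duration,
                                 genotype = genotype(genotype_label)), sim)
  cfg <- do.call(sim_config, args)
  traj <- simulate_population(cfg, field)
  set.seed(sub_seed(seed, 77L))
  scs <- observe_population(traj)
  rs <- trim_ratio_series(ratio_series(scs), cfg$mixing_duration)
  ps <- power_spectrum(preprocess(rs))
  list(traj = traj, spectrum = ps, summary = characterize_peak(ps))
}
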