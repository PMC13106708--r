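#' Strain genotype with respect to the phytochrome photoreceptor
#'
#' `WT` (wild type) and `Tc` (transformed but non-mutated control) carry a
#' functional photoreceptor; `KO` (knockout) does not, which zeroes every
#' light-gated term in the population dynamics.
#'
#' @param label one of `"WT"`, `"Tc"`, `"KO"`.
#' @return an object of class `"genotype"`.
#' @export
genotype <- function(label = c("WT", "Tc", "KO")) {
  label <- match.arg(label)
  structure(list(label = label, dph_functional = label != "KO"),
            class = "genotype")
}

#' Simulation configuration for a wobbling-cell population
#'
#' Defaults mirror the standard continuous-light assay: 500 cells observed at
#' 1 Hz for 2 h at a density of 3e8 cells/L, natural wobble periods drawn
#' around 140 s (CV 5%), an initial 100 s mixing (agitation) phase, mean tilt
#' `beta0 = 0.35` rad and wobble amplitude `A = 0.25` rad with `A < beta0`
#' enforced so the orientation observable oscillates at the wobble frequency
#' rather than its double.
#'
#' @param n_cells number of cells (>= 1).
#' @param duration simulated time, s.
#' @param dt integration/sampling step, s; must satisfy
#'   `dt <= natural_period_mean / 20`.
#' @param seed integer root seed (see [sub_seed()] for the stream policy).
#' @param natural_period_mean mean natural wobble period, s.
#' @param natural_period_cv coefficient of variation of the period across
#'   cells.
#' @param coupling_gain K, rad/s per unit mean-field amplitude (>= 0).
#' @param forcing_gain F, rad/s per unit modulated irradiance (>= 0).
#' @param phase_noise_intensity D, rad^2/s; white phase noise enters as
#'   increments with standard deviation `sqrt(2 * D * dt)`.
#' @param mixing_duration length of the initial agitation phase, s, during
#'   which phases are re-randomized every step.
#' @param mean_tilt beta0, rad.
#' @param wobble_amplitude A, rad (must be < `mean_tilt`).
#' @param genotype a [genotype()].
#' @param cell_density cells per litre.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 500, duration = 7200, dt = 1, seed = 1,
                       natural_period_mean = 140, natural_period_cv = 0.05,
                       coupling_gain = 0.007, forcing_gain = 0.002,
                       phase_noise_intensity = 1e-4, mixing_duration = 100,
                       mean_tilt = 0.35, wobble_amplitude = 0.25,
                       genotype = diatomsync::genotype("WT"),
                       cell_density = 3e8) {
  .assert(.is_number(n_cells) && n_cells >= 1, "n_cells must be >= 1")
  .assert(.is_number(duration) && duration > 0, "duration must be > 0")
  .assert(.is_number(dt) && dt > 0, "dt must be > 0")
  .assert(.is_number(natural_period_mean) && natural_period_mean > 0,
          "natural_period_mean must be > 0")
  .assert(dt <= natural_period_mean / 20,
          "dt must be <= natural_period_mean / 20")
  .assert(.is_number(natural_period_cv) && natural_period_cv >= 0,
          "natural_period_cv must be >= 0")
  .assert(.is_number(coupling_gain) && coupling_gain >= 0,
          "coupling_gain must be >= 0")
  .assert(.is_number(forcing_gain) && forcing_gain >= 0,
          "forcing_gain must be >= 0")
  .assert(.is_number(phase_noise_intensity) && phase_noise_intensity >= 0,
          "phase_noise_intensity must be >= 0")
  .assert(.is_number(mixing_duration) && mixing_duration >= 0,
          "mixing_duration must be >= 0")
  .assert(.is_number(mean_tilt) && mean_tilt > 0 && mean_tilt < pi / 2,
          "mean_tilt must be in (0, pi/2)")
  .assert(.is_number(wobble_amplitude) && wobble_amplitude >= 0,
          "wobble_amplitude must be >= 0")
  .assert(wobble_amplitude < mean_tilt,
          "wobble_amplitude must be < mean_tilt (prevents frequency doubling)")
  .assert(inherits(genotype, "genotype"), "genotype must be a genotype object")
  .assert(.is_number(cell_density) && cell_density > 0,
          "cell_density must be > 0")
  .assert(.is_number(seed), "seed must be a single number")
  structure(list(n_cells = as.integer(n_cells), duration = duration, dt = dt,
                 seed = as.integer(seed),
                 natural_period_mean = natural_period_mean,
                 natural_period_cv = natural_period_cv,
                 coupling_gain = coupling_gain, forcing_gain = forcing_gain,
                 phase_noise_intensity = phase_noise_intensity,
                 mixing_duration = mixing_duration, mean_tilt = mean_tilt,
                 wobble_amplitude = wobble_amplitude, genotype = genotype,
                 cell_density = cell_density),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d %s cells, %g s @ dt %g s, period %g s (CV %g)\n",
    x$n_cells, x$genotype$label, x$duration, x$dt,
    x$natural_period_mean, x$natural_period_cv))
  cat(sprintf("  K = %g, F = %g, D = %g, mixing %g s, beta0 = %g, A = %g\n",
              x$coupling_gain, x$forcing_gain, x$phase_noise_intensity,
              x$mixing_duration, x$mean_tilt, x$wobble_amplitude))
  invisible(x)
}

#' Kuramoto order parameter of a set of phases
#'
#' `R * exp(1i * Phi) = mean(exp(1i * phases))`. `R = 1` is perfect synchrony;
#' for `N` independent uniform phases `E[R] ~ sqrt(pi)/2 * N^(-1/2)`.
#'
#' @param phases numeric vector of phases, rad (non-empty).
#' @return a list with elements `R` (in \[0, 1\]) and `Phi` (rad, in
#'   \[-pi, pi\]).
#' @export
order_parameter <- function(phases) {
  if (!is.numeric(phases) || length(phases) == 0L)
    stop("phases must be a non-empty numeric vector", call. = FALSE)
  .assert(all(is.finite(phases)), "phases must be finite")
  z <- mean(exp(1i * phases))
  list(R = Mod(z), Phi = Arg(z))
}

#' Simulate a population of light-gated coupled wobbling oscillators
#'
#' Integrates, by Euler-Maruyama,
#' \deqn{d\phi_i = [\omega_i + g^K_i K R \sin(\Phi - \phi_i)
#'   + g^F_i F \sum_b m_b \sin(\psi_b(t) - \phi_i)] dt + \sqrt{2 D dt}\,\eta}
#' where `(R, Phi)` is the population order parameter (the mean field standing
#' for perceived autofluorescence), `m_b` and `psi_b` are the amplitude and
#' phase of each sinusoidally modulated band of the light field, and `eta` is
#' standard Gaussian noise.
#'
#' Gating: the coupling gate is `dph_functional * activation(t)` (the
#' photostationary state of the photoreceptor under the current field). The
#' forcing gate defaults to `dph_functional * c(lambda)` with `c(lambda)` the
#' total photoconversion cross-section (activation + deactivation weight) at
#' the modulated band's wavelength, so that temporally modulated red light —
#' which photoconverts the receptor but leaves its steady state inactive —
#' can still entrain functional strains, while knockouts and spectrally blind
#' wavelengths cannot. `forcing_gate = "activation"` instead gates forcing by
#' the photostationary activation itself.
#'
#' During the initial mixing phase (`t < mixing_duration`) phases are
#' re-randomized every step (strong agitation); free evolution follows.
#' Identical `(config, field, spectrum)` and seed give bit-identical output.
#'
#' @param config a [sim_config()].
#' @param field a [light_field()] with `duration >= config$duration`.
#' @param spectrum an [action_spectrum()].
#' @param forcing_gate `"photoconversion"` (default) or `"activation"`.
#' @param gating `"instantaneous"` (default) or `"time_averaged"`: whether the
#'   coupling gate follows the instantaneous photostationary activation or its
#'   average over the run.
#' @param dark_activation passed to [dph_steady_state()].
#' @param initial_phases optional numeric vector of length `n_cells`
#'   overriding the random uniform initial phases (useful for controlled
#'   starts; the mixing phase, if any, still re-randomizes).
#' @param keep_phases keep the full time-by-cell phase matrix (needed by the
#'   observation models).
#' @return an object of class `"population_trajectory"`: `times`, `phases`
#'   (time-by-cell matrix or `NULL`), `R`, `Phi`, `dph_activation`,
#'   `natural_periods`, `config`.
#' @export
simulate_population <- function(config, field,
                                spectrum = default_action_spectrum(),
                                forcing_gate = c("photoconversion",
                                                 "activation"),
                                gating = c("instantaneous", "time_averaged"),
                                dark_activation = 0, initial_phases = NULL,
                                keep_phases = TRUE) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  .assert(inherits(field, "light_field"), "field must be a light_field")
  forcing_gate <- match.arg(forcing_gate)
  gating <- match.arg(gating)
  .assert(field$duration >= config$duration,
          "field duration must cover config duration")

  n <- config$n_cells
  dt <- config$dt
  times <- seq(0, config$duration, by = dt)
  n_t <- length(times)

  act <- dph_steady_state(field, spectrum, times, dark_activation)
  if (gating == "time_averaged") act[] <- mean(act)

  sins <- Filter(Negate(is.null), lapply(field$bands, .band_sinusoid))
  if (length(sins)) {
    wl <- vapply(sins, `[[`, numeric(1), "wavelength")
    gate_f <- .spectrum_weight(spectrum$activation, wl, "activation") +
      .spectrum_weight(spectrum$deactivation, wl, "deactivation")
    for (j in seq_along(sins)) sins[[j]]$gate <- gate_f[j]
  }

  functional <- config$genotype$dph_functional

  set.seed(sub_seed(config$seed, 1L))
  periods <- stats::rnorm(n, config$natural_period_mean,
                          config$natural_period_cv *
                            config$natural_period_mean)
  periods <- pmax(periods, 0.2 * config$natural_period_mean)
  omega <- 2 * pi / periods

  set.seed(sub_seed(config$seed, 2L))
  phi <- stats::runif(n, -pi, pi)
  if (!is.null(initial_phases)) {
    .assert(is.numeric(initial_phases) && length(initial_phases) == n &&
              all(is.finite(initial_phases)),
            "initial_phases must be a finite numeric vector of length n_cells")
    phi <- as.numeric(initial_phases)
  }

  set.seed(sub_seed(config$seed, 3L))
  noise_sd <- sqrt(2 * config$phase_noise_intensity * dt)
  r_series <- numeric(n_t)
  phi_series <- numeric(n_t)
  phases <- if (keep_phases) matrix(NA_real_, n_t, n) else NULL

  for (k in seq_len(n_t)) {
    if (times[k] < config$mixing_duration) phi <- stats::runif(n, -pi, pi)
    cph <- cos(phi)
    sph <- sin(phi)
    mc <- mean(cph)
    ms <- mean(sph)
    r_series[k] <- sqrt(mc * mc + ms * ms)
    phi_series[k] <- atan2(ms, mc)
    if (keep_phases) phases[k, ] <- phi
    if (k == n_t) break
    drift <- omega
    if (functional) {
      if (config$coupling_gain > 0 && act[k] > 0) {
        # K * R * sin(Phi - phi) = K * (ms * cos(phi) - mc * sin(phi))
        a <- act[k] * config$coupling_gain
        drift <- drift + a * (ms * cph - mc * sph)
      }
      if (config$forcing_gain > 0 && length(sins)) {
        for (s in sins) {
          g <- if (forcing_gate == "photoconversion") s$gate else act[k]
          if (g > 0) {
            psi <- 2 * pi * times[k] / s$period + s$phase
            fa <- g * config$forcing_gain * s$amplitude
            drift <- drift + fa * (sin(psi) * cph - cos(psi) * sph)
          }
        }
      }
    }
    phi <- phi + drift * dt
    if (noise_sd > 0) phi <- phi + stats::rnorm(n, 0, noise_sd)
  }

  structure(list(times = times, phases = phases, R = r_series,
                 Phi = phi_series, dph_activation = act,
                 natural_periods = periods, config = config),
            class = "population_trajectory")
}

#' @export
print.population_trajectory <- function(x, ...) {
  sed <- x$times >= x$config$mixing_duration
  cat(sprintf(
    "population_trajectory: %d %s cells, %d samples @ dt %g s\n",
    x$config$n_cells, x$config$genotype$label, length(x$times), x$config$dt))
  cat(sprintf("  mean R (sedimentation phase): %.3f; mean DPH activation: %.3f\n",
              mean(x$R[sed]), mean(x$dph_activation)))
  invisible(x)
}

#' Per-cell tilt angles of a trajectory
#'
#' `beta_i(t) = beta0 + A * sin(phi_i(t))`, rad.
#'
#' @param trajectory a [simulate_population()] result with kept phases.
#' @return a time-by-cell matrix of tilt angles.
#' @export
population_tilts <- function(trajectory) {
  .assert(inherits(trajectory, "population_trajectory"),
          "trajectory must be a population_trajectory")
  .assert(!is.null(trajectory$phases),
          "trajectory was simulated with keep_phases = FALSE")
  trajectory$config$mean_tilt +
    trajectory$config$wobble_amplitude * sin(trajectory$phases)
}

#' Export a trajectory's population summary as CSV
#'
#' Columns `time_s`, `R`, `Phi`, `dph_activation`. Optionally writes the full
#' per-cell phase matrix as a second, wide CSV (`time_s`, `phi_001`, ...).
#'
#' @param trajectory a [simulate_population()] result.
#' @param path output CSV path.
#' @param phases_path optional path for the wide per-cell phase matrix.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, phases_path = NULL) {
  .assert(inherits(trajectory, "population_trajectory"),
          "trajectory must be a population_trajectory")
  df <- data.frame(time_s = trajectory$times, R = trajectory$R,
                   Phi = trajectory$Phi,
                   dph_activation = trajectory$dph_activation)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(phases_path)) {
    .assert(!is.null(trajectory$phases), "trajectory has no phase matrix")
    wide <- as.data.frame(trajectory$phases)
    names(wide) <- sprintf("phi_%03d", seq_len(ncol(wide)))
    wide <- cbind(data.frame(time_s = trajectory$times), wide)
    utils::write.csv(wide, phases_path, row.names = FALSE)
  }
  invisible(path)
}

#' Round-trip a simulation configuration through JSON
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `read_sim_config` returns a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  x <- unclass(config)
  x$genotype <- config$genotype$label
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$genotype <- genotype(x$genotype)
  do.call(sim_config, x)
}
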