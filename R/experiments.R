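#' Config-driven experiment specification
#'
#' Describes one of the four in-silico experiment families end-to-end
#' (simulate -> observe -> analyze), in triplicate by default:
#'
#' * `wavelength_scan`: continuous light at 430/530/617/660/780 nm,
#'   8 umol photons m^-2 s^-1, 2 h.
#' * `composed_rb`: 430 nm at 8 plus 660 nm at 0/2/4/6 (R:B ratios
#'   0/0.25/0.5/0.75), with blue-only controls at matched total intensities
#'   8/10/12/14.
#' * `pulsed`: 660 and 780 nm sinusoidally modulated at the ~140 s natural
#'   wobble period (peak irradiance ~8, max-normalized), plus constant-light
#'   references at the same wavelength and a constant-blue reference.
#' * `fluorescence`: 430 nm at 30 umol photons m^-2 s^-1 for 45 min, two-band
#'   autofluorescence readout.
#'
#' @param family one of `"wavelength_scan"`, `"composed_rb"`, `"pulsed"`,
#'   `"fluorescence"`.
#' @param genotypes subset of `c("WT", "Tc", "KO")`.
#' @param replicates number of replicates; must equal `length(seeds)`.
#' @param seeds integer seeds, one per replicate (default 1:3).
#' @param protocol named list of family-specific protocol overrides (see the
#'   per-family defaults in the source of `.default_protocol`).
#' @param sim named list of [sim_config()] overrides (e.g. `n_cells`,
#'   `duration` for scaled-down runs).
#' @param noise_cv laser-diffraction measurement noise CV.
#' @param output_dir optional directory; when set, runners write per-run CSVs
#'   and a summary JSON there.
#' @return an object of class `"experiment_spec"`.
#' @export
experiment_spec <- function(family = c("wavelength_scan", "composed_rb",
                                       "pulsed", "fluorescence"),
                            genotypes = c("WT", "KO"), replicates = 3,
                            seeds = seq_len(replicates), protocol = list(),
                            sim = list(), noise_cv = 0.05,
                            output_dir = NULL) {
  family <- match.arg(family)
  .assert(length(genotypes) >= 1L &&
            all(genotypes %in% c("WT", "Tc", "KO")),
          "genotypes must be a subset of WT, Tc, KO")
  .assert(.is_number(replicates) && replicates >= 1,
          "replicates must be >= 1")
  .assert(length(seeds) == replicates, "replicates must equal length(seeds)")
  .assert(is.list(protocol) && is.list(sim),
          "protocol and sim must be named lists")
  proto <- utils::modifyList(.default_protocol(family), protocol)
  .validate_protocol(family, proto)
  structure(list(family = family, genotypes = genotypes,
                 replicates = as.integer(replicates),
                 seeds = as.integer(seeds), protocol = proto, sim = sim,
                 noise_cv = noise_cv, output_dir = output_dir),
            class = "experiment_spec")
}

.default_protocol <- function(family) {
  switch(family,
    wavelength_scan = list(wavelengths = c(430, 530, 617, 660, 780),
                           irradiance = 8, duration = 7200),
    composed_rb = list(blue_wavelength = 430, blue_irradiance = 8,
                       red_wavelength = 660, red_irradiances = c(0, 2, 4, 6),
                       control_intensities = c(10, 12, 14), duration = 7200),
    pulsed = list(wavelengths = c(660, 780), irradiance = 8, period = 140,
                  depth = 1, reference_blue = 430, duration = 7200),
    fluorescence = list(excitation_wavelength = 430, excitation = 30,
                        duration = 2700, anisotropy = 0.8))
}

.validate_protocol <- function(family, p) {
  if (family == "composed_rb") {
    .assert(.is_number(p$blue_wavelength) && .is_number(p$red_wavelength),
            "composed_rb requires exactly one blue and one red band")
    .assert(p$blue_wavelength < 500 && p$red_wavelength > 600,
            "composed_rb bands must be one blue (<500 nm) and one red (>600 nm)")
    .assert(all(p$red_irradiances >= 0), "red irradiances must be >= 0")
  }
  if (family == "pulsed")
    .assert(all(p$wavelengths %in% c(660, 780)),
            "pulsed wavelengths must be 660 and/or 780 nm")
  .assert(.is_number(p$duration) && p$duration > 0, "duration must be > 0")
  invisible(TRUE)
}

#' @export
print.experiment_spec <- function(x, ...) {
  cat(sprintf("experiment_spec [%s]: genotypes %s, %d replicate(s), seeds %s\n",
              x$family, paste(x$genotypes, collapse = "/"), x$replicates,
              paste(x$seeds, collapse = ",")))
  invisible(x)
}

#' Experiment spec JSON round-trip
#'
#' @param spec an [experiment_spec()].
#' @param path file path.
#' @return `read_experiment_spec` returns an [experiment_spec()].
#' @export
write_experiment_spec <- function(spec, path) {
  .assert(inherits(spec, "experiment_spec"), "spec must be an experiment_spec")
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_experiment_spec
#' @export
read_experiment_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  experiment_spec(family = x$family, genotypes = x$genotypes,
                  replicates = x$replicates, seeds = x$seeds,
                  protocol = if (is.null(x$protocol)) list() else
                    as.list(x$protocol),
                  sim = if (is.null(x$sim)) list() else as.list(x$sim),
                  noise_cv = if (is.null(x$noise_cv)) 0.05 else x$noise_cv,
                  output_dir = x$output_dir)
}

# Build a sim_config for one run: spec-level overrides + per-run settings.
.make_config <- function(spec, label, seed, duration) {
  args <- utils::modifyList(
    list(duration = duration, seed = seed,
         genotype = genotype(label)), spec$sim)
  args$genotype <- genotype(label)
  args$seed <- seed
  args$duration <- duration
  do.call(sim_config, args)
}

# One full simulate -> observe -> Ratio -> spectrum -> peak chain.
# Mixing phase is excluded from spectral analysis.
.run_chain <- function(spec, label, field, seed, tag,
                       spectrum = default_action_spectrum(),
                       keep_series = FALSE) {
  cfg <- .make_config(spec, label, seed, field$duration)
  traj <- simulate_population(cfg, field, spectrum)
  set.seed(sub_seed(seed, 77L))
  scs <- observe_population(traj, noise_cv = spec$noise_cv)
  rs <- ratio_series(scs)
  sed <- trim_ratio_series(rs, cfg$mixing_duration)
  ps <- power_spectrum(preprocess(sed))
  summary <- characterize_peak(ps)
  t0 <- Sys.time()
  message(sprintf(
    "[%s] %s genotype=%s seed=%d fit=%s period=%.1fs amp=%.3g",
    spec$family, tag, label, seed, summary$fit_mode, summary$mean_period_s,
    summary$normalized_amplitude))
  out <- list(tag = tag, genotype = label, seed = seed, config = cfg,
              spectrum = ps, summary = summary, logged_at = t0)
  if (keep_series) {
    out$size_class_series <- scs
    out$ratio <- rs
  }
  out
}

.mean_sd <- function(x) c(mean = mean(x), sd = stats::sd(x))

.write_run_outputs <- function(spec, runs, summary_df, summary_name) {
  if (is.null(spec$output_dir)) return(invisible(NULL))
  dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (r in runs) {
    stem <- file.path(spec$output_dir,
                      sprintf("%s_%s_seed%d", r$tag, r$genotype, r$seed))
    write_power_spectrum(r$spectrum, paste0(stem, "_spectrum.csv"))
    write_peak_summary(r$summary, paste0(stem, "_summary.json"))
    if (!is.null(r$ratio))
      write_ratio_series(r$ratio, paste0(stem, "_ratio.csv"))
    if (!is.null(r$size_class_series))
      write_size_class_series(r$size_class_series,
                              paste0(stem, "_sizeclass.csv"))
  }
  utils::write.csv(summary_df,
                   file.path(spec$output_dir,
                             paste0(summary_name, "_summary.csv")),
                   row.names = FALSE)
  jsonlite::write_json(summary_df,
                       file.path(spec$output_dir,
                                 paste0(summary_name, "_summary.json")),
                       dataframe = "rows", digits = NA)
  invisible(NULL)
}

#' Run a wavelength-scan experiment
#'
#' Continuous monochromatic light per wavelength and genotype; reports the
#' Pk/FWHM normalized amplitude and fitted mean period as mean +/- sample SD
#' over replicates (per-replicate fit, then average).
#'
#' @param spec an [experiment_spec()] with `family = "wavelength_scan"`.
#' @param keep_series retain per-run size-class and ratio series (memory!).
#' @return an object of class `"wavelength_scan_result"`: `summary` data
#'   frame (wavelength, genotype, amplitude mean/sd, period mean/sd,
#'   dominant fit mode), `runs` (per-run summaries and spectra).
#' @export
run_wavelength_scan <- function(spec, keep_series = FALSE) {
  .assert(inherits(spec, "experiment_spec") &&
            spec$family == "wavelength_scan",
          "spec must be an experiment_spec with family wavelength_scan")
  p <- spec$protocol
  runs <- list()
  rows <- list()
  for (wl in p$wavelengths) {
    field <- light_field(spectral_band(wl, p$irradiance), p$duration)
    for (g in spec$genotypes) {
      reps <- lapply(spec$seeds, function(s)
        .run_chain(spec, g, field, s, tag = sprintf("wl%03d", wl),
                   keep_series = keep_series))
      amp <- vapply(reps, function(r) r$summary$normalized_amplitude,
                    numeric(1))
      per <- vapply(reps, function(r) r$summary$mean_period_s, numeric(1))
      modes <- vapply(reps, function(r) r$summary$fit_mode, character(1))
      rows[[length(rows) + 1L]] <- data.frame(
        wavelength = wl, genotype = g,
        amplitude_mean = mean(amp), amplitude_sd = stats::sd(amp),
        period_mean = mean(per), period_sd = stats::sd(per),
        fit_mode = names(sort(table(modes), decreasing = TRUE))[1],
        n = length(reps))
      runs <- c(runs, reps)
    }
  }
  summary_df <- do.call(rbind, rows)
  .write_run_outputs(spec, runs, summary_df, "wavelength_scan")
  structure(list(summary = summary_df, runs = runs, spec = spec),
            class = "wavelength_scan_result")
}

#' Run a composed red:blue mixing experiment
#'
#' Constant blue (8 umol) plus red at 0/2/4/6 umol (R:B = red/blue irradiance
#' = 0/0.25/0.5/0.75) and blue-only controls at matched total intensities.
#' Amplitudes are normalized to the mean R:B = 0 baseline; each arm gets an
#' ordinary least-squares line with a 95% confidence interval on the slope
#' (R:B arm versus ratio; control arm versus total intensity).
#'
#' @param spec an [experiment_spec()] with `family = "composed_rb"`.
#' @return an object of class `"composed_rb_result"`: `summary` data frame
#'   (arm, rb_ratio, total_intensity, normalized amplitude mean/sd, period
#'   mean/sd), `fits` (per-arm slope, 95% CI, lm objects), `runs`.
#' @export
run_composed_rb <- function(spec) {
  .assert(inherits(spec, "experiment_spec") && spec$family == "composed_rb",
          "spec must be an experiment_spec with family composed_rb")
  p <- spec$protocol
  g <- spec$genotypes[1]
  if (length(spec$genotypes) > 1L)
    message("composed_rb: using first genotype ", g)

  arms <- rbind(
    data.frame(arm = "rb", red = p$red_irradiances,
               blue = p$blue_irradiance,
               total = p$blue_irradiance + p$red_irradiances,
               rb_ratio = p$red_irradiances / p$blue_irradiance),
    data.frame(arm = "control", red = 0, blue = p$control_intensities,
               total = p$control_intensities, rb_ratio = 0))

  runs <- list()
  per_run <- list()
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    bands <- list(spectral_band(p$blue_wavelength, a$blue))
    if (a$red > 0)
      bands <- c(bands, list(spectral_band(p$red_wavelength, a$red)))
    field <- light_field(bands, p$duration)
    tag <- sprintf("%s_b%g_r%g", a$arm, a$blue, a$red)
    reps <- lapply(spec$seeds, function(s) .run_chain(spec, g, field, s, tag))
    for (r in reps)
      per_run[[length(per_run) + 1L]] <- data.frame(
        arm = a$arm, rb_ratio = a$rb_ratio, total_intensity = a$total,
        seed = r$seed, amplitude = r$summary$normalized_amplitude,
        period = r$summary$mean_period_s)
    runs <- c(runs, reps)
  }
  df <- do.call(rbind, per_run)
  baseline <- mean(df$amplitude[df$arm == "rb" & df$rb_ratio == 0])
  .assert(baseline > 0, "zero baseline amplitude; cannot normalize")
  df$norm_amplitude <- df$amplitude / baseline

  agg <- do.call(rbind, lapply(split(df, list(df$arm, df$rb_ratio,
                                              df$total_intensity),
                                     drop = TRUE), function(d)
    data.frame(arm = d$arm[1], rb_ratio = d$rb_ratio[1],
               total_intensity = d$total_intensity[1],
               norm_amplitude_mean = mean(d$norm_amplitude),
               norm_amplitude_sd = stats::sd(d$norm_amplitude),
               period_mean = mean(d$period), period_sd = stats::sd(d$period),
               n = nrow(d))))
  agg <- agg[order(agg$arm, agg$total_intensity), , drop = FALSE]
  rownames(agg) <- NULL

  rb <- df[df$arm == "rb", ]
  fit_rb <- stats::lm(norm_amplitude ~ rb_ratio, data = rb)
  # controls: the R:B = 0 baseline is the blue-only point at 8 umol
  ctl <- rbind(df[df$arm == "control", ],
               df[df$arm == "rb" & df$rb_ratio == 0, ])
  fit_ctl <- stats::lm(norm_amplitude ~ total_intensity, data = ctl)
  ci <- function(fit) stats::confint(fit, level = 0.95)[2, ]
  fits <- list(
    rb = list(slope = unname(stats::coef(fit_rb)[2]), ci95 = ci(fit_rb),
              lm = fit_rb),
    control = list(slope = unname(stats::coef(fit_ctl)[2]),
                   ci95 = ci(fit_ctl), lm = fit_ctl))

  .write_run_outputs(spec, runs, agg, "composed_rb")
  structure(list(summary = agg, per_run = df, fits = fits, runs = runs,
                 spec = spec),
            class = "composed_rb_result")
}

#' Run a pulsed red/far-red entrainment experiment
#'
#' For each wavelength (660 and/or 780 nm) and genotype: a sinusoidally
#' modulated run at the natural wobble period (peak irradiance ~8,
#' max-normalized) and a constant-light reference at the same wavelength,
#' yielding the per-strain [entrainment_index()]. A constant-blue reference
#' per genotype supports the pulsed-red versus constant-blue peak-amplitude
#' comparison.
#'
#' @param spec an [experiment_spec()] with `family = "pulsed"`.
#' @return an object of class `"pulsed_result"`: `summary` (wavelength,
#'   genotype, pulsed/constant Pk mean and sd, entrainment index mean,
#'   pulsed f0 mean), `blue_reference` (per-genotype constant-blue Pk),
#'   `pulsed_vs_blue` (pulsed-660 Pk / constant-430 Pk per genotype),
#'   `runs`.
#' @export
run_pulsed <- function(spec) {
  .assert(inherits(spec, "experiment_spec") && spec$family == "pulsed",
          "spec must be an experiment_spec with family pulsed")
  p <- spec$protocol
  runs <- list()
  rows <- list()
  pk_of <- function(reps) vapply(reps, function(r) r$summary$pk, numeric(1))

  blue_field <- light_field(spectral_band(p$reference_blue, p$irradiance),
                            p$duration)
  blue_ref <- list()
  for (g in spec$genotypes) {
    reps <- lapply(spec$seeds, function(s)
      .run_chain(spec, g, blue_field, s, tag = "constB"))
    blue_ref[[g]] <- list(pk = mean(pk_of(reps)), runs = reps)
    runs <- c(runs, reps)
  }

  pulsed_pk <- list()
  for (wl in p$wavelengths) {
    pulsed_field <- light_field(
      spectral_band(wl, p$irradiance,
                    modulation_sinusoid(p$period, p$depth,
                                        normalize = "max")),
      p$duration)
    const_field <- light_field(spectral_band(wl, p$irradiance), p$duration)
    for (g in spec$genotypes) {
      reps_p <- lapply(spec$seeds, function(s)
        .run_chain(spec, g, pulsed_field, s, tag = sprintf("pulsed%d", wl)))
      reps_c <- lapply(spec$seeds, function(s)
        .run_chain(spec, g, const_field, s, tag = sprintf("const%d", wl)))
      ei <- mapply(function(rp, rc)
        entrainment_index(rp$summary, rc$summary)$index,
        reps_p, reps_c)
      rows[[length(rows) + 1L]] <- data.frame(
        wavelength = wl, genotype = g,
        pulsed_pk_mean = mean(pk_of(reps_p)),
        pulsed_pk_sd = stats::sd(pk_of(reps_p)),
        constant_pk_mean = mean(pk_of(reps_c)),
        constant_pk_sd = stats::sd(pk_of(reps_c)),
        entrainment_index_mean = mean(ei),
        pulsed_f0_mean = mean(vapply(reps_p, function(r) r$summary$f0_hz,
                                     numeric(1))),
        n = length(reps_p))
      if (wl == 660) pulsed_pk[[g]] <- mean(pk_of(reps_p))
      runs <- c(runs, reps_p, reps_c)
    }
  }
  summary_df <- do.call(rbind, rows)
  pulsed_vs_blue <- vapply(
    spec$genotypes,
    function(g) if (is.null(pulsed_pk[[g]])) NA_real_ else
      pulsed_pk[[g]] / blue_ref[[g]]$pk,
    numeric(1))
  .write_run_outputs(spec, runs, summary_df, "pulsed")
  structure(list(summary = summary_df,
                 blue_reference = vapply(blue_ref, `[[`, numeric(1), "pk"),
                 pulsed_vs_blue = pulsed_vs_blue, runs = runs, spec = spec),
            class = "pulsed_result")
}

#' Run a fluorescence experiment
#'
#' Blue excitation (430 nm, 30 umol photons m^-2 s^-1, 45 min by default);
#' per genotype, the two-band autofluorescence series and a power spectrum
#' and peak summary per band (mixing phase excluded).
#'
#' @param spec an [experiment_spec()] with `family = "fluorescence"`.
#' @return an object of class `"fluorescence_result"`: per-genotype list of
#'   replicate runs (each with `series`, `spectrum_R`, `spectrum_FR`,
#'   `summary_R`, `summary_FR`), plus a `summary` data frame with per-band
#'   fitted peak frequencies.
#' @export
run_fluorescence <- function(spec) {
  .assert(inherits(spec, "experiment_spec") && spec$family == "fluorescence",
          "spec must be an experiment_spec with family fluorescence")
  p <- spec$protocol
  field <- light_field(spectral_band(p$excitation_wavelength, p$excitation),
                       p$duration)
  out <- list()
  rows <- list()
  for (g in spec$genotypes) {
    reps <- lapply(spec$seeds, function(s) {
      cfg <- .make_config(spec, g, s, p$duration)
      traj <- simulate_population(cfg, field)
      fl <- emit_fluorescence(traj, excitation = p$excitation,
                              anisotropy = p$anisotropy)
      analyze <- function(band) {
        keep <- fl$times >= cfg$mixing_duration
        y <- if (band == "R") fl$band_R else fl$band_FR
        ps <- power_spectrum(preprocess(y[keep], dt = cfg$dt))
        list(spectrum = ps, summary = characterize_peak(ps))
      }
      a_r <- analyze("R")
      a_fr <- analyze("FR")
      message(sprintf(
        "[fluorescence] genotype=%s seed=%d f0_R=%.4g Hz f0_FR=%.4g Hz",
        g, s, a_r$summary$f0_hz, a_fr$summary$f0_hz))
      list(genotype = g, seed = s, series = fl,
           spectrum_R = a_r$spectrum, spectrum_FR = a_fr$spectrum,
           summary_R = a_r$summary, summary_FR = a_fr$summary)
    })
    out[[g]] <- reps
    for (r in reps)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, seed = r$seed,
        f0_R = r$summary_R$f0_hz, f0_FR = r$summary_FR$f0_hz,
        pk_R = r$summary_R$pk, pk_FR = r$summary_FR$pk,
        band_correlation = stats::cor(r$series$band_R, r$series$band_FR))
  }
  summary_df <- do.call(rbind, rows)
  if (!is.null(spec$output_dir)) {
    dir.create(spec$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in names(out)) for (r in out[[g]]) {
      stem <- file.path(spec$output_dir,
                        sprintf("fluor_%s_seed%d", g, r$seed))
      write_fluorescence_series(r$series, paste0(stem, ".csv"))
      write_power_spectrum(r$spectrum_R, paste0(stem, "_spectrum_R.csv"))
      write_power_spectrum(r$spectrum_FR, paste0(stem, "_spectrum_FR.csv"))
    }
    utils::write.csv(summary_df,
                     file.path(spec$output_dir, "fluorescence_summary.csv"),
                     row.names = FALSE)
  }
  structure(list(summary = summary_df, genotypes = out, spec = spec),
            class = "fluorescence_result")
}

#' Run an experiment specification
#'
#' Dispatches to the family-specific runner.
#'
#' @param spec an [experiment_spec()].
#' @param ... passed to the family runner.
#' @return the family runner's result object.
#' @export
run_experiment <- function(spec, ...) {
  .assert(inherits(spec, "experiment_spec"), "spec must be an experiment_spec")
  switch(spec$family,
         wavelength_scan = run_wavelength_scan(spec, ...),
         composed_rb = run_composed_rb(spec, ...),
         pulsed = run_pulsed(spec, ...),
         fluorescence = run_fluorescence(spec, ...))
}

#' Validate an experiment summary against its shipped schema
#'
#' Each family ships a minimal column schema under
#' `inst/schemas/<family>.json` (`{"required_columns": {name: type}}`);
#' this checks presence and base type of every required column.
#'
#' @param summary_df a runner's `summary` data frame.
#' @param family the experiment family.
#' @return `TRUE` invisibly; errors on mismatch.
#' @export
validate_experiment_summary <- function(summary_df, family) {
  path <- system.file("schemas", paste0(family, ".json"),
                      package = "diatomsync")
  .assert(nzchar(path), sprintf("no schema shipped for family %s", family))
  schema <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- schema$required_columns
  for (col in names(req)) {
    .assert(col %in% names(summary_df),
            sprintf("missing required column %s", col))
    ok <- switch(req[[col]],
                 number = is.numeric(summary_df[[col]]),
                 string = is.character(summary_df[[col]]) ||
                   is.factor(summary_df[[col]]),
                 integer = is.numeric(summary_df[[col]]),
                 TRUE)
    .assert(ok, sprintf("column %s is not of type %s", col, req[[col]]))
  }
  invisible(TRUE)
}

#' Emit small canned fixture datasets
#'
#' Writes a short deterministic wild-type run (size-class CSV, ratio CSV,
#' spectrum CSV, light-field JSON, sim-config JSON) into a directory; useful
#' for trying the analyze path on known-good files.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @return `out_dir` invisibly.
#' @export
emit_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(n_cells = 60, duration = 900, seed = seed)
  field <- light_field(spectral_band(430, 8), 900)
  traj <- simulate_population(cfg, field)
  set.seed(sub_seed(seed, 77L))
  scs <- observe_population(traj)
  rs <- ratio_series(scs)
  ps <- power_spectrum(preprocess(trim_ratio_series(rs,
                                                    cfg$mixing_duration)))
  write_sim_config(cfg, file.path(out_dir, "fixture_config.json"))
  write_light_field(field, file.path(out_dir, "fixture_lightfield.json"))
  write_size_class_series(scs, file.path(out_dir, "fixture_sizeclass.csv"))
  write_ratio_series(rs, file.path(out_dir, "fixture_ratio.csv"))
  write_power_spectrum(ps, file.path(out_dir, "fixture_spectrum.csv"))
  invisible(out_dir)
}

#' Analyze an externally supplied Ratio CSV
#'
#' Runs the spectral pipeline (preprocess -> periodogram -> prominence-gated
#' Gaussian fit) on a `time_s, ratio[, valid]` CSV, e.g. one exported from a
#' real laser-diffractometer record. Samples before `tmin` (the mixing
#' phase) are excluded.
#'
#' @param path CSV path.
#' @param tmin exclude samples before this time, s (default 0).
#' @return a list with `spectrum` ([power_spectrum()]) and `summary`
#'   ([characterize_peak()]).
#' @export
analyze_ratio_csv <- function(path, tmin = 0) {
  rs <- read_ratio_series(path)
  if (tmin > 0) rs <- trim_ratio_series(rs, tmin)
  ps <- power_spectrum(preprocess(rs))
  list(spectrum = ps, summary = characterize_peak(ps))
}
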