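#' Temporal modulation descriptors for a spectral band
#'
#' A band is either constant or sinusoidally modulated. Two normalizations of
#' the sinusoid are supported: `"mean"` (the stated irradiance is the time
#' average, `I(t) = I0 * (1 + depth * sin(2*pi*t/period + phase))`) and
#' `"max"` (the stated irradiance is the peak, i.e. the mean-normalized wave
#' divided by `1 + depth`), the latter matching protocols where a source is
#' attenuated "down to a maximum value". Both keep instantaneous irradiance
#' nonnegative for `depth` in \[0, 1\].
#'
#' @param period modulation period, s (> 0).
#' @param depth modulation depth, in \[0, 1\].
#' @param phase phase offset, rad.
#' @param normalize `"mean"` or `"max"` (see above).
#' @return an object of class `"modulation"`.
#' @export
modulation_sinusoid <- function(period, depth = 1, phase = 0,
                                normalize = c("mean", "max")) {
  normalize <- match.arg(normalize)
  .assert(.is_number(period) && period > 0, "period must be > 0")
  .assert(.is_number(depth) && depth >= 0 && depth <= 1,
          "depth must be in [0, 1]")
  .assert(.is_number(phase), "phase must be a finite number")
  structure(list(type = "sinusoid", period = period, depth = depth,
                 phase = phase, normalize = normalize),
            class = "modulation")
}

#' @rdname modulation_sinusoid
#' @export
modulation_constant <- function() {
  structure(list(type = "constant"), class = "modulation")
}

#' A single spectral band of an illumination protocol
#'
#' @param center_wavelength nm; any positive value (protocol LEDs here are
#'   430, 530, 617, 660 and 780 nm).
#' @param irradiance photon irradiance, umol photons m^-2 s^-1 (>= 0). Its
#'   meaning under sinusoidal modulation depends on the modulation's
#'   normalization, see [modulation_sinusoid()].
#' @param modulation a `"modulation"` object.
#' @return an object of class `"spectral_band"`.
#' @export
spectral_band <- function(center_wavelength, irradiance,
                          modulation = modulation_constant()) {
  .assert(.is_number(center_wavelength) && center_wavelength > 0,
          "center_wavelength must be > 0")
  .assert(.is_number(irradiance) && irradiance >= 0,
          "irradiance must be >= 0")
  .assert(inherits(modulation, "modulation"),
          "modulation must be a modulation object")
  structure(list(center_wavelength = center_wavelength,
                 irradiance = irradiance, modulation = modulation),
            class = "spectral_band")
}

#' Multiband illumination protocol
#'
#' @param bands a list of [spectral_band()] objects (at least one).
#' @param duration protocol duration, s (> 0).
#' @return an object of class `"light_field"`.
#' @export
light_field <- function(bands, duration) {
  if (inherits(bands, "spectral_band")) bands <- list(bands)
  .assert(is.list(bands) && length(bands) >= 1L &&
            all(vapply(bands, inherits, logical(1), "spectral_band")),
          "bands must be a non-empty list of spectral_band objects")
  .assert(.is_number(duration) && duration > 0, "duration must be > 0")
  structure(list(bands = bands, duration = duration), class = "light_field")
}

#' @export
print.light_field <- function(x, ...) {
  cat(sprintf("light_field: %d band(s), duration %g s\n",
              length(x$bands), x$duration))
  for (b in x$bands) {
    m <- b$modulation
    desc <- if (m$type == "constant") "constant" else
      sprintf("sinusoid period %g s, depth %g, %s-normalized",
              m$period, m$depth, m$normalize)
    cat(sprintf("  %g nm @ %g umol photons m-2 s-1 (%s)\n",
                b$center_wavelength, b$irradiance, desc))
  }
  invisible(x)
}

.band_irradiance <- function(band, t) {
  m <- band$modulation
  if (m$type == "constant") return(rep(band$irradiance, length(t)))
  wave <- 1 + m$depth * sin(2 * pi * t / m$period + m$phase)
  if (m$normalize == "max") wave <- wave / (1 + m$depth)
  band$irradiance * wave
}

# Amplitude/period/phase of the sinusoidal component (for forcing terms);
# NULL for constant bands.
.band_sinusoid <- function(band) {
  m <- band$modulation
  if (m$type != "sinusoid" || m$depth == 0) return(NULL)
  amp <- band$irradiance * m$depth
  if (m$normalize == "max") amp <- amp / (1 + m$depth)
  list(amplitude = amp, period = m$period, phase = m$phase,
       wavelength = band$center_wavelength)
}

#' Evaluate a light field at given times
#'
#' @param field a [light_field()].
#' @param t time(s), s; every element must lie in \[0, duration\].
#' @return a numeric matrix, `length(t)` rows by one column per band; column
#'   names are the band wavelengths (nm). Entries are instantaneous
#'   irradiances, always >= 0.
#' @export
evaluate_lightfield <- function(field, t) {
  .assert(inherits(field, "light_field"), "field must be a light_field")
  .assert(is.numeric(t) && length(t) >= 1L && all(is.finite(t)),
          "t must be finite numeric")
  if (any(t < 0 | t > field$duration))
    stop(sprintf("t outside [0, %g]", field$duration), call. = FALSE)
  out <- vapply(field$bands, .band_irradiance, numeric(length(t)), t = t)
  out <- matrix(out, nrow = length(t))
  colnames(out) <- vapply(field$bands,
                          function(b) as.character(b$center_wavelength),
                          character(1))
  out
}

#' Photoreceptor action spectrum (photoconversion cross-sections)
#'
#' Tabulated activation/deactivation weights (arbitrary units, >= 0) versus
#' wavelength, interpolated linearly between anchors. Wavelengths outside the
#' tabulated range are a configuration error.
#'
#' The default parameterization follows the qualitative diatom-phytochrome
#' photoreversibility pattern: activation by blue (430 nm) and far-red
#' (780 nm), deactivation by red (660 nm, partially by amber 617 nm), and no
#' sensitivity in the green (530 nm).
#'
#' @param activation,deactivation data frames with columns `wavelength` (nm)
#'   and `weight` (>= 0), or named numeric vectors (names = wavelengths).
#' @return an object of class `"action_spectrum"`.
#' @export
action_spectrum <- function(activation, deactivation) {
  as_tab <- function(x, what) {
    if (is.numeric(x) && !is.null(names(x)))
      x <- data.frame(wavelength = as.numeric(names(x)), weight = unname(x))
    .assert(is.data.frame(x) && all(c("wavelength", "weight") %in% names(x)),
            sprintf("%s must have columns wavelength and weight", what))
    .assert(all(is.finite(x$wavelength)) && all(is.finite(x$weight)),
            sprintf("%s table must be finite", what))
    .assert(all(x$weight >= 0), sprintf("%s weights must be >= 0", what))
    x <- x[order(x$wavelength), , drop = FALSE]
    .assert(!anyDuplicated(x$wavelength),
            sprintf("%s wavelengths must be unique", what))
    .assert(nrow(x) >= 2L, sprintf("%s needs at least two anchors", what))
    x
  }
  structure(list(activation = as_tab(activation, "activation"),
                 deactivation = as_tab(deactivation, "deactivation")),
            class = "action_spectrum")
}

#' @rdname action_spectrum
#' @export
default_action_spectrum <- function() {
  action_spectrum(
    activation = data.frame(
      wavelength = c(430, 530, 617, 660, 780),
      weight     = c(1.0, 0.0, 0.0, 0.0, 1.0)),
    deactivation = data.frame(
      wavelength = c(430, 530, 617, 660, 780),
      weight     = c(0.0, 0.0, 0.3, 1.0, 0.0)))
}

.spectrum_weight <- function(tab, wavelength, what) {
  rng <- range(tab$wavelength)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop(sprintf(
      "wavelength %s nm not covered by the %s action spectrum [%g, %g]",
      paste(wavelength[wavelength < rng[1] | wavelength > rng[2]],
            collapse = ", "), what, rng[1], rng[2]), call. = FALSE)
  stats::approx(tab$wavelength, tab$weight, xout = wavelength)$y
}

#' Photostationary (steady-state) photoreceptor activation
#'
#' Two-state photoconversion at photoequilibrium: with per-band instantaneous
#' irradiances `I(lambda, t)`,
#' `K_act = sum(activation_weight(lambda) * I)`,
#' `K_deact = sum(deactivation_weight(lambda) * I)`, and
#' `activation = K_act / (K_act + K_deact)`. The formula is the fixed point of
#' the two-state rate equation `da/dt = K_act (1 - a) - K_deact a` and is
#' invariant under uniform scaling of all irradiances (ratiometric sensing).
#' In darkness (both sums zero) the configured dark-state activation is
#' returned.
#'
#' @param field a [light_field()].
#' @param spectrum an [action_spectrum()] covering all band wavelengths.
#' @param t time(s), s, within the field duration.
#' @param dark_activation activation fraction returned in darkness
#'   (default 0).
#' @return numeric vector of activation fractions in \[0, 1\], one per time.
#' @export
dph_steady_state <- function(field, spectrum, t, dark_activation = 0) {
  .assert(inherits(spectrum, "action_spectrum"),
          "spectrum must be an action_spectrum")
  .assert(.is_number(dark_activation) &&
            dark_activation >= 0 && dark_activation <= 1,
          "dark_activation must be in [0, 1]")
  irr <- evaluate_lightfield(field, t)
  wl <- as.numeric(colnames(irr))
  wa <- .spectrum_weight(spectrum$activation, wl, "activation")
  wd <- .spectrum_weight(spectrum$deactivation, wl, "deactivation")
  k_act <- drop(irr %*% wa)
  k_deact <- drop(irr %*% wd)
  tot <- k_act + k_deact
  ifelse(tot > 0, k_act / tot, dark_activation)
}

#' Read / write light-field protocols as JSON
#'
#' The JSON layout is a list of
#' `{wavelength_nm, irradiance, modulation: {type, period_s, depth, phase_rad,
#' normalize}}` plus a top-level `duration_s`.
#'
#' @param field a [light_field()].
#' @param path file path.
#' @return `read_light_field` returns a [light_field()];
#'   `write_light_field` returns `path` invisibly.
#' @export
write_light_field <- function(field, path) {
  .assert(inherits(field, "light_field"), "field must be a light_field")
  bands <- lapply(field$bands, function(b) {
    m <- b$modulation
    mod <- if (m$type == "constant") list(type = "constant") else
      list(type = "sinusoid", period_s = m$period, depth = m$depth,
           phase_rad = m$phase, normalize = m$normalize)
    list(wavelength_nm = b$center_wavelength, irradiance = b$irradiance,
         modulation = mod)
  })
  jsonlite::write_json(list(duration_s = field$duration, bands = bands),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_light_field
#' @export
read_light_field <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  bands <- lapply(x$bands, function(b) {
    m <- b$modulation
    mod <- if (identical(m$type, "sinusoid"))
      modulation_sinusoid(m$period_s, m$depth,
                          if (is.null(m$phase_rad)) 0 else m$phase_rad,
                          if (is.null(m$normalize)) "mean" else m$normalize)
    else modulation_constant()
    spectral_band(b$wavelength_nm, b$irradiance, mod)
  })
  light_field(bands, x$duration_s)
}
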