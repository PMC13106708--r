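#' Prepare a time series for spectral analysis
#'
#' Drops invalid samples (with a gap report), requires uniform sampling and
#' at least 64 valid samples, removes a linear trend (which also removes the
#' mean), and optionally z-scores the residual for "normalized" displays.
#' Interior invalid samples would break uniformity and are an error — no
#' silent resampling.
#'
#' @param x a [ratio_series()], or a numeric signal (with `times` or `dt`).
#' @param normalization `"none"` or `"zscore"`.
#' @param times sample times, s (numeric method; defaults to `0:(n-1) * dt`).
#' @param dt sampling step, s (numeric method, when `times` absent).
#' @param tol relative tolerance on sampling uniformity.
#' @param ... passed between methods.
#' @return an object of class `"prepared_signal"`: `signal` (detrended,
#'   mean-zero), `dt`, `times`, `n_dropped`, `gaps` (times of dropped
#'   samples), `normalization`.
#' @export
preprocess <- function(x, ...) UseMethod("preprocess")

#' @rdname preprocess
#' @export
preprocess.ratio_series <- function(x, normalization = c("none", "zscore"),
                                    tol = 1e-6, ...) {
  keep <- x$valid & is.finite(x$ratio)
  .preprocess_core(x$ratio[keep], x$times[keep], x$times[!keep],
                   match.arg(normalization), tol)
}

#' @rdname preprocess
#' @export
preprocess.fluorescence_series <- function(x, band = c("R", "FR"),
                                           normalization = c("none",
                                                             "zscore"),
                                           tol = 1e-6, ...) {
  band <- match.arg(band)
  y <- if (band == "R") x$band_R else x$band_FR
  .preprocess_core(y, x$times, numeric(0), match.arg(normalization), tol)
}

#' @rdname preprocess
#' @export
preprocess.default <- function(x, times = NULL, dt = 1,
                               normalization = c("none", "zscore"),
                               tol = 1e-6, ...) {
  .assert(is.numeric(x), "x must be numeric")
  keep <- is.finite(x)
  if (is.null(times)) times <- (seq_along(x) - 1) * dt
  .preprocess_core(x[keep], times[keep], times[!keep],
                   match.arg(normalization), tol)
}

#' @param band which fluorescence band to analyze (`"R"` or `"FR"`).
#' @noRd
.preprocess_core <- function(y, times, gap_times, normalization, tol) {
  if (length(y) < 64L)
    stop(sprintf("need >= 64 valid samples, got %d", length(y)),
         call. = FALSE)
  dts <- diff(times)
  dt <- stats::median(dts)
  if (max(abs(dts - dt)) > tol * dt)
    stop("non-uniform sampling after dropping invalid samples; refusing to resample",
         call. = FALSE)
  detrended <- stats::lsfit(times, y)$residuals
  detrended <- detrended - mean(detrended)
  if (normalization == "zscore") {
    s <- stats::sd(detrended)
    .assert(s > 0, "cannot z-score a constant signal")
    detrended <- detrended / s
  }
  structure(list(signal = as.numeric(detrended), dt = dt, times = times,
                 n_dropped = length(gap_times), gaps = gap_times,
                 normalization = normalization),
            class = "prepared_signal")
}

#' Variance-normalized periodogram of a prepared signal
#'
#' Single (non-Welch) FFT periodogram on the positive frequency half-axis,
#' zero frequency excluded, no taper by default (an optional Hann window is
#' available behind `window` but off for reproducibility). Power is
#' normalized so that `sum(power)` equals the variance (mean squared
#' deviation) of the analyzed signal — a Parseval identity that holds to
#' floating-point accuracy for every spectrum produced.
#'
#' @param x a [preprocess()] result or a numeric mean-zero signal.
#' @param dt sampling step, s (ignored when `x` is a prepared signal).
#' @param window `"none"` (default) or `"hann"`.
#' @return an object of class `"power_spectrum"`: `frequencies` (Hz, strictly
#'   increasing), `power`, `df` (bin width, Hz), `n`, `dt`, `variance`.
#' @export
power_spectrum <- function(x, dt = 1, window = c("none", "hann")) {
  window <- match.arg(window)
  if (inherits(x, "prepared_signal")) {
    dt <- x$dt
    x <- x$signal
  }
  .assert(is.numeric(x) && all(is.finite(x)), "signal must be finite numeric")
  n <- length(x)
  if (n < 64L)
    stop(sprintf("need >= 64 samples, got %d", n), call. = FALSE)
  x <- x - mean(x)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / n))
    x <- x * w / sqrt(mean(w^2))
  }
  ft <- stats::fft(x)
  half <- n %/% 2L
  k <- seq_len(half)
  power <- 2 * Mod(ft[k + 1L])^2 / n^2
  if (n %% 2L == 0L) power[half] <- power[half] / 2  # Nyquist bin, unpaired
  structure(list(frequencies = k / (n * dt), power = power, df = 1 / (n * dt),
                 n = n, dt = dt, variance = mean(x^2)),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  imax <- which.max(x$power)
  cat(sprintf(
    "power_spectrum: %d bins, df %.3g Hz; argmax %.4g Hz (period %.4g s)\n",
    length(x$power), x$df, x$frequencies[imax], 1 / x$frequencies[imax]))
  invisible(x)
}

#' Spectrum CSV I/O (`frequency_hz, power`)
#'
#' @param x a [power_spectrum()].
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_power_spectrum <- function(x, path) {
  .assert(inherits(x, "power_spectrum"), "x must be a power_spectrum")
  utils::write.csv(data.frame(frequency_hz = x$frequencies, power = x$power),
                   path, row.names = FALSE)
  invisible(path)
}

#' Topographic peak prominences of a power spectrum
#'
#' Locates interior local maxima and computes each peak's standard
#' topographic prominence: extend from the peak in each direction until
#' higher terrain (or the spectrum boundary) is met, take the minimum power
#' encountered on each side, and subtract the higher of the two bases from
#' the peak height. Prominences are reported relative to the median spectral
#' power (the "relative prominence" Pro) and sorted in decreasing order,
#' ties broken by lower frequency. A monotone spectrum yields an empty list,
#' which downstream forces full-spectrum fitting.
#'
#' @param spectrum a [power_spectrum()] (>= 3 points).
#' @return a data frame with columns `index`, `frequency`, `height`,
#'   `prominence` (relative, Pro), `prominence_abs`; attribute `reference`
#'   holds the median power used for normalization.
#' @export
peak_prominences <- function(spectrum) {
  .assert(inherits(spectrum, "power_spectrum"),
          "spectrum must be a power_spectrum")
  p <- spectrum$power
  n <- length(p)
  .assert(n >= 3L, "spectrum needs at least 3 points")
  empty <- data.frame(index = integer(0), frequency = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      prominence_abs = numeric(0))
  interior <- 2:(n - 1)
  is_peak <- p[interior] > p[interior - 1] & p[interior] > p[interior + 1]
  peaks <- interior[is_peak]
  ref <- stats::median(p)
  if (length(peaks) == 0L) {
    attr(empty, "reference") <- ref
    return(empty)
  }
  prom <- vapply(peaks, function(i) {
    higher_left <- which(p[seq_len(i - 1)] > p[i])
    from <- if (length(higher_left)) max(higher_left) else 1L
    left_base <- min(p[from:(i - 1)])
    right_seq <- seq(i + 1L, n)
    higher_right <- right_seq[p[right_seq] > p[i]]
    to <- if (length(higher_right)) min(higher_right) else n
    right_base <- min(p[(i + 1L):to])
    p[i] - max(left_base, right_base)
  }, numeric(1))
  out <- data.frame(index = peaks, frequency = spectrum$frequencies[peaks],
                    height = p[peaks],
                    prominence = if (ref > 0) prom / ref else prom,
                    prominence_abs = prom)
  out <- out[order(-out$prominence, out$frequency), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "reference") <- ref
  out
}

# Least-squares Gaussian fit on (log Pk, f0, log sigma), multi-start
# Nelder-Mead refined by box-constrained L-BFGS-B; f0 is confined to the
# fitted frequency range and sigma to [df/4, full range] so a narrow peak
# cannot be "fitted" by pushing the Gaussian outside the spectrum.
.fit_gaussian <- function(f, p, pk0, f00, s0) {
  rng <- range(f)
  df <- if (length(f) > 1) min(diff(f)) else 1
  obj <- function(par) {
    g <- exp(par[1]) * exp(-(f - par[2])^2 / (2 * exp(par[3])^2))
    sum((p - g)^2)
  }
  lower <- c(-745, rng[1], log(df / 4))
  upper <- c(log(max(max(p), pk0) * 10 + .Machine$double.xmin), rng[2],
             log(max(rng[2] - rng[1], df)))
  clamp <- function(par) pmin(pmax(par, lower), upper)
  starts <- list(c(log(pk0), f00, log(s0)),
                 c(log(pk0), f00, log(s0 * 5)),
                 c(log(pk0), f00, log(max(s0 / 5, df / 4))))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch({
      nm <- stats::optim(clamp(p0), obj, method = "Nelder-Mead",
                         control = list(maxit = 5000, reltol = 1e-14))
      stats::optim(clamp(nm$par), obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 2000, factr = 10))
    }, error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop(sprintf(
      "Gaussian fit failed to converge from starts near (Pk=%.3g, f0=%.3g, sigma=%.3g)",
      pk0, f00, s0), call. = FALSE)
  list(pk = exp(best$par[1]), f0 = best$par[2], sigma = exp(best$par[3]),
       sse = best$value, convergence = best$convergence)
}

# Half-width (in frequency units) at the given level around a local maximum.
.half_width <- function(f, p, i0, level) {
  n <- length(p)
  li <- i0
  while (li > 1L && p[li] > level) li <- li - 1L
  ri <- i0
  while (ri < n && p[ri] > level) ri <- ri + 1L
  f[ri] - f[li]
}

#' Prominence-gated Gaussian characterization of the dominant spectral peak
#'
#' Computes the relative prominence list Pro, then applies the fit-mode
#' switch: if the sample standard deviation of Pro exceeds one (a main peak
#' can be isolated), a Gaussian
#' `G(f) = Pk * exp(-(f - f0)^2 / (2 sigma^2))` is least-squares fitted to a
#' window of +/- 5 initial-FWHM around the most prominent peak (initial sigma
#' from the half-width at half-prominence); otherwise — including spectra
#' with fewer than two detected peaks, where the standard deviation is
#' undefined — the same form is fitted across the full spectrum. The switch
#' is a pure function of the Pro list.
#'
#' @param spectrum a [power_spectrum()].
#' @return an object of class `"spectral_peak_summary"`: `fit_mode`
#'   (`"main_peak"` or `"full_spectrum"`), `pro` (relative prominences,
#'   descending), `pk`, `f0_hz`, `sigma_hz`,
#'   `fwhm_hz` (`= 2 sqrt(2 log 2) sigma`), `normalized_amplitude`
#'   (`= pk / fwhm_hz`, the oscillation-amplitude measure), `mean_period_s`
#'   (`= 1 / f0`), `n`, `df`, fit diagnostics (`sse`, `convergence`).
#' @export
characterize_peak <- function(spectrum) {
  .assert(inherits(spectrum, "power_spectrum"),
          "spectrum must be a power_spectrum")
  pro <- peak_prominences(spectrum)
  f <- spectrum$frequencies
  p <- spectrum$power
  n <- length(p)
  fit_mode <- if (nrow(pro) >= 2L && stats::sd(pro$prominence) > 1)
    "main_peak" else "full_spectrum"

  if (fit_mode == "main_peak") {
    i0 <- pro$index[1]
    half_level <- p[i0] - pro$prominence_abs[1] / 2
    fwhm0 <- max(.half_width(f, p, i0, half_level), spectrum$df)
    in_win <- abs(f - f[i0]) <= 5 * fwhm0
    if (sum(in_win) < 7L)
      in_win <- seq_along(f) %in% seq(max(1L, i0 - 3L), min(n, i0 + 3L))
    fit <- .fit_gaussian(f[in_win], p[in_win], pk0 = p[i0], f00 = f[i0],
                         s0 = fwhm0 / (2 * sqrt(2 * log(2))))
  } else {
    i0 <- which.max(p)
    fwhm0 <- max(.half_width(f, p, i0, p[i0] / 2), spectrum$df)
    fit <- .fit_gaussian(f, p, pk0 = p[i0], f00 = f[i0],
                         s0 = fwhm0 / (2 * sqrt(2 * log(2))))
  }
  if (!is.finite(fit$f0) || fit$f0 <= 0)
    stop(sprintf("Gaussian fit returned non-positive center frequency %g",
                 fit$f0), call. = FALSE)
  fwhm <- 2 * sqrt(2 * log(2)) * fit$sigma
  structure(list(fit_mode = fit_mode, pro = pro$prominence, pk = fit$pk,
                 f0_hz = fit$f0, sigma_hz = fit$sigma, fwhm_hz = fwhm,
                 normalized_amplitude = fit$pk / fwhm,
                 mean_period_s = 1 / fit$f0, n = spectrum$n,
                 df = spectrum$df, sse = fit$sse,
                 convergence = fit$convergence),
            class = "spectral_peak_summary")
}

#' @export
print.spectral_peak_summary <- function(x, ...) {
  cat(sprintf(
    "spectral_peak_summary [%s]: Pk %.4g, f0 %.4g Hz (period %.4g s), FWHM %.4g Hz\n",
    x$fit_mode, x$pk, x$f0_hz, x$mean_period_s, x$fwhm_hz))
  cat(sprintf("  Pk/FWHM = %.4g; %d prominence(s), top %.3g\n",
              x$normalized_amplitude, length(x$pro),
              if (length(x$pro)) x$pro[1] else NA_real_))
  invisible(x)
}

#' Write a peak summary as JSON
#'
#' Layout: `{fit_mode, pro, pk, f0_hz, fwhm_hz, normalized_amplitude,
#' mean_period_s}`.
#'
#' @param x a [characterize_peak()] result.
#' @param path file path.
#' @return `path` invisibly.
#' @export
write_peak_summary <- function(x, path) {
  .assert(inherits(x, "spectral_peak_summary"),
          "x must be a spectral_peak_summary")
  jsonlite::write_json(
    list(fit_mode = x$fit_mode, pro = x$pro, pk = x$pk, f0_hz = x$f0_hz,
         fwhm_hz = x$fwhm_hz, normalized_amplitude = x$normalized_amplitude,
         mean_period_s = x$mean_period_s),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Entrainment index: pulsed versus constant-light peak amplitude
#'
#' The ratio of Gaussian-fit peak amplitudes `pulsed$pk / constant$pk`
#' (values near 1 indicate similar collective behavior), plus a variant using
#' the Pk/FWHM normalized amplitudes. Both summaries must derive from
#' signals of the same length and frequency resolution.
#'
#' @param pulsed,constant [characterize_peak()] results.
#' @return an object of class `"entrainment_index"`: `index`,
#'   `index_normalized`, `flagged` (TRUE when the constant-light peak is
#'   zero and the index undefined).
#' @export
entrainment_index <- function(pulsed, constant) {
  .assert(inherits(pulsed, "spectral_peak_summary") &&
            inherits(constant, "spectral_peak_summary"),
          "inputs must be spectral_peak_summary objects")
  .assert(pulsed$n == constant$n &&
            isTRUE(all.equal(pulsed$df, constant$df)),
          "summaries must come from same-length, same-resolution signals")
  if (!is.finite(constant$pk) || constant$pk <= 0)
    return(structure(list(index = NA_real_, index_normalized = NA_real_,
                          flagged = TRUE), class = "entrainment_index"))
  structure(list(index = pulsed$pk / constant$pk,
                 index_normalized = pulsed$normalized_amplitude /
                   constant$normalized_amplitude,
                 flagged = FALSE),
            class = "entrainment_index")
}

#' @export
print.entrainment_index <- function(x, ...) {
  if (x$flagged) cat("entrainment_index: undefined (constant-light Pk = 0)\n")
  else cat(sprintf("entrainment_index: %.4g (Pk ratio), %.4g (Pk/FWHM ratio)\n",
                   x$index, x$index_normalized))
  invisible(x)
}
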