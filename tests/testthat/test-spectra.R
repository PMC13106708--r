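test_that("preprocess removes trend and mean, and guards its preconditions", {
  n <- 128
  expect_equal(preprocess(rep(3.2, n))$signal, rep(0, n), tolerance = 1e-12)
  expect_equal(preprocess(0.01 * (1:n) + 5)$signal, rep(0, n),
               tolerance = 1e-9)
  tt <- 0:(n - 1)
  wave <- sin(2 * pi * tt / 16)
  # closed-form expectation: the residual of the wave after projecting out
  # span{1, t}, computed here by the normal equations directly
  X <- cbind(1, tt)
  wave_perp <- wave - X %*% solve(crossprod(X), crossprod(X, wave))
  got <- preprocess(wave + 0.03 * tt + 2, dt = 1)$signal
  expect_lt(sqrt(mean((got - wave_perp)^2)), 1e-9)
  expect_error(preprocess(rnorm(63)), ">= 64")
  expect_error(preprocess(rnorm(128), times = cumsum(runif(128, 0.5, 1.5))),
               "non-uniform")
})

test_that("preprocess drops invalid edge samples but refuses interior gaps", {
  x <- sin(2 * pi * (0:149) / 20)
  rs <- structure(list(times = 0:149, ratio = x,
                       valid = c(rep(FALSE, 5), rep(TRUE, 145)),
                       normalization = "none"), class = "ratio_series")
  pp <- preprocess(rs)
  expect_equal(pp$n_dropped, 5L)
  expect_length(pp$signal, 145L)
  rs$valid[70] <- FALSE
  expect_error(preprocess(rs), "non-uniform")
})

test_that("periodogram satisfies Parseval and resolves bin-centered tones", {
  n <- 256
  tt <- 0:(n - 1)
  x <- sin(2 * pi * 8 * tt / n)  # exactly bin 8
  ps <- power_spectrum(x, dt = 1)
  expect_equal(sum(ps$power), mean((x - mean(x))^2), tolerance = 1e-9)
  expect_equal(max(ps$power), 0.5, tolerance = 1e-9)
  expect_equal(ps$frequencies[which.max(ps$power)], 8 / n)
  expect_equal(sum(ps$power > 1e-20), 1L)  # all power in one bin
  # Parseval as a property, odd and even lengths, random signals
  set.seed(5)
  for (m in c(101, 128, 255)) {
    y <- rnorm(m)
    psy <- power_spectrum(y, dt = 0.5)
    expect_equal(sum(psy$power), mean((y - mean(y))^2), tolerance = 1e-9)
  }
  expect_error(power_spectrum(rnorm(32)), ">= 64")
})

test_that("periodogram equals a brute-force DFT oracle", {
  set.seed(6)
  x <- rnorm(128) + sin(2 * pi * (0:127) / 9.7)
  ps <- power_spectrum(x, dt = 2)
  oracle <- brute_force_periodogram(x, dt = 2)
  expect_equal(ps$frequencies, oracle$frequencies, tolerance = 1e-12)
  expect_equal(ps$power, oracle$power, tolerance = 1e-9)
})

test_that("white-noise spectra are flat on average", {
  # odd length: no unpaired Nyquist bin (which carries half the power of an
  # interior bin for real signals and would break flatness by construction)
  set.seed(7)
  n <- 255
  acc <- numeric(n %/% 2)
  for (i in 1:200) acc <- acc + power_spectrum(rnorm(n), dt = 1)$power
  acc <- acc / 200
  expect_lt(max(acc) / min(acc), 1.5)
})

test_that("peak prominences match the topographic definition", {
  mk_spec <- function(p) structure(
    list(frequencies = seq_along(p), power = p, df = 1, n = 2 * length(p),
         dt = 1, variance = sum(p)), class = "power_spectrum")
  # single triangular peak on a zero baseline
  p <- c(0, 1, 2, 3, 2, 1, 0)
  pro <- peak_prominences(mk_spec(p))
  expect_equal(nrow(pro), 1L)
  expect_equal(pro$prominence_abs, 3)
  expect_equal(pro$prominence, 3 / median(p))
  # two peaks separated by a valley: the lower peak's prominence is its
  # height above the valley floor; equal twins both carry full prominence
  p2 <- c(0, 4, 1, 3.5, 0)
  pro2 <- peak_prominences(mk_spec(p2))
  expect_equal(nrow(pro2), 2L)
  expect_equal(sort(pro2$prominence_abs), c(3.5 - 1, 4))
  twin <- peak_prominences(mk_spec(c(0, 4, 1, 4, 0)))
  expect_equal(twin$prominence_abs, c(4, 4))
  expect_equal(pro2, pro2[order(-pro2$prominence, pro2$frequency), ],
               ignore_attr = TRUE)
  # monotone spectrum: no interior maximum
  expect_equal(nrow(peak_prominences(mk_spec(1:10))), 0L)
})

test_that("prominences agree with an exhaustive level-set oracle", {
  mk_spec <- function(p) structure(
    list(frequencies = seq_along(p), power = p, df = 1, n = 2 * length(p),
         dt = 1, variance = sum(p)), class = "power_spectrum")
  set.seed(8)
  for (i in 1:20) {
    p <- round(rexp(sample(10:64, 1)), 3)
    got <- peak_prominences(mk_spec(p))
    want <- prominence_oracle(p)
    got <- got[order(got$index), c("index", "prominence_abs")]
    expect_equal(got, want, ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("characterize_peak recovers exact Gaussian spectra within 1%", {
  df <- 1 / 7100
  f <- seq(df, 0.5, by = df)
  for (par in list(c(pk = 2, f0 = 1 / 140, sigma = 1e-3),
                   c(pk = 0.05, f0 = 0.02, sigma = 5e-4))) {
    p <- par["pk"] * exp(-(f - par["f0"])^2 / (2 * par["sigma"]^2))
    spec <- structure(list(frequencies = f, power = p, df = df,
                           n = 2 * length(f), dt = 1, variance = sum(p)),
                      class = "power_spectrum")
    ck <- characterize_peak(spec)
    expect_equal(ck$pk, unname(par["pk"]), tolerance = 0.01)
    expect_equal(ck$f0_hz, unname(par["f0"]), tolerance = 0.01)
    expect_equal(ck$fwhm_hz, 2 * sqrt(2 * log(2)) * unname(par["sigma"]),
                 tolerance = 0.01)
    expect_equal(ck$mean_period_s * ck$f0_hz, 1, tolerance = 1e-12)
    expect_equal(ck$normalized_amplitude, ck$pk / ck$fwhm_hz)
  }
})

test_that("the fit-mode switch is a pure function of the prominence spread", {
  # flat spectrum plus tiny jitter: nothing stands out
  set.seed(9)
  f <- seq(0.001, 0.5, by = 0.001)
  p <- 1 + 1e-3 * runif(length(f))
  spec <- structure(list(frequencies = f, power = p, df = 0.001,
                         n = 2 * length(f), dt = 1, variance = sum(p)),
                    class = "power_spectrum")
  ck <- characterize_peak(spec)
  expect_identical(ck$fit_mode, "full_spectrum")
  pro <- peak_prominences(spec)
  expect_lte(sd(pro$prominence), 1)
  # re-running on the same spectrum gives the same mode (pure function)
  expect_identical(characterize_peak(spec)$fit_mode, ck$fit_mode)
  # a towering peak flips the switch
  p2 <- p
  p2[200] <- 50
  spec2 <- structure(list(frequencies = f, power = p2, df = 0.001,
                          n = 2 * length(f), dt = 1, variance = sum(p2)),
                     class = "power_spectrum")
  expect_identical(characterize_peak(spec2)$fit_mode, "main_peak")
})

test_that("fitted f0 lands within one bin for off-bin sinusoids", {
  n <- 1024
  tt <- 0:(n - 1)
  for (cycles in c(23.4, 37.7, 51.2)) {
    x <- sin(2 * pi * cycles * tt / n)
    ps <- power_spectrum(preprocess(x, dt = 1))
    ck <- characterize_peak(ps)
    expect_lt(abs(ck$f0_hz - cycles / n), ps$df)
  }
})

test_that("entrainment_index compares like with like", {
  f <- seq(1 / 512, 0.5, by = 1 / 512)
  mk <- function(pk) {
    p <- pk * exp(-(f - 0.01)^2 / (2 * 1e-3^2)) + 1e-6
    characterize_peak(structure(
      list(frequencies = f, power = p, df = 1 / 512, n = 512, dt = 1,
           variance = sum(p)), class = "power_spectrum"))
  }
  a <- mk(2)
  expect_equal(entrainment_index(a, a)$index, 1)
  b <- mk(1)
  expect_equal(entrainment_index(a, b)$index, 2, tolerance = 0.05)
  short <- mk(1)
  short$n <- 256
  expect_error(entrainment_index(a, short), "same-length")
})

test_that("peak summaries serialize to JSON with the documented layout", {
  f <- seq(1 / 512, 0.5, by = 1 / 512)
  p <- 2 * exp(-(f - 0.02)^2 / (2 * 1e-3^2)) + 1e-6
  ck <- characterize_peak(structure(
    list(frequencies = f, power = p, df = 1 / 512, n = 512, dt = 1,
         variance = sum(p)), class = "power_spectrum"))
  path <- withr::local_tempfile(fileext = ".json")
  write_peak_summary(ck, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(names(back), c("fit_mode", "pro", "pk", "f0_hz", "fwhm_hz",
                                 "normalized_amplitude", "mean_period_s"))
  expect_equal(back$pk, ck$pk)
})
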