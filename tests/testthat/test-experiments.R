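# Scaled-down runs (small n_cells / short duration via the sim override) keep
# this file fast; the default-scale behavior is exercised in test-acceptance.R.

tiny_sim <- list(n_cells = 60, duration = 900)

test_that("experiment specs validate and round-trip through JSON", {
  expect_error(experiment_spec("wavelength_scan", replicates = 3,
                               seeds = 1:2), "length")
  expect_error(experiment_spec("composed_rb",
                               protocol = list(red_wavelength = 430)),
               "one blue and one red|red")
  expect_error(experiment_spec("pulsed", protocol = list(wavelengths = 530)),
               "660")
  spec <- experiment_spec("wavelength_scan", genotypes = "WT",
                          replicates = 2, seeds = c(4, 9),
                          protocol = list(wavelengths = c(430, 530)),
                          sim = tiny_sim)
  path <- withr::local_tempfile(fileext = ".json")
  write_experiment_spec(spec, path)
  spec2 <- read_experiment_spec(path)
  expect_equal(spec2$seeds, spec$seeds)
  expect_equal(spec2$protocol$wavelengths, spec$protocol$wavelengths)
  expect_equal(spec2$sim$n_cells, 60)
})

test_that("wavelength scan runs, validates its schema, and separates B from G", {
  spec <- experiment_spec("wavelength_scan", genotypes = "WT",
                          replicates = 2, seeds = 1:2,
                          protocol = list(wavelengths = c(430, 530),
                                          duration = 1800),
                          sim = list(n_cells = 150))
  res <- suppressMessages(run_wavelength_scan(spec))
  expect_true(validate_experiment_summary(res$summary, "wavelength_scan"))
  amp <- function(wl) res$summary$amplitude_mean[res$summary$wavelength == wl]
  expect_gt(amp(430), 5 * amp(530))
  expect_equal(nrow(res$summary), 2L)
})

test_that("identical seeds give zero replicate SD", {
  spec <- experiment_spec("wavelength_scan", genotypes = "WT",
                          replicates = 2, seeds = c(3, 3),
                          protocol = list(wavelengths = 430),
                          sim = tiny_sim)
  res <- suppressMessages(run_wavelength_scan(spec))
  expect_equal(res$summary$amplitude_sd, 0)
  expect_equal(res$summary$period_sd, 0)
})

test_that("experiment outputs are byte-identical across reruns", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  mk <- function(dir) experiment_spec("wavelength_scan", genotypes = "WT",
                                      replicates = 1, seeds = 5,
                                      protocol = list(wavelengths = 430),
                                      sim = tiny_sim, output_dir = dir)
  suppressMessages(run_wavelength_scan(mk(d1), keep_series = TRUE))
  suppressMessages(run_wavelength_scan(mk(d2), keep_series = TRUE))
  files <- sort(list.files(d1))
  expect_gt(length(files), 0)
  expect_identical(files, sort(list.files(d2)))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("composed_rb produces per-arm fits with confidence intervals", {
  spec <- experiment_spec("composed_rb", genotypes = "WT",
                          replicates = 2, seeds = 1:2,
                          protocol = list(red_irradiances = c(0, 6),
                                          control_intensities = 12,
                                          duration = 1800),
                          sim = list(n_cells = 150))
  res <- suppressMessages(run_composed_rb(spec))
  expect_true(validate_experiment_summary(res$summary, "composed_rb"))
  expect_named(res$fits, c("rb", "control"))
  expect_length(res$fits$rb$ci95, 2L)
  # normalization anchored at the R:B = 0 baseline
  base <- res$summary$norm_amplitude_mean[res$summary$arm == "rb" &
                                            res$summary$rb_ratio == 0]
  expect_equal(base, 1, tolerance = 1e-12)
})

test_that("pulsed family reports entrainment indices per strain", {
  spec <- experiment_spec("pulsed", genotypes = c("WT", "KO"),
                          replicates = 1, seeds = 2,
                          protocol = list(wavelengths = 660,
                                          duration = 1800),
                          sim = list(n_cells = 150))
  res <- suppressMessages(run_pulsed(spec))
  expect_true(validate_experiment_summary(res$summary, "pulsed"))
  wt <- res$summary[res$summary$genotype == "WT", ]
  ko <- res$summary[res$summary$genotype == "KO", ]
  expect_gt(wt$entrainment_index_mean, 5)
  expect_gt(wt$pulsed_pk_mean / ko$pulsed_pk_mean, 5)
  expect_named(res$pulsed_vs_blue, c("WT", "KO"))
})

test_that("fluorescence family finds coincident two-band peaks for WT only", {
  spec <- experiment_spec("fluorescence", genotypes = c("WT", "KO"),
                          replicates = 1, seeds = 1,
                          protocol = list(duration = 1500),
                          sim = list(n_cells = 150))
  res <- suppressMessages(run_fluorescence(spec))
  expect_true(validate_experiment_summary(res$summary, "fluorescence"))
  wt <- res$summary[res$summary$genotype == "WT", ]
  expect_lt(abs(wt$f0_R - wt$f0_FR), res$genotypes$WT[[1]]$spectrum_R$df)
  expect_gt(wt$band_correlation, 0.99)
})

test_that("analysis refuses series truncated below 64 samples", {
  spec <- experiment_spec("fluorescence", genotypes = "WT", replicates = 1,
                          seeds = 1, protocol = list(duration = 160),
                          sim = list(n_cells = 40, duration = 160))
  # only 60 post-mixing samples survive the 100 s mixing exclusion
  expect_error(suppressMessages(run_fluorescence(spec)), ">= 64")
})

test_that("run_experiment dispatches on family", {
  spec <- experiment_spec("wavelength_scan", genotypes = "WT",
                          replicates = 1, seeds = 7,
                          protocol = list(wavelengths = 430),
                          sim = tiny_sim)
  res <- suppressMessages(run_experiment(spec))
  expect_s3_class(res, "wavelength_scan_result")
})

test_that("fixtures are emitted and re-analyzable from CSV", {
  d <- withr::local_tempdir()
  suppressMessages(emit_fixtures(d, seed = 2))
  expect_true(file.exists(file.path(d, "fixture_ratio.csv")))
  res <- analyze_ratio_csv(file.path(d, "fixture_ratio.csv"), tmin = 100)
  expect_s3_class(res$summary, "spectral_peak_summary")
  expect_gt(res$summary$mean_period_s, 0)
})
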