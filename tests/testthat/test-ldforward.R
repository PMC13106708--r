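test_that("size-class grid is 32 contiguous log-spaced bins", {
  g <- size_class_grid()
  expect_identical(g$n_classes, 32L)
  expect_length(g$edges, 33L)
  expect_true(all(diff(g$edges) > 0))
  ratios <- g$edges[-1] / g$edges[-33]
  expect_lt(diff(range(ratios)) / mean(ratios), 1e-9)
  expect_equal(g$edges[1], 1.25)
  expect_equal(g$edges[33], 250)
})

test_that("default orientation bands match the instrument constants", {
  b <- default_size_bands()
  expect_equal(b$vd1$lo, 2.5)
  expect_equal(b$vd1$hi, 3.5)
  expect_equal(b$vd2$lo, 7.33)
  expect_equal(b$vd2$hi, 14)
  expect_lte(b$vd1$hi, b$vd2$lo)
})

test_that("apparent_length projects a tilted prolate spheroid", {
  geom <- cell_geometry()
  expect_equal(apparent_length(geom, 0), 10.5)
  expect_equal(apparent_length(geom, pi / 2), 3.0)
  expect_equal(apparent_length(geom, pi), 10.5)  # periodic
  l <- apparent_length(geom, 0.35)
  expect_gt(l, 3.0)
  expect_lt(l, 10.5)
  for (beta in c(0.1, 0.35, 0.6, 1.2))
    expect_equal(apparent_length(geom, beta),
                 apparent_length_oracle(10.5, 3.0, beta),
                 tolerance = 1e-3)
})

test_that("observe conserves deposited volume and honors the geometry", {
  set.seed(1)
  traj <- make_trajectory(matrix(runif(40 * 8, -pi, pi), 40, 8))
  scs <- observe_population(traj, noise_cv = 0)
  # total deposited volume per time step: cell_density * spheroid volume
  total <- 3e8 * pi / 6 * 10.5 * 3^2 * 1e-9
  expect_equal(rowSums(scs$volume_concentration), rep(total, 40),
               tolerance = 1e-12)
  expect_true(all(scs$volume_concentration >= 0))
  expect_identical(ncol(scs$volume_concentration), 32L)
})

test_that("observe reproduces a hand-computed two-cell deposit", {
  # two cells at fixed phases: beta = 0.35 + 0.25 * sin(phi)
  traj <- make_trajectory(matrix(c(0, pi / 2), 1, 2), cell_density = 1e9)
  scs <- observe_population(traj, noise_cv = 0)
  g <- size_class_grid()
  r1 <- 10.5
  r2 <- 3.0
  share <- 1e9 * pi / 6 * r1 * r2^2 * 1e-9 / 2
  beta <- 0.35 + 0.25 * sin(c(0, pi / 2))
  len <- sqrt(r1^2 * cos(beta)^2 + r2^2 * sin(beta)^2)
  w <- (len - r2) / (r1 - r2)
  expected <- numeric(32)
  for (i in 1:2) {
    b <- findInterval(len[i], g$edges)
    expected[b] <- expected[b] + w[i] * share
  }
  bm <- findInterval(r2, g$edges)
  expected[bm] <- expected[bm] + share * sum(1 - w)
  expect_equal(as.numeric(scs$volume_concentration[1, ]), expected,
               tolerance = 1e-12)
})

test_that("end-on cells put everything in the minor-axis band", {
  # mean tilt ~ pi/2, zero wobble: cells seen end-on
  traj <- make_trajectory(matrix(0, 5, 10), mean_tilt = 1.5707,
                          wobble_amplitude = 0)
  scs <- observe_population(traj, noise_cv = 0)
  centers <- scs$grid$centers
  vd <- default_size_bands()
  in2 <- centers >= vd$vd2$lo & centers <= vd$vd2$hi
  in1 <- centers >= vd$vd1$lo & centers <= vd$vd1$hi
  expect_equal(sum(scs$volume_concentration[, in2]), 0)
  expect_equal(sum(scs$volume_concentration[, in1]),
               sum(scs$volume_concentration), tolerance = 1e-12)
  # VD2 empty -> Ratio invalid everywhere -> error
  expect_error(ratio_series(scs), "invalid")
})

test_that("a static population observed without noise is constant", {
  traj <- make_trajectory(matrix(0.4, 20, 6))
  scs <- observe_population(traj, noise_cv = 0)
  expect_equal(scs$volume_concentration,
               scs$volume_concentration[rep(1, 20), ])
  rs <- ratio_series(scs)
  expect_equal(diff(range(rs$ratio)), 0, tolerance = 1e-12)
})

test_that("tilting further end-on never decreases the Ratio", {
  set.seed(2)
  phases <- matrix(runif(30 * 12, -pi, pi), 30, 12)
  r_at <- function(tilt) {
    traj <- make_trajectory(phases, mean_tilt = tilt)
    mean(ratio_series(observe_population(traj, noise_cv = 0))$ratio)
  }
  ratios <- vapply(c(0.3, 0.45, 0.6, 0.9), r_at, numeric(1))
  expect_true(all(diff(ratios) >= 0))
})

test_that("ratio_series does band-center arithmetic and flags invalid times", {
  g <- size_class_grid()
  vd <- default_size_bands()
  in1 <- which(g$centers >= vd$vd1$lo & g$centers <= vd$vd1$hi)
  in2 <- which(g$centers >= vd$vd2$lo & g$centers <= vd$vd2$hi)
  vc <- matrix(0, 3, 32)
  vc[, in1] <- 3 / length(in1)  # VD1 sums to 3
  vc[, in2] <- 8 / length(in2)  # VD2 sums to 8
  vc[2, in2] <- 0               # one invalid time point
  rs <- ratio_series(make_size_class_series(vc))
  expect_equal(rs$ratio[c(1, 3)], c(3 / 8, 3 / 8))
  expect_false(rs$valid[2])
  expect_true(is.na(rs$ratio[2]))
  expect_equal(sum(rs$valid), 2L)
})

test_that("coherent wobbling shows up in the Ratio periodogram at 1/140 Hz", {
  tt <- 0:1199
  phases <- matrix(2 * pi * tt / 140, ncol = 1)[, rep(1, 20)]
  traj <- make_trajectory(phases)
  set.seed(3)
  rs <- ratio_series(observe_population(traj, noise_cv = 0.05))
  ps <- power_spectrum(preprocess(rs))
  f_peak <- ps$frequencies[which.max(ps$power)]
  f_bins <- abs(ps$frequencies - 1 / 140)
  expect_equal(f_peak, ps$frequencies[which.min(f_bins)])
  # dominant frequency is omega, not its double
  expect_lt(abs(f_peak - 1 / 140), abs(f_peak - 2 / 140))
})

test_that("out-of-range apparent lengths are clamped and counted", {
  grid <- size_class_grid(n_classes = 8, range_um = c(2, 9))
  traj <- make_trajectory(matrix(c(-pi / 2, pi / 2), 1, 2))
  expect_message(scs <- observe_population(traj, grid = grid, noise_cv = 0),
                 "clamped")
  expect_gt(scs$n_out_of_range, 0)
})

test_that("size-class and ratio series round-trip through CSV", {
  traj <- make_trajectory(matrix(runif(10 * 4, -pi, pi), 10, 4))
  set.seed(4)
  scs <- observe_population(traj)
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_size_class_series(scs, p1)
  back <- read_size_class_series(p1)
  expect_equal(back$volume_concentration, scs$volume_concentration)
  expect_equal(back$grid$edges, scs$grid$edges)
  rs <- ratio_series(scs)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_ratio_series(rs, p2)
  back2 <- read_ratio_series(p2)
  expect_equal(back2$ratio, rs$ratio)
  expect_equal(back2$valid, rs$valid)
})
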