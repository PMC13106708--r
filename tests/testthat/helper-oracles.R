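# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's own code paths: brute-force transforms, level-set
# searches, point clouds and explicit ODE integration.

# O(n^2) discrete Fourier transform periodogram with the package's variance
# normalization (positive half-axis, zero frequency excluded).
brute_force_periodogram <- function(x, dt) {
  n <- length(x)
  x <- x - mean(x)
  half <- n %/% 2L
  power <- vapply(seq_len(half), function(k) {
    ang <- -2 * pi * k * (seq_len(n) - 1) / n
    re <- sum(x * cos(ang))
    im <- sum(x * sin(ang))
    2 * (re^2 + im^2) / n^2
  }, numeric(1))
  if (n %% 2L == 0L) power[half] <- power[half] / 2
  list(frequencies = seq_len(half) / (n * dt), power = power)
}

# Exhaustive contour-search topographic prominence, per the "higher of the
# two bounding minima along the lower enclosing contour" definition: on each
# side of a peak, the enclosing contour extends over every position j whose
# intervening terrain max(p[j..peak]) does not exceed the peak; the side base
# is the minimum over that window, and the prominence subtracts the higher
# base. Implemented with explicit subrange max/min checks rather than the
# package's directional scan.
prominence_oracle <- function(p) {
  n <- length(p)
  out <- list()
  for (i in seq(2, n - 1)) {
    if (!(p[i] > p[i - 1] && p[i] > p[i + 1])) next
    left <- seq_len(i - 1)
    in_left <- vapply(left, function(j) max(p[j:(i - 1)]) <= p[i],
                      logical(1))
    left_base <- min(p[left[in_left]])
    right <- seq(i + 1, n)
    in_right <- vapply(right, function(j) max(p[(i + 1):j]) <= p[i],
                       logical(1))
    right_base <- min(p[right[in_right]])
    out[[length(out) + 1L]] <- data.frame(
      index = i, prominence_abs = p[i] - max(left_base, right_base))
  }
  if (!length(out)) return(data.frame(index = integer(0),
                                      prominence_abs = numeric(0)))
  do.call(rbind, out)
}

# Explicit Euler integration of the two-state photoconversion ODE
# da/dt = k_act (1 - a) - k_deact a, run to convergence.
photoconversion_ode_oracle <- function(k_act, k_deact, a0 = 0.5,
                                       dt = 1e-3, t_end = 2000) {
  a <- a0
  for (i in seq_len(round(t_end / dt)))
    a <- a + dt * (k_act * (1 - a) - k_deact * a)
  a
}

# Point-cloud projection oracle for the apparent major extent of a tilted
# prolate spheroid: sample the surface, rotate the major axis by beta out of
# the detector (x-z) plane, project, and take the maximal caliper extent.
apparent_length_oracle <- function(r1, r2, beta, n_u = 120, n_v = 60,
                                   n_dir = 720) {
  a <- r1 / 2
  b <- r2 / 2
  u <- seq(0, 2 * pi, length.out = n_u)
  v <- seq(0, pi, length.out = n_v)
  g <- expand.grid(u = u, v = v)
  x <- b * sin(g$v) * cos(g$u)
  y <- b * sin(g$v) * sin(g$u)
  z <- a * cos(g$v)
  # rotate about x: major axis (0,0,1) -> (0, sin beta, cos beta)
  y2 <- y * cos(beta) - z * sin(beta)
  z2 <- y * sin(beta) + z * cos(beta)
  px <- x
  pz <- z2
  theta <- seq(0, pi, length.out = n_dir)
  max(vapply(theta, function(th) {
    s <- px * cos(th) + pz * sin(th)
    max(s) - min(s)
  }, numeric(1)))
}

# Monte-Carlo null for the order parameter of n independent uniform phases.
incoherent_R_samples <- function(n, reps, seed) {
  set.seed(seed)
  vapply(seq_len(reps), function(i) {
    ph <- stats::runif(n, -pi, pi)
    sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
  }, numeric(1))
}
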