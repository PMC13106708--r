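#' Prolate-spheroid cell geometry
#'
#' Default axes follow the fusiform P. tricornutum morphotype: major axis
#' 10.5 um (inside the VD2 size band) and minor axis 3.0 um (inside VD1).
#'
#' @param major_axis r1, um (> minor_axis).
#' @param minor_axis r2, um (> 0).
#' @return an object of class `"cell_geometry"`.
#' @export
cell_geometry <- function(major_axis = 10.5, minor_axis = 3.0) {
  .assert(.is_number(minor_axis) && minor_axis > 0, "minor_axis must be > 0")
  .assert(.is_number(major_axis) && major_axis > minor_axis,
          "major_axis must exceed minor_axis")
  structure(list(major_axis = major_axis, minor_axis = minor_axis),
            class = "cell_geometry")
}

#' Logarithmically spaced 32-bin size-class grid
#'
#' Mirrors a 32-ring laser-diffraction detector: bin edges are log-spaced
#' (constant edge ratio) over a configurable range, default 1.25-250 um (a
#' common type-B instrument convention).
#'
#' @param n_classes number of contiguous bins (instrument-native default 32).
#' @param range_um numeric length-2, lower and upper edge in um.
#' @return an object of class `"size_class_grid"` with `edges` (length
#'   `n_classes + 1`) and geometric-mean `centers`.
#' @export
size_class_grid <- function(n_classes = 32, range_um = c(1.25, 250)) {
  .assert(.is_number(n_classes) && n_classes >= 2, "n_classes must be >= 2")
  .assert(is.numeric(range_um) && length(range_um) == 2L &&
            all(range_um > 0) && range_um[2] > range_um[1],
          "range_um must be two increasing positive numbers")
  edges <- exp(seq(log(range_um[1]), log(range_um[2]),
                   length.out = n_classes + 1))
  structure(list(n_classes = as.integer(n_classes), edges = edges,
                 centers = sqrt(edges[-1] * edges[-(n_classes + 1)])),
            class = "size_class_grid")
}

#' A size band of the laser-diffraction size distribution
#'
#' @param lo,hi band limits, um (`lo < hi`).
#' @param role `"VD1"` (minor-axis band) or `"VD2"` (major-axis band).
#' @return an object of class `"size_band"`.
#' @export
size_band <- function(lo, hi, role = c("VD1", "VD2")) {
  role <- match.arg(role)
  .assert(.is_number(lo) && .is_number(hi) && lo > 0 && lo < hi,
          "need 0 < lo < hi")
  structure(list(lo = lo, hi = hi, role = role), class = "size_band")
}

#' Default VD1/VD2 orientation bands
#'
#' VD1 = 2.5-3.5 um (minor axis), VD2 = 7.33-14 um (major axis).
#'
#' @return a list with elements `vd1` and `vd2`.
#' @export
default_size_bands <- function() {
  list(vd1 = size_band(2.5, 3.5, "VD1"), vd2 = size_band(7.33, 14, "VD2"))
}

#' Apparent (projected) major extent of a tilted prolate spheroid
#'
#' For a spheroid with axes `r1 > r2` whose major axis makes angle `beta`
#' with the detector plane, the projected major extent is
#' `sqrt(r1^2 cos(beta)^2 + r2^2 sin(beta)^2)`. Periodic in `beta`; equals
#' `r1` face-on (`beta = 0`) and `r2` end-on (`beta = pi/2`).
#'
#' @param geometry a [cell_geometry()].
#' @param beta tilt angle(s) from the detector plane, rad (vector or matrix).
#' @return apparent length(s), um, same shape as `beta`.
#' @export
apparent_length <- function(geometry, beta) {
  .assert(inherits(geometry, "cell_geometry"),
          "geometry must be a cell_geometry")
  sqrt(geometry$major_axis^2 * cos(beta)^2 +
         geometry$minor_axis^2 * sin(beta)^2)
}

#' Forward laser-diffraction observation of a population trajectory
#'
#' Converts per-cell tilt angles into a time-by-32 size-class
#' volume-concentration series. Each cell's volume share (total concentration
#' = `cell_density * spheroid volume`) is split between the bin containing
#' its apparent major extent and the bin containing the minor axis `r2`, with
#' orientation weight `w(beta) = (L(beta) - r2) / (r1 - r2)`: a face-on cell
#' registers entirely at its major length, an end-on cell entirely at its
#' minor length, so tilting moves signal from the VD2 band toward the VD1
#' band ("opposite behavior" of the two bands). The per-time bin sum is
#' exactly conserved before noise. Multiplicative lognormal measurement noise
#' (mean 1, coefficient of variation `noise_cv`) is applied per bin and time
#' from the current RNG state.
#'
#' @param trajectory a [simulate_population()] result with kept phases.
#' @param geometry a [cell_geometry()].
#' @param grid a [size_class_grid()].
#' @param noise_cv measurement noise CV (>= 0; default 0.05).
#' @return an object of class `"size_class_series"`: `times`,
#'   `volume_concentration` (time x n_classes matrix, uL/L), `grid`,
#'   `n_out_of_range` (count of apparent lengths clamped to edge bins).
#' @export
observe_population <- function(trajectory, geometry = cell_geometry(),
                               grid = size_class_grid(), noise_cv = 0.05) {
  .assert(inherits(trajectory, "population_trajectory"),
          "trajectory must be a population_trajectory")
  .assert(inherits(grid, "size_class_grid"), "grid must be a size_class_grid")
  .assert(.is_number(noise_cv) && noise_cv >= 0, "noise_cv must be >= 0")
  tilts <- population_tilts(trajectory)
  n_t <- nrow(tilts)
  n <- ncol(tilts)
  r1 <- geometry$major_axis
  r2 <- geometry$minor_axis
  nb <- grid$n_classes

  apparent <- apparent_length(geometry, tilts)
  # volume of a prolate spheroid with full axes r1, r2: pi/6 * r1 * r2^2 um^3
  # 1 um^3 = 1e-9 uL -> total concentration in uL/L
  total_vc <- trajectory$config$cell_density * pi / 6 * r1 * r2^2 * 1e-9
  share <- total_vc / n

  w <- (apparent - r2) / (r1 - r2)
  w <- pmin(pmax(w, 0), 1)

  bin_of <- function(x) findInterval(x, grid$edges, rightmost.closed = TRUE)
  bins <- bin_of(apparent)
  oor <- bins < 1L | bins > nb
  n_oor <- sum(oor)
  if (n_oor > 0) {
    bins[bins < 1L] <- 1L
    bins[bins > nb] <- nb
    message(sprintf(
      "observe_population: %d apparent length(s) outside grid range, clamped to edge bins",
      n_oor))
  }
  bin_minor <- bin_of(r2)
  .assert(bin_minor >= 1L && bin_minor <= nb,
          "minor axis lies outside the size grid")

  vc <- matrix(0, n_t, nb)
  # major-extent deposits, aggregated by (time, bin) linear index
  idx <- as.vector(row(apparent)) + n_t * (as.vector(bins) - 1L)
  agg <- rowsum(as.vector(w) * share, idx)
  vc[as.integer(rownames(agg))] <- agg
  # minor-extent deposits always land in the bin containing r2
  vc[, bin_minor] <- vc[, bin_minor] + share * rowSums(1 - w)

  if (noise_cv > 0) {
    sl <- sqrt(log(1 + noise_cv^2))
    vc <- vc * matrix(stats::rlnorm(length(vc), -sl^2 / 2, sl), n_t, nb)
  }

  structure(list(times = trajectory$times, volume_concentration = vc,
                 grid = grid, n_out_of_range = n_oor),
            class = "size_class_series")
}

#' @export
print.size_class_series <- function(x, ...) {
  cat(sprintf(
    "size_class_series: %d samples x %d bins, total VC %.3g uL/L (t = 0)\n",
    length(x$times), x$grid$n_classes, sum(x$volume_concentration[1, ])))
  invisible(x)
}

#' The Ratio orientation proxy from two size bands
#'
#' `Ratio(t) = sum(VD1 bins) / sum(VD2 bins)`, where a bin belongs to a band
#' iff its (geometric-mean) center falls inside `[lo, hi]` — stable under
#' grid refinement. Times where the VD2 sum is zero are flagged invalid
#' (`ratio = NA`), not dropped; an all-invalid series is an error.
#'
#' @param series a [observe_population()] result.
#' @param vd1,vd2 [size_band()]s; default the instrument bands
#'   2.5-3.5 um and 7.33-14 um.
#' @return an object of class `"ratio_series"`: `times`, `ratio`, `valid`,
#'   `normalization` (`"none"`).
#' @export
ratio_series <- function(series, vd1 = default_size_bands()$vd1,
                         vd2 = default_size_bands()$vd2) {
  .assert(inherits(series, "size_class_series"),
          "series must be a size_class_series")
  .assert(inherits(vd1, "size_band") && inherits(vd2, "size_band"),
          "vd1 and vd2 must be size_band objects")
  .assert(vd1$hi <= vd2$lo, "VD1 must lie entirely below VD2")
  grid <- series$grid
  rng <- range(grid$edges)
  .assert(vd1$lo >= rng[1] && vd2$hi <= rng[2],
          "bands must lie within the grid range")
  centers <- grid$centers
  in1 <- centers >= vd1$lo & centers <= vd1$hi
  in2 <- centers >= vd2$lo & centers <= vd2$hi
  .assert(any(in1) && any(in2), "each band must contain at least one bin center")
  s1 <- rowSums(series$volume_concentration[, in1, drop = FALSE])
  s2 <- rowSums(series$volume_concentration[, in2, drop = FALSE])
  valid <- s2 > 0
  if (!any(valid)) stop("all time points invalid: VD2 sum is zero everywhere",
                        call. = FALSE)
  ratio <- ifelse(valid, s1 / s2, NA_real_)
  structure(list(times = series$times, ratio = ratio, valid = valid,
                 normalization = "none"),
            class = "ratio_series")
}

#' @export
print.ratio_series <- function(x, ...) {
  cat(sprintf(
    "ratio_series: %d samples (%d valid), mean Ratio %.4g [%s]\n",
    length(x$times), sum(x$valid), mean(x$ratio, na.rm = TRUE),
    x$normalization))
  invisible(x)
}

#' Restrict a ratio series to times at or after a cutoff
#'
#' Used to exclude the mixing (agitation) phase from spectral analysis.
#'
#' @param x a [ratio_series()].
#' @param tmin keep samples with `times >= tmin`, s.
#' @return a [ratio_series()].
#' @export
trim_ratio_series <- function(x, tmin) {
  .assert(inherits(x, "ratio_series"), "x must be a ratio_series")
  keep <- x$times >= tmin
  .assert(any(keep), "no samples at or after tmin")
  structure(list(times = x$times[keep], ratio = x$ratio[keep],
                 valid = x$valid[keep], normalization = x$normalization),
            class = "ratio_series")
}

#' Size-class and ratio series CSV I/O
#'
#' Size-class CSVs carry the grid edges in '#'-prefixed metadata comment
#' lines followed by a header `time_s, vc_01, ..., vc_NN`. Ratio CSVs have
#' columns `time_s, ratio, valid`.
#'
#' @param series,x objects to write.
#' @param path file path.
#' @return read functions return the corresponding object; write functions
#'   return `path` invisibly.
#' @export
write_size_class_series <- function(series, path) {
  .assert(inherits(series, "size_class_series"),
          "series must be a size_class_series")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# size_class_edges_um: %s",
                     paste(format(series$grid$edges, digits = 15),
                           collapse = " ")), con)
  df <- as.data.frame(series$volume_concentration)
  names(df) <- sprintf("vc_%02d", seq_len(ncol(df)))
  df <- cbind(data.frame(time_s = series$times), df)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_size_class_series
#' @export
read_size_class_series <- function(path) {
  header <- readLines(path, n = 1L)
  .assert(startsWith(header, "# size_class_edges_um:"),
          "missing size-class edge metadata line")
  edges <- as.numeric(strsplit(sub("^# size_class_edges_um: *", "", header),
                               " +")[[1]])
  df <- utils::read.csv(path, comment.char = "#")
  vc <- as.matrix(df[, grep("^vc_", names(df)), drop = FALSE])
  dimnames(vc) <- NULL
  n <- ncol(vc)
  grid <- structure(list(n_classes = n, edges = edges,
                         centers = sqrt(edges[-1] * edges[-(n + 1)])),
                    class = "size_class_grid")
  structure(list(times = df$time_s, volume_concentration = vc, grid = grid,
                 n_out_of_range = NA_integer_),
            class = "size_class_series")
}

#' @rdname write_size_class_series
#' @export
write_ratio_series <- function(x, path) {
  .assert(inherits(x, "ratio_series"), "x must be a ratio_series")
  utils::write.csv(data.frame(time_s = x$times, ratio = x$ratio,
                              valid = x$valid),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_size_class_series
#' @export
read_ratio_series <- function(path) {
  df <- utils::read.csv(path)
  .assert(all(c("time_s", "ratio") %in% names(df)),
          "ratio CSV needs columns time_s and ratio")
  valid <- if ("valid" %in% names(df)) as.logical(df$valid) else
    is.finite(df$ratio)
  structure(list(times = df$time_s, ratio = df$ratio, valid = valid,
                 normalization = "none"),
            class = "ratio_series")
}
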