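#' Wall shear stress time series
#'
#' A `wss_series` is a long-format tibble of wall shear stress vectors:
#' one row per wall point and time sample, columns `point_id`,
#' `arc_length_m`, `time_s`, `wss_x`, `wss_y` (Pa), with the cardiac
#' period attached as an attribute. Time samples must be uniform per point
#' and span exactly one period (the sample at `t = T` is identified with
#' the first by periodicity). Quadrature over the cycle uses the
#' trapezoidal rule on the periodic grid, which for a uniform periodic
#' grid reduces to the plain sample mean and is exact for piecewise-linear
#' periodic integrands.
#'
#' @param df A data frame with the columns above (extra columns such as
#'   wall coordinates are preserved).
#' @param period Cycle period T, s.
#' @return A tibble of class `wss_series`.
#' @export
wss_series <- function(df, period = 1) {
  need <- c("point_id", "arc_length_m", "time_s", "wss_x", "wss_y")
  if (!all(need %in% names(df))) {
    stop("wss_series needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(is.finite(df$wss_x)) || !all(is.finite(df$wss_y))) {
    stop("WSS values must be finite", call. = FALSE)
  }
  tt <- sort(unique(df$time_s))
  if (length(tt) < 2L) {
    stop("wss_series needs at least 2 time samples", call. = FALSE)
  }
  dt <- diff(tt)
  if (any(abs(dt - dt[1]) > 1e-8 * max(dt))) {
    stop("wss_series time samples must be uniform", call. = FALSE)
  }
  if (abs(length(tt) * dt[1] - period) > 1e-6 * period) {
    stop("time samples must span exactly one period", call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "period") <- period
  class(out) <- unique(c("wss_series", class(out)))
  out
}

#' @export
print.wss_series <- function(x, ...) {
  cat(sprintf("<wss_series> %d wall points x %d times over %g s\n",
              length(unique(x$point_id)), length(unique(x$time_s)),
              attr(x, "period")))
  NextMethod()
}

series_period <- function(series) attr(series, "period", exact = TRUE)

#' Time-averaged wall shear stress (TAWSS)
#'
#' Cycle average of the wall shear stress magnitude,
#' \eqn{\mathrm{TAWSS} = (1/T)\int_0^T |\mathbf{WSS}(t)|\,dt}, evaluated
#' per wall point by periodic trapezoidal quadrature (the sample mean on
#' the uniform periodic grid).
#'
#' @param series A [wss_series()].
#' @return A tibble with one row per wall point: `point_id`,
#'   `arc_length_m`, `tawss` (Pa).
#' @export
tawss <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  dplyr::summarise(dplyr::group_by(series, .data$point_id),
                   arc_length_m = .data$arc_length_m[1],
                   tawss = mean(sqrt(.data$wss_x^2 + .data$wss_y^2)),
                   .groups = "drop")
}

#' Oscillatory shear index (OSI)
#'
#' \deqn{\mathrm{OSI} = \frac{1}{2}\left(1 -
#'   \frac{|\int_0^T \mathbf{WSS}\,dt|}{\int_0^T |\mathbf{WSS}|\,dt}\right)}
#' with the vector integral in the numerator and the magnitude integral in
#' the denominator (the normalization that guarantees OSI in [0, 0.5]).
#' OSI is 0 for a WSS vector that keeps one direction over the whole
#' cycle and 0.5 for equally oscillatory directions. Points with zero
#' magnitude integral are defined to have OSI 0. The result is clamped to
#' [0, 0.5] against round-off.
#'
#' @param series A [wss_series()].
#' @return A tibble per wall point: `point_id`, `arc_length_m`, `osi`.
#' @export
osi <- function(series) {
  stopifnot(inherits(series, "wss_series"))
  out <- dplyr::summarise(
    dplyr::group_by(series, .data$point_id),
    arc_length_m = .data$arc_length_m[1],
    .mean_mag = mean(sqrt(.data$wss_x^2 + .data$wss_y^2)),
    .mag_mean = sqrt(mean(.data$wss_x)^2 + mean(.data$wss_y)^2),
    .groups = "drop")
  out$osi <- ifelse(out$.mean_mag > 0,
                    pmin(pmax(0.5 * (1 - out$.mag_mean / out$.mean_mag), 0),
                         0.5),
                    0)
  out[, c("point_id", "arc_length_m", "osi")]
}

#' Relative residence time (RRT)
#'
#' \eqn{\mathrm{RRT} = 1/[(1 - 2\,\mathrm{OSI})\,\mathrm{TAWSS}]} in 1/Pa,
#' a proxy for near-wall particle residence. The expression is singular at
#' OSI = 0.5 or TAWSS = 0; such points are capped at a configurable
#' ceiling and flagged `degenerate` rather than returned as infinities.
#'
#' @param maps A tibble holding at least `tawss` and `osi` columns (e.g.
#'   from joining [tawss()] and [osi()], or an in-progress
#'   [hemodynamic_indices()] table).
#' @param ceiling Cap applied at singular points, 1/Pa (default 1e3).
#' @return `maps` with columns `rrt` (1/Pa) and logical `degenerate`
#'   added (the flag is OR-combined with an existing one).
#' @export
rrt <- function(maps, ceiling = 1e3) {
  stopifnot(all(c("tawss", "osi") %in% names(maps)), ceiling > 0)
  denom <- (1 - 2 * maps$osi) * maps$tawss
  bad <- !(denom > 1 / ceiling)
  maps$rrt <- ifelse(bad, ceiling, 1 / pmax(denom, 1 / ceiling))
  maps$degenerate <- bad | (if ("degenerate" %in% names(maps))
    maps$degenerate else FALSE)
  maps
}

#' Endothelial cell activation potential (ECAP)
#'
#' The ratio OSI / TAWSS in 1/Pa, flagging wall regions that combine low
#' shear with high oscillation. Zero-TAWSS points are set to 0 and flagged
#' `degenerate`.
#'
#' @inheritParams rrt
#' @return `maps` with columns `ecap` (1/Pa) and `degenerate` added.
#' @export
ecap <- function(maps) {
  stopifnot(all(c("tawss", "osi") %in% names(maps)))
  bad <- maps$tawss <= 0
  maps$ecap <- ifelse(bad, 0, maps$osi / pmax(maps$tawss, 1e-300))
  maps$degenerate <- bad | (if ("degenerate" %in% names(maps))
    maps$degenerate else FALSE)
  maps
}

#' All four endothelial risk indices of a WSS series
#'
#' Computes TAWSS, OSI, RRT and ECAP per wall point and returns them as a
#' single `index_maps` tibble. Identities that hold wherever the point is
#' not flagged degenerate: `rrt * tawss * (1 - 2 * osi) = 1` and
#' `ecap * tawss = osi`.
#'
#' @param series A [wss_series()].
#' @param rrt_ceiling Cap for singular RRT points, 1/Pa.
#' @return A tibble of class `index_maps`: `point_id`, `arc_length_m`,
#'   `tawss`, `osi`, `rrt`, `ecap`, `degenerate` (plus wall coordinates
#'   `x`, `y` when present in the series).
#' @export
hemodynamic_indices <- function(series, rrt_ceiling = 1e3) {
  stopifnot(inherits(series, "wss_series"))
  maps <- dplyr::inner_join(tawss(series), osi(series),
                            by = c("point_id", "arc_length_m"))
  if (all(c("x", "y") %in% names(series))) {
    xy <- dplyr::distinct(tibble::as_tibble(series)[, c("point_id", "x", "y")])
    maps <- dplyr::left_join(maps, xy, by = "point_id")
  }
  maps <- ecap(rrt(maps, ceiling = rrt_ceiling))
  class(maps) <- unique(c("index_maps", class(maps)))
  maps
}

#' Snapshot WSS magnitude maps at selected times
#'
#' Extracts |WSS| per wall point at the requested within-cycle times by
#' periodic linear interpolation between stored samples. The default times
#' are the four standard reporting instants of the cardiac cycle used in
#' aortic WSS studies: early acceleration (0.01 s), systolic peak
#' (0.14 s), mid deceleration (0.35 s) and diastole (0.59 s).
#'
#' @param series A [wss_series()].
#' @param times Times within `[0, period]`, s.
#' @return A tibble: `point_id`, `arc_length_m`, `time_s`, `wss_mag` (Pa).
#' @export
wss_snapshots <- function(series, times = c(0.01, 0.14, 0.35, 0.59)) {
  stopifnot(inherits(series, "wss_series"))
  period <- series_period(series)
  if (any(times < 0 | times > period)) {
    stop("snapshot times must lie within the period", call. = FALSE)
  }
  purrr::map_dfr(times, function(tq) {
    dplyr::summarise(
      dplyr::group_by(series, .data$point_id),
      arc_length_m = .data$arc_length_m[1],
      wss_mag = {
        mag <- sqrt(.data$wss_x^2 + .data$wss_y^2)
        interp_periodic(.data$time_s, mag, period, tq)
      },
      time_s = tq,
      .groups = "drop")
  })
}

#' Read and write WSS series CSV files
#'
#' Long-format CSV with columns `point_id, arc_length_m, time_s, wss_x,
#' wss_y` (Pa and m). On read the period is inferred from the uniform
#' time grid unless given.
#'
#' @param series A [wss_series()].
#' @param path File path.
#' @param period Optional period override on read, s.
#' @return `read_wss_csv()` returns a [wss_series()];
#'   `write_wss_csv()` returns `path` invisibly.
#' @export
write_wss_csv <- function(series, path) {
  stopifnot(inherits(series, "wss_series"))
  cols <- c("point_id", "arc_length_m", "time_s", "wss_x", "wss_y")
  readr::write_csv(tibble::as_tibble(series)[, cols], path)
  invisible(path)
}

#' @rdname write_wss_csv
#' @export
read_wss_csv <- function(path, period = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tt <- sort(unique(df$time_s))
  if (is.null(period)) period <- length(tt) * diff(tt)[1]
  wss_series(df, period = period)
}

#' Export index maps as VTK point data
#'
#' Writes the wall points as VTK POLYDATA vertices with point-data arrays
#' `TAWSS`, `OSI`, `RRT`, `ECAP`. Wall coordinates `x`, `y` are used when
#' present; otherwise points are laid out along the arc length.
#'
#' @param maps An `index_maps` tibble from [hemodynamic_indices()].
#' @param path Output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_index_maps_vtk <- function(maps, path) {
  stopifnot(inherits(maps, "index_maps"))
  n <- nrow(maps)
  px <- if ("x" %in% names(maps)) maps$x else maps$arc_length_m
  py <- if ("y" %in% names(maps)) maps$y else rep(0, n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "hemoflow index maps", "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g 0", px, py), con)
  writeLines(sprintf("VERTICES %d %d", n, 2L * n), con)
  writeLines(sprintf("1 %d", seq_len(n) - 1L), con)
  writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in c("tawss", "osi", "rrt", "ecap")) {
    writeLines(c(sprintf("SCALARS %s double 1", toupper(nm)),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", maps[[nm]]), con)
  }
  invisible(path)
}
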