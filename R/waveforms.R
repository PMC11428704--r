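#' Construct a sampled periodic waveform
#'
#' A waveform is a tibble with columns `time_s` and `value`, uniformly
#' sampled over one period on the grid \eqn{t_k = kT/n, k = 0, ..., n-1}
#' (the sample at \eqn{t = T} is identified with \eqn{t = 0} by
#' periodicity). The physical unit travels with the object as an attribute
#' and is checked by every operation that combines waveforms.
#'
#' @param value Numeric vector of samples.
#' @param period Period T in seconds.
#' @param unit One of `"mmHg"`, `"m/s"`, `"mL/s"`.
#' @param time_s Optional explicit sample times; defaults to the canonical
#'   uniform grid on `[0, period)`.
#' @return A tibble of class `waveform` with attributes `unit` and `period`.
#' @export
waveform <- function(value, period = 1, unit = c("mmHg", "m/s", "mL/s"),
                     time_s = NULL) {
  unit <- match.arg(unit)
  stopifnot(is.numeric(value), length(value) >= 2L, all(is.finite(value)),
            is.numeric(period), period > 0)
  n <- length(value)
  if (is.null(time_s)) {
    time_s <- period * (seq_len(n) - 1) / n
  } else {
    stopifnot(length(time_s) == n)
  }
  out <- tibble::tibble(time_s = time_s, value = value)
  attr(out, "unit") <- unit
  attr(out, "period") <- period
  class(out) <- c("waveform", class(out))
  out
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples over %g s, unit %s\n",
              nrow(x), wf_period(x), wf_unit(x)))
  NextMethod()
}

#' Waveform unit and period accessors
#' @param w A [waveform()].
#' @return The unit tag (character) or the period in seconds.
#' @export
wf_unit <- function(w) attr(w, "unit", exact = TRUE)

#' @rdname wf_unit
#' @export
wf_period <- function(w) attr(w, "period", exact = TRUE)

stop_if_unit_mismatch <- function(a, b) {
  if (!identical(wf_unit(a), wf_unit(b))) {
    stop(sprintf("waveform unit mismatch: '%s' vs '%s'",
                 wf_unit(a), wf_unit(b)), call. = FALSE)
  }
}

#' Specification of a physiological pulse
#'
#' Parameterizes a smooth periodic pulse by its period, the time of the
#' systolic peak, the systolic and diastolic levels, and the number of
#' Fourier harmonics used to shape it. Defaults follow a hypertensive
#' aortic setting: 1 s cycle, systolic peak at 0.14 s, and (for pressure)
#' a 140 mmHg systolic over an 80 mmHg diastolic level.
#'
#' @param period Cycle period T, s.
#' @param peak_time Time of the systolic peak, s, strictly inside (0, T).
#' @param systolic_level Peak value (mmHg for pressure, m/s for velocity).
#' @param diastolic_level Minimum value; must be strictly below the peak.
#' @param unit Unit tag of the synthesized waveform.
#' @param harmonic_count Number of cosine harmonics in the pulse family.
#' @return An object of class `waveform_spec`.
#' @seealso [synthesize_pulse()]
#' @export
waveform_spec <- function(period = 1, peak_time = 0.14,
                          systolic_level = 140, diastolic_level = 80,
                          unit = c("mmHg", "m/s", "mL/s"),
                          harmonic_count = 8L) {
  unit <- match.arg(unit)
  if (!is.finite(period) || period <= 0) {
    stop("`period` must be positive", call. = FALSE)
  }
  if (!is.finite(peak_time) || peak_time <= 0 || peak_time >= period) {
    stop("`peak_time` must lie strictly inside (0, period)", call. = FALSE)
  }
  if (!(systolic_level > diastolic_level)) {
    stop("`systolic_level` must exceed `diastolic_level`", call. = FALSE)
  }
  if (harmonic_count < 1L) stop("`harmonic_count` must be >= 1", call. = FALSE)
  structure(
    list(period = period, peak_time = peak_time,
         systolic_level = systolic_level, diastolic_level = diastolic_level,
         unit = unit, harmonic_count = as.integer(harmonic_count)),
    class = "waveform_spec"
  )
}

#' @rdname waveform_spec
#' @export
pressure_pulse_spec <- function(period = 1, peak_time = 0.14,
                                systolic_level = 140, diastolic_level = 80,
                                harmonic_count = 8L) {
  waveform_spec(period, peak_time, systolic_level, diastolic_level,
                unit = "mmHg", harmonic_count = harmonic_count)
}

#' @rdname waveform_spec
#' @export
velocity_pulse_spec <- function(period = 1, peak_time = 0.14,
                                systolic_level = 0.5, diastolic_level = 0.02,
                                harmonic_count = 8L) {
  waveform_spec(period, peak_time, systolic_level, diastolic_level,
                unit = "m/s", harmonic_count = harmonic_count)
}

#' Synthesize a physiological pulse waveform
#'
#' Builds a smooth periodic pulse from a truncated cosine series
#' \eqn{g(t) = \sum_{k=1}^{H} a_k \cos(2\pi k (t - t_p)/T)} with
#' geometrically decaying positive amplitudes, then rescales it linearly so
#' that the sampled waveform attains exactly `diastolic_level` at its
#' minimum and `systolic_level` at the peak. Because every term is
#' maximized at \eqn{t = t_p}, the global maximum falls exactly on the
#' systolic peak time (when `peak_time` is a grid point, which holds for
#' the default sampling). An optional seed applies a small reproducible
#' jitter to the harmonic amplitudes, giving a family of distinct but
#' equally valid pulse shapes.
#'
#' @param spec A [waveform_spec()].
#' @param n_samples Number of uniform samples over one period.
#' @param seed Optional integer seed for amplitude jitter; `NULL` gives the
#'   canonical member of the family.
#' @return A [waveform()].
#' @examples
#' p <- synthesize_pulse(pressure_pulse_spec())
#' max(p$value)              # 140 exactly
#' p$time_s[which.max(p$value)]  # 0.14
#' @export
synthesize_pulse <- function(spec, n_samples = 200L, seed = NULL) {
  stopifnot(inherits(spec, "waveform_spec"))
  if (n_samples < 8L) stop("`n_samples` must be >= 8", call. = FALSE)
  h <- seq_len(spec$harmonic_count)
  amps <- 0.55^h
  if (!is.null(seed)) {
    amps <- amps * withr::with_seed(as.integer(seed),
                                    1 + stats::runif(length(h), -0.1, 0.1))
  }
  tt <- spec$period * (seq_len(n_samples) - 1) / n_samples
  phase <- 2 * pi * outer(tt - spec$peak_time, h) / spec$period
  g <- drop(cos(phase) %*% amps)
  gmin <- min(g)
  gmax <- sum(amps)  # attained at t = peak_time
  v <- spec$diastolic_level +
    (spec$systolic_level - spec$diastolic_level) * (g - gmin) / (gmax - gmin)
  waveform(v, period = spec$period, unit = spec$unit, time_s = tt)
}

#' Fourier decomposition of a waveform
#'
#' Returns complex harmonic coefficients `c[0..H]` such that the waveform
#' is reconstructed as
#' \eqn{v(t) = c_0 + \sum_{m=1}^{H} 2\,\mathrm{Re}(c_m e^{i 2\pi m t/T})}.
#' Coefficient 0 is the time mean. With `n_harmonics` at the maximum
#' allowed (below Nyquist) the reconstruction reproduces the samples to
#' round-off for band-limited signals.
#'
#' @param w A [waveform()] on the canonical uniform grid.
#' @param n_harmonics Number of harmonics H to keep; must be below the
#'   Nyquist limit `floor((n-1)/2)`.
#' @return Complex vector of length `H + 1` with attribute `period`.
#' @export
fourier_decompose <- function(w, n_harmonics) {
  stopifnot(inherits(w, "waveform"))
  n <- nrow(w)
  if (n < 4L) stop("too few samples for Fourier analysis", call. = FALSE)
  nyq <- floor((n - 1) / 2)
  if (n_harmonics < 0 || n_harmonics > nyq) {
    stop(sprintf("`n_harmonics` must be in [0, %d] for %d samples", nyq, n),
         call. = FALSE)
  }
  co <- stats::fft(w$value) / n
  out <- co[seq_len(n_harmonics + 1L)]
  attr(out, "period") <- wf_period(w)
  out
}

#' @rdname fourier_decompose
#' @param coefs Complex coefficients as returned by [fourier_decompose()].
#' @param t Times at which to evaluate the reconstruction, s.
#' @param period Period T, s; defaults to the attribute carried by `coefs`.
#' @export
fourier_reconstruct <- function(coefs, t, period = attr(coefs, "period")) {
  stopifnot(is.complex(coefs) || is.numeric(coefs), is.numeric(t))
  m <- seq_along(coefs) - 1L
  ph <- outer(t, m) * (2i * pi / period)
  re <- Re(exp(ph) %*% (coefs * c(1, rep(2, length(coefs) - 1L))))
  drop(re)
}

# Complex Bessel J0/J1 by the ascending power series. Accurate to ~1e-10
# for |z| <= 25, which covers Womersley numbers up to ~17 in double
# precision; arguments beyond that are rejected.
besselJ_complex <- function(z, nu = 0L) {
  stopifnot(nu %in% c(0L, 1L))
  if (any(Mod(z) > 25)) {
    stop("complex Bessel series restricted to |z| <= 25", call. = FALSE)
  }
  zh2 <- -(z * z) / 4
  term <- if (nu == 0L) rep(1 + 0i, length(z)) else z / 2
  total <- term
  for (m in seq_len(120L)) {
    term <- term * zh2 / (m * (m + nu))
    total <- total + term
    if (all(Mod(term) < 1e-18 * (Mod(total) + 1e-300)) && m > 8L) break
  }
  total
}

#' Womersley pulsatile tube-flow solution
#'
#' Evaluates the classical analytic solution for laminar pulsatile flow of
#' a Newtonian fluid in a rigid circular tube driven by an axial pressure
#' gradient \eqn{\partial p/\partial x = \mathrm{Re}\sum_m k_m e^{i m
#' \omega t}}. The steady term gives the Poiseuille parabola
#' \eqn{-k_0 (R^2 - r^2)/(4\mu)}; each oscillatory harmonic contributes
#' \deqn{u_m(r, t) = \mathrm{Re}\left[\frac{i k_m}{\rho m \omega}
#'   \left(1 - \frac{J_0(i^{3/2}\alpha_m r/R)}{J_0(i^{3/2}\alpha_m)}\right)
#'   e^{i m \omega t}\right]}
#' with Womersley number \eqn{\alpha_m = R\sqrt{m\omega/\nu}}. This serves
#' as the independent oracle for the transient flow solver and as a
#' fully developed inlet profile generator.
#'
#' @param radius Tube radius R, m.
#' @param pressure_gradient_harmonics Complex vector `k[0..M]`; element 1
#'   is the steady gradient (Pa/m, its real part is used), element m+1 the
#'   complex amplitude of harmonic m.
#' @param rheology A Newtonian [rheology_params()] (`mu_zero == mu_inf`).
#' @param r Radial positions, m, with `|r| <= radius`; vectorized.
#' @param t Times, s; vectorized.
#' @param period Fundamental period T, s.
#' @return Axial velocity in m/s: a `length(r) x length(t)` matrix, dropped
#'   to a vector when either argument has length one.
#' @export
womersley_velocity <- function(radius, pressure_gradient_harmonics,
                               rheology, r, t, period = 1) {
  stopifnot(radius > 0, period > 0)
  if (!is_newtonian(rheology)) {
    stop("Womersley oracle requires a Newtonian rheology (mu_zero == mu_inf)",
         call. = FALSE)
  }
  if (any(abs(r) > radius * (1 + 1e-12))) {
    stop("`r` must satisfy |r| <= radius", call. = FALSE)
  }
  k <- pressure_gradient_harmonics
  mu <- rheology$mu_inf
  rho <- rheology$density
  nu <- mu / rho
  u <- outer(-Re(k[1]) * (radius^2 - r^2) / (4 * mu), rep(1, length(t)))
  if (length(k) > 1L) {
    for (m in seq_len(length(k) - 1L)) {
      km <- k[m + 1L]
      if (Mod(km) == 0) next
      om <- 2 * pi * m / period
      lam <- complex(real = -1, imaginary = 1) / sqrt(2) *
        (radius * sqrt(om / nu))  # i^{3/2} * alpha_m
      prof <- (1i * km / (rho * om)) *
        (1 - besselJ_complex(lam * r / radius) / besselJ_complex(lam))
      u <- u + Re(outer(prof, exp(1i * om * t)))
    }
  }
  drop(u)
}

#' @rdname womersley_velocity
#' @details `womersley_mean_velocity()` returns the complex harmonics of
#'   the cross-sectionally averaged velocity for the same driving gradient;
#'   `womersley_gradient_for_flow()` inverts that map, yielding the
#'   pressure-gradient harmonics that produce a prescribed mean-velocity
#'   harmonic content (used to impose fully developed pulsatile inlets).
#' @export
womersley_mean_velocity <- function(radius, pressure_gradient_harmonics,
                                    rheology, period = 1) {
  stopifnot(radius > 0)
  if (!is_newtonian(rheology)) {
    stop("Womersley oracle requires a Newtonian rheology", call. = FALSE)
  }
  k <- pressure_gradient_harmonics
  mu <- rheology$mu_inf
  rho <- rheology$density
  nu <- mu / rho
  out <- complex(length(k))
  out[1] <- -Re(k[1]) * radius^2 / (8 * mu)
  if (length(k) > 1L) {
    for (m in seq_len(length(k) - 1L)) {
      om <- 2 * pi * m / period
      lam <- complex(real = -1, imaginary = 1) / sqrt(2) *
        (radius * sqrt(om / nu))
      shape <- 1 - 2 * besselJ_complex(lam, 1L) / (lam * besselJ_complex(lam))
      out[m + 1L] <- (1i * k[m + 1L] / (rho * om)) * shape
    }
  }
  out
}

#' @rdname womersley_velocity
#' @param mean_velocity_harmonics Complex harmonics of the desired
#'   cross-sectional mean velocity (element 1 = time mean, m/s).
#' @export
womersley_gradient_for_flow <- function(mean_velocity_harmonics, radius,
                                        rheology, period = 1) {
  stopifnot(radius > 0)
  if (!is_newtonian(rheology)) {
    stop("Womersley oracle requires a Newtonian rheology", call. = FALSE)
  }
  ub <- mean_velocity_harmonics
  mu <- rheology$mu_inf
  rho <- rheology$density
  nu <- mu / rho
  out <- complex(length(ub))
  out[1] <- -8 * mu * Re(ub[1]) / radius^2
  if (length(ub) > 1L) {
    for (m in seq_len(length(ub) - 1L)) {
      om <- 2 * pi * m / period
      lam <- complex(real = -1, imaginary = 1) / sqrt(2) *
        (radius * sqrt(om / nu))
      shape <- 1 - 2 * besselJ_complex(lam, 1L) / (lam * besselJ_complex(lam))
      out[m + 1L] <- ub[m + 1L] * rho * om / (1i * shape)
    }
  }
  out
}

#' Poiseuille wall shear stress
#'
#' Steady laminar wall shear stress in a circular tube,
#' \eqn{\tau_w = 4 \mu Q / (\pi R^3)}; the planar-channel analogue
#' \eqn{\tau_w = 6 \mu \bar u / h} is provided for 2-D channel cases.
#'
#' @param flow_rate Volumetric flow rate Q, m^3/s.
#' @param radius Tube radius R, m (positive).
#' @param viscosity Dynamic viscosity, Pa s.
#' @return Wall shear stress in Pa.
#' @export
poiseuille_wss <- function(flow_rate, radius, viscosity) {
  if (!is.finite(radius) || radius <= 0) {
    stop("`radius` must be positive", call. = FALSE)
  }
  4 * viscosity * flow_rate / (pi * radius^3)
}

#' @rdname poiseuille_wss
#' @param mean_velocity Cross-sectional mean velocity, m/s.
#' @param height Channel height h, m.
#' @export
poiseuille_channel_wss <- function(mean_velocity, height, viscosity) {
  if (!is.finite(height) || height <= 0) {
    stop("`height` must be positive", call. = FALSE)
  }
  6 * viscosity * mean_velocity / height
}

#' Convert a mean-velocity waveform to a flow-rate waveform
#'
#' Multiplies a mean-velocity trace by the circular cross-section area of
#' the given equivalent diameter, \eqn{Q(t) = u(t)\,\pi (d/2)^2}, and
#' reports the result in mL/s. The descending-aorta equivalent diameter of
#' 25.2 mm is the conventional preset for validation against published
#' aortic flow-rate data.
#'
#' @param w A [waveform()] with unit `"m/s"`.
#' @param diameter Equivalent vessel diameter in mm (default 25.2).
#' @return A [waveform()] with unit `"mL/s"`.
#' @export
flow_rate_from_velocity <- function(w, diameter = 25.2) {
  stopifnot(inherits(w, "waveform"))
  if (!identical(wf_unit(w), "m/s")) {
    stop("`w` must carry the velocity unit tag 'm/s'", call. = FALSE)
  }
  if (!is.finite(diameter) || diameter <= 0) {
    stop("`diameter` must be positive (mm)", call. = FALSE)
  }
  area_m2 <- pi * (diameter / 2000)^2
  waveform(w$value * area_m2 * 1e6, period = wf_period(w), unit = "mL/s",
           time_s = w$time_s)
}

#' Resample a waveform onto a uniform grid by periodic linear interpolation
#'
#' @param w A [waveform()].
#' @param n Number of samples of the target canonical grid.
#' @return A [waveform()] on the grid `t_k = k T / n`.
#' @export
resample_waveform <- function(w, n) {
  stopifnot(inherits(w, "waveform"), n >= 2L)
  t_new <- wf_period(w) * (seq_len(n) - 1) / n
  waveform(interp_periodic(w$time_s, w$value, wf_period(w), t_new),
           period = wf_period(w), unit = wf_unit(w), time_s = t_new)
}

interp_periodic <- function(t, v, period, t_out) {
  # wrap one sample at each end so approx() covers [0, period)
  tw <- c(t[length(t)] - period, t, t[1] + period)
  vw <- c(v[length(v)], v, v[1])
  stats::approx(tw, vw, xout = t_out %% period, rule = 2)$y
}

#' Relative L2 difference between two waveforms, in percent
#'
#' The canonical comparison metric for validating a computed flow-rate or
#' pressure waveform against a reference trace:
#' \eqn{100\,\lVert a - b\rVert_2 / \lVert b\rVert_2} with `b` the
#' reference, evaluated after resampling both onto a common uniform grid.
#' The metric is positively homogeneous: scaling the test waveform to
#' `(1 + e) * b` yields exactly `100 e` percent. A symmetric variant
#' normalizing by the mean of the two norms is available.
#'
#' @param a Test [waveform()].
#' @param b Reference [waveform()]; must carry the same unit tag.
#' @param symmetric Use the symmetrized normalization instead of the
#'   reference norm.
#' @return Percent difference (non-negative scalar).
#' @export
waveform_percent_difference <- function(a, b, symmetric = FALSE) {
  stopifnot(inherits(a, "waveform"), inherits(b, "waveform"))
  stop_if_unit_mismatch(a, b)
  n <- max(nrow(a), nrow(b))
  av <- resample_waveform(a, n)$value
  bv <- resample_waveform(b, n)$value
  nb <- sqrt(sum(bv^2))
  if (nb == 0) stop("reference waveform has zero norm", call. = FALSE)
  dev <- sqrt(sum((av - bv)^2))
  if (symmetric) {
    na <- sqrt(sum(av^2))
    100 * dev / ((na + nb) / 2)
  } else {
    100 * dev / nb
  }
}

# Peak location with parabolic sub-sample refinement on the periodic grid.
peak_time_refined <- function(w) {
  n <- nrow(w)
  i <- which.max(w$value)
  dt <- wf_period(w) / n
  vm <- w$value[if (i == 1L) n else i - 1L]
  vp <- w$value[if (i == n) 1L else i + 1L]
  v0 <- w$value[i]
  denom <- vm - 2 * v0 + vp
  off <- if (denom < 0) 0.5 * (vm - vp) / denom else 0
  (w$time_s[i] + off * dt) %% wf_period(w)
}

#' Systolic amplification and peak lead between two waveforms
#'
#' Compares a test waveform (e.g. a false-lumen pressure trace) against a
#' reference (e.g. the true lumen): the systolic amplification is the
#' percent increase of the test maximum over the reference maximum,
#' \eqn{100\,(\max a - \max b)/\max b}, and the peak lead is the time by
#' which the test systolic peak precedes the reference peak (positive =
#' test peaks earlier). Peak times are refined to sub-sample precision by
#' a local parabolic fit; the lead is wrapped into `(-T/2, T/2]`.
#'
#' @param test Test [waveform()].
#' @param reference Reference [waveform()]; same unit and period.
#' @return A tibble with columns `amplification` (percent) and `peak_lead`
#'   (seconds).
#' @export
systolic_metrics <- function(test, reference) {
  stopifnot(inherits(test, "waveform"), inherits(reference, "waveform"))
  stop_if_unit_mismatch(test, reference)
  if (!isTRUE(all.equal(wf_period(test), wf_period(reference)))) {
    stop("waveform periods differ", call. = FALSE)
  }
  mref <- max(reference$value)
  if (mref <= 0) {
    stop("reference waveform must have a positive maximum", call. = FALSE)
  }
  amp <- 100 * (max(test$value) - mref) / mref
  lead <- peak_time_refined(reference) - peak_time_refined(test)
  half <- wf_period(test) / 2
  lead <- ((lead + half) %% wf_period(test)) - half
  tibble::tibble(amplification = amp, peak_lead = lead)
}

#' Read and write waveform CSV files
#'
#' The on-disk dialect is a three-column CSV `time_s, value, unit` with the
#' unit tag repeated per row; times must form a uniform grid starting at 0.
#' A trailing sample at `t = period` (duplicating `t = 0`) is accepted on
#' read and dropped.
#'
#' @param w A [waveform()].
#' @param path File path.
#' @param period Optional period override on read; by default inferred from
#'   the uniform grid as `n * dt`.
#' @return `read_waveform_csv()` returns a [waveform()];
#'   `write_waveform_csv()` returns `path` invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  df <- tibble::tibble(time_s = w$time_s, value = w$value, unit = wf_unit(w))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_waveform_csv
#' @export
read_waveform_csv <- function(path, period = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_s", "value", "unit")
  if (!all(need %in% names(df))) {
    stop("waveform CSV must have columns time_s, value, unit", call. = FALSE)
  }
  unit <- unique(df$unit)
  if (length(unit) != 1L || !unit %in% c("mmHg", "m/s", "mL/s")) {
    stop("waveform CSV must carry a single unit tag (mmHg, m/s or mL/s)",
         call. = FALSE)
  }
  tt <- df$time_s
  vv <- df$value
  n <- length(tt)
  dt <- diff(tt)
  if (n < 3L || any(abs(dt - dt[1]) > 1e-9 * max(dt))) {
    stop("waveform CSV times must form a uniform grid", call. = FALSE)
  }
  inferred <- n * dt[1]
  if (is.null(period)) period <- inferred
  # inclusive endpoint: drop duplicated final sample
  if (abs(tt[n] - period) < 1e-9 * period) {
    tt <- tt[-n]; vv <- vv[-n]
    period <- if (is.null(period)) (n - 1) * dt[1] else period
  }
  waveform(vv, period = period, unit = unit, time_s = tt)
}

#' Pressure unit conversion
#'
#' Fixed conversion constant 1 mmHg = 133.322 Pa. All internal computation
#' is in SI (Pa); mmHg appears only at I/O boundaries.
#'
#' @param x Pressure values.
#' @return Converted values.
#' @export
mmHg_to_Pa <- function(x) x * 133.322

#' @rdname mmHg_to_Pa
#' @export
Pa_to_mmHg <- function(x) x / 133.322
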