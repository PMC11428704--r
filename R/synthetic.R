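#' Ground truth for synthetic fixtures
#'
#' Prescribes the exact quantities a synthetic fixture must carry so that
#' downstream estimators can be validated by round-trip: the target TAWSS
#' and OSI of a wall-point WSS series, and the systolic amplification and
#' peak lead of a paired pressure trace (the structure observed when
#' comparing a false lumen against the true lumen: e.g. 25 percent
#' amplification and a 0.01 s peak lead for the false lumen, 3 percent
#' for the true lumen against the pre-dissection state).
#'
#' @param target_tawss Target TAWSS, Pa (> 0).
#' @param target_osi Target OSI, in [0, 0.5).
#' @param amplification Systolic amplification, percent.
#' @param peak_lead Peak lead time, s (positive = test peaks earlier).
#' @param seed Integer seed driving all randomness of the generators.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(target_tawss = 3, target_osi = 0.25,
                         amplification = 25, peak_lead = 0.01,
                         seed = 1L) {
  if (!is.finite(target_tawss) || target_tawss <= 0) {
    stop("`target_tawss` must be positive", call. = FALSE)
  }
  if (!is.finite(target_osi) || target_osi < 0 || target_osi >= 0.5) {
    stop("`target_osi` must lie in [0, 0.5)", call. = FALSE)
  }
  structure(list(target_tawss = target_tawss, target_osi = target_osi,
                 amplification = amplification, peak_lead = peak_lead,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Synthetic WSS series with exact TAWSS and OSI
#'
#' Builds, per wall point, a WSS signal along a random unit direction
#' composed of a steady component `a` plus a reversing square wave of
#' amplitude `b` (equal dwell in each half-cycle). For `b >= a >= 0` the
#' continuous-time indices are available in closed form — TAWSS `= b` and
#' OSI `= (1 - a/b)/2` — so the amplitude ratio is solved exactly from the
#' targets: `b = target_tawss`, `a = b (1 - 2 target_osi)`. On an even
#' uniform time grid the discrete quadrature reproduces the targets to
#' round-off, making this the reference fixture for the index estimators.
#'
#' @param truth A [ground_truth()].
#' @param n_points Number of wall points.
#' @param n_steps Number of time samples over the cycle (>= 16; even
#'   values make the half-cycle split exact).
#' @param period Cycle period, s.
#' @return A [wss_series()] with the truth attached as attribute
#'   `ground_truth`.
#' @export
make_wss_series <- function(truth, n_points = 10L, n_steps = 200L,
                            period = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_steps < 16L) stop("`n_steps` must be >= 16", call. = FALSE)
  b <- truth$target_tawss
  a <- b * (1 - 2 * truth$target_osi)
  tt <- period * (seq_len(n_steps) - 1) / n_steps
  sq <- ifelse(tt < period / 2, 1, -1)
  dirs <- withr::with_seed(truth$seed, {
    th <- stats::runif(n_points, 0, 2 * pi)
    cbind(cos(th), sin(th))
  })
  df <- purrr::map_dfr(seq_len(n_points), function(p) {
    amp <- a + b * sq
    tibble::tibble(point_id = p,
                   arc_length_m = (p - 1) * 1e-3,
                   time_s = tt,
                   wss_x = dirs[p, 1] * amp,
                   wss_y = dirs[p, 2] * amp)
  })
  out <- wss_series(df, period = period)
  attr(out, "ground_truth") <- truth
  out
}

#' Paired pressure waveforms with exact amplification and peak lead
#'
#' Returns `reference = base` and a test waveform obtained by scaling the
#' base about its diastolic floor so that the systolic peak is amplified
#' by exactly `truth$amplification` percent, then time-shifting it by
#' `-truth$peak_lead` (so the test peak leads). Feeding the pair to
#' [systolic_metrics()] recovers the ground truth within one sample
#' interval (exactly, when the lead is a multiple of the sampling step).
#'
#' @param truth A [ground_truth()].
#' @param base A [waveform()] with a positive maximum.
#' @return A list with elements `test` and `reference` (waveforms) and
#'   `truth`.
#' @export
make_pressure_pair <- function(truth, base = synthesize_pulse(pressure_pulse_spec())) {
  stopifnot(inherits(truth, "ground_truth"), inherits(base, "waveform"))
  period <- wf_period(base)
  if (abs(truth$peak_lead) >= period) {
    stop("peak lead must be smaller than the period", call. = FALSE)
  }
  mx <- max(base$value)
  if (mx <= 0) stop("base waveform must have a positive maximum",
                    call. = FALSE)
  floor_v <- min(base$value)
  target_max <- mx * (1 + truth$amplification / 100)
  if (target_max <= floor_v) {
    stop("amplification drives the peak below the diastolic floor",
         call. = FALSE)
  }
  s <- (target_max - floor_v) / (mx - floor_v)
  scaled <- floor_v + s * (base$value - floor_v)
  shifted <- interp_periodic(base$time_s, scaled, period,
                             base$time_s + truth$peak_lead)
  test <- waveform(shifted, period = period, unit = wf_unit(base),
                   time_s = base$time_s)
  list(test = test, reference = base, truth = truth)
}

#' Add reproducible Gaussian noise to a waveform or WSS series
#'
#' Adds zero-mean Gaussian perturbations with standard deviation
#' `relative_sd` times the root-mean-square of the signal (of the WSS
#' magnitude for a series, applied per vector component). Deterministic
#' for a fixed seed.
#'
#' @param x A [waveform()] or [wss_series()].
#' @param relative_sd Noise level relative to the signal RMS (>= 0).
#' @param seed Integer seed.
#' @return An object of the same type as `x`.
#' @export
add_noise <- function(x, relative_sd, seed = 1L) {
  if (!is.finite(relative_sd) || relative_sd < 0) {
    stop("`relative_sd` must be non-negative", call. = FALSE)
  }
  if (relative_sd == 0) return(x)
  if (inherits(x, "waveform")) {
    rms <- sqrt(mean(x$value^2))
    noise <- withr::with_seed(as.integer(seed),
                              stats::rnorm(nrow(x), 0, relative_sd * rms))
    out <- x
    out$value <- x$value + noise
    return(out)
  }
  if (inherits(x, "wss_series")) {
    rms <- sqrt(mean(x$wss_x^2 + x$wss_y^2))
    noise <- withr::with_seed(as.integer(seed),
                              matrix(stats::rnorm(2L * nrow(x), 0,
                                                  relative_sd * rms),
                                     ncol = 2L))
    out <- x
    out$wss_x <- x$wss_x + noise[, 1]
    out$wss_y <- x$wss_y + noise[, 2]
    return(out)
  }
  stop("`x` must be a waveform or wss_series", call. = FALSE)
}
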