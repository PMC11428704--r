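# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: the pulsatile tube-flow oracle solves
# the harmonic momentum ODE by finite differences (no Bessel functions),
# and the index oracle integrates on a fine grid by direct summation.

# complex tridiagonal Thomas solve
tridiag_solve_cplx <- function(lower, diag, upper, rhs) {
  n <- length(diag)
  cp <- complex(n); dp <- complex(n)
  cp[1] <- upper[1] / diag[1]
  dp[1] <- rhs[1] / diag[1]
  for (i in 2:n) {
    m <- diag[i] - lower[i] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / m else 0
    dp[i] <- (rhs[i] - lower[i] * dp[i - 1]) / m
  }
  x <- complex(n)
  x[n] <- dp[n]
  for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
  x
}

# axial velocity of pulsatile laminar tube flow: per-harmonic BVP
#   i m w rho u = -k_m + mu (1/r) d/dr(r du/dr),  u(R)=0, u'(0)=0
# discretized at M cell centres; quadratic wall ghost for 2nd order.
womersley_fd_oracle <- function(radius, k_harm, mu, rho, r_eval, t_eval,
                                period = 1, M = 1200L) {
  h <- radius / M
  rc <- (seq_len(M) - 0.5) * h
  rf <- (0:M) * h
  u_eval <- matrix(0, length(r_eval), length(t_eval))
  for (m in seq_along(k_harm) - 1L) {
    km <- k_harm[m + 1L]
    if (Mod(km) == 0) next
    om <- 2 * pi * m / period
    lower <- complex(M); diag <- complex(M); upper <- complex(M)
    for (i in seq_len(M)) {
      aS <- if (i == 1L) 0 else mu * rf[i] / (rc[i] * h^2)
      aN <- mu * rf[i + 1L] / (rc[i] * h^2)
      lower[i] <- aS
      upper[i] <- aN
      diag[i] <- -1i * om * rho - aS - aN
    }
    # wall: quadratic ghost u_{M+1} = -2 u_M + u_{M-1}/3
    diag[M] <- diag[M] - 2 * upper[M]
    lower[M] <- lower[M] + upper[M] / 3
    upper[M] <- 0
    uh <- tridiag_solve_cplx(lower, diag, upper, rep(km + 0i, M))
    ur <- stats::approx(c(0, rc, radius),
                        c(Re(uh[1]), Re(uh), 0), xout = abs(r_eval))$y +
      1i * stats::approx(c(0, rc, radius),
                         c(Im(uh[1]), Im(uh), 0), xout = abs(r_eval))$y
    if (m == 0L) {
      u_eval <- u_eval + matrix(Re(ur), length(r_eval), length(t_eval))
    } else {
      u_eval <- u_eval + Re(outer(ur, exp(1i * om * t_eval)))
    }
  }
  u_eval
}

# fine-grid OSI/TAWSS by direct summation of a vector-valued function
indices_fine_oracle <- function(fx, fy, period = 1, n = 200000L) {
  tt <- period * (seq_len(n) - 0.5) / n
  vx <- fx(tt); vy <- fy(tt)
  mean_mag <- mean(sqrt(vx^2 + vy^2))
  mag_mean <- sqrt(mean(vx)^2 + mean(vy)^2)
  list(tawss = mean_mag,
       osi = 0.5 * (1 - mag_mean / mean_mag))
}

# build a wss_series directly from sampled vector components
series_from_fun <- function(fx, fy, n_steps, period = 1, n_points = 1L) {
  tt <- period * (seq_len(n_steps) - 1) / n_steps
  df <- purrr::map_dfr(seq_len(n_points), function(p) {
    tibble::tibble(point_id = p, arc_length_m = (p - 1) * 1e-3,
                   time_s = tt, wss_x = fx(tt), wss_y = fy(tt))
  })
  wss_series(df, period = period)
}
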