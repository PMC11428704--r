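test_that("pulse synthesis honours its spec exactly", {
  spec <- pressure_pulse_spec()
  w <- synthesize_pulse(spec, n_samples = 100)
  expect_equal(max(w$value), 140)
  expect_equal(w$time_s[which.max(w$value)], 0.14)
  expect_equal(min(w$value), 80)
  expect_identical(wf_unit(w), "mmHg")
  # determinism for fixed spec and seed
  expect_identical(synthesize_pulse(spec, 100, seed = 5),
                   synthesize_pulse(spec, 100, seed = 5))
  expect_false(identical(synthesize_pulse(spec, 100, seed = 5),
                         synthesize_pulse(spec, 100, seed = 6)))
  # jittered members still attain the exact extrema
  wj <- synthesize_pulse(spec, 100, seed = 11)
  expect_equal(max(wj$value), 140)
  expect_equal(min(wj$value), 80)
})

test_that("waveform specs reject degenerate parameters", {
  expect_error(waveform_spec(peak_time = 1.2), "peak_time")
  expect_error(waveform_spec(peak_time = 0), "peak_time")
  expect_error(waveform_spec(systolic_level = 80, diastolic_level = 80),
               "exceed")
})

test_that("Fourier decomposition round-trips and isolates harmonics", {
  # constant waveform: only the mean coefficient
  const <- waveform(rep(3.5, 64), unit = "m/s")
  co <- fourier_decompose(const, 10)
  expect_equal(Re(co[1]), 3.5)
  expect_true(all(Mod(co[-1]) < 1e-12))
  # pure cosine at harmonic 1
  tt <- (0:63) / 64
  w1 <- waveform(cos(2 * pi * tt), unit = "m/s", time_s = tt)
  co1 <- fourier_decompose(w1, 5)
  expect_equal(Mod(co1[2]), 0.5, tolerance = 1e-12)
  expect_true(all(Mod(co1[-2]) < 1e-12))
  # round trip of a random band-limited signal
  withr::with_seed(3, {
    coefs <- complex(real = stats::rnorm(9), imaginary = stats::rnorm(9))
  })
  v <- fourier_reconstruct(coefs, tt, period = 1)
  wr <- waveform(v, unit = "mmHg", time_s = tt)
  back <- fourier_decompose(wr, 8)
  rec <- fourier_reconstruct(back, tt)
  expect_lt(max(abs(rec - v)), 1e-10)
  expect_error(fourier_decompose(wr, 40), "n_harmonics")
})

test_that("Womersley solution reduces to Poiseuille and honours no-slip", {
  rh <- rheology_params(mu_inf = 0.0035, mu_zero = 0.0035)
  R <- 0.002; k0 <- -500
  r <- seq(0, R, length.out = 21)
  u <- womersley_velocity(R, complex(real = k0), rh, r, t = 0.3)
  expect_equal(u, -k0 * (R^2 - r^2) / (4 * rh$mu_inf), tolerance = 1e-12)
  # centreline = 2 x mean for the steady term
  expect_equal(u[1], 2 * (-k0 * R^2 / (8 * rh$mu_inf)), tolerance = 1e-12)
  expect_equal(u[21], 0)
  # oscillatory case pinned by the independent finite-difference oracle
  kh <- c(complex(real = -700), complex(real = -400, imaginary = 250))
  tt <- c(0.05, 0.4, 0.77)
  u2 <- womersley_velocity(R, kh, rh, r, tt)
  ref <- womersley_fd_oracle(R, kh, rh$mu_inf, rh$density, r, tt)
  expect_lt(max(abs(u2 - ref)) / max(abs(ref)), 2e-3)
  # non-Newtonian rheology is refused
  expect_error(womersley_velocity(R, kh, rheology_params(), r, tt),
               "Newtonian")
})

test_that("flow/gradient harmonic maps are mutual inverses", {
  rh <- rheology_params(mu_inf = 0.0035, mu_zero = 0.0035)
  R <- 0.0126
  ub <- c(complex(real = 0.1), complex(real = 0.05, imaginary = -0.02),
          complex(real = -0.01, imaginary = 0.01))
  kh <- womersley_gradient_for_flow(ub, R, rh)
  back <- womersley_mean_velocity(R, kh, rh)
  expect_lt(max(Mod(back - ub)), 1e-12)
})

test_that("Poiseuille WSS formulas are exact", {
  expect_identical(poiseuille_wss(0, 0.01, 0.0035), 0)
  expect_equal(poiseuille_wss(2e-4, 0.01, 0.0035),
               2 * poiseuille_wss(1e-4, 0.01, 0.0035))
  # hand evaluation of 4 mu Q / (pi R^3)
  expect_equal(poiseuille_wss(1e-4, 0.0126, 0.0035), 0.22277503862139265,
               tolerance = 1e-12)
  expect_error(poiseuille_wss(1e-4, -1, 0.0035), "radius")
  expect_equal(poiseuille_channel_wss(0.1, 0.01, 0.0035),
               6 * 0.0035 * 0.1 / 0.01)
})

test_that("velocity-to-flow conversion uses the equivalent diameter", {
  u <- waveform(rep(1, 50), unit = "m/s")
  q <- flow_rate_from_velocity(u, diameter = 25.2)
  expect_identical(wf_unit(q), "mL/s")
  expect_equal(q$value[1], 498.7592496839156, tolerance = 1e-12)
  expect_equal(flow_rate_from_velocity(waveform(rep(0, 50), unit = "m/s"))$value,
               rep(0, 50))
  expect_error(flow_rate_from_velocity(waveform(rep(1, 50), unit = "mmHg")),
               "m/s")
})

test_that("percent difference is a reference-normalized relative L2", {
  w <- synthesize_pulse(pressure_pulse_spec(), 100)
  expect_equal(waveform_percent_difference(w, w), 0)
  w11 <- waveform(1.1 * w$value, unit = "mmHg", time_s = w$time_s)
  expect_equal(waveform_percent_difference(w11, w), 10, tolerance = 1e-10)
  # fixture pair pinned by direct sum-of-squares arithmetic
  a <- waveform(c(3, 5, 2, 4, 6, 1, 2, 3), unit = "mL/s")
  b <- waveform(c(2, 6, 2, 3, 7, 2, 1, 3), unit = "mL/s")
  expected <- 100 * sqrt(sum((a$value - b$value)^2)) / sqrt(sum(b$value^2))
  expect_equal(waveform_percent_difference(a, b), expected, tolerance = 1e-12)
  expect_error(waveform_percent_difference(a, w), "unit mismatch")
  # symmetric variant normalizes by the mean norm
  sym <- waveform_percent_difference(a, b, symmetric = TRUE)
  na <- sqrt(sum(a$value^2)); nb <- sqrt(sum(b$value^2))
  expect_equal(sym, 100 * sqrt(sum((a$value - b$value)^2)) / ((na + nb) / 2))
})

test_that("systolic metrics recover amplification and lead", {
  w <- synthesize_pulse(pressure_pulse_spec(), 200)
  same <- systolic_metrics(w, w)
  expect_equal(same$amplification, 0)
  expect_equal(same$peak_lead, 0)
  # constructed: x1.25 about zero, shifted one sample earlier (0.005 s)
  shifted <- waveform(1.25 * c(w$value[-1], w$value[1]), unit = "mmHg",
                      time_s = w$time_s)
  sm <- systolic_metrics(shifted, w)
  expect_equal(sm$amplification, 25)
  expect_equal(sm$peak_lead, 0.005, tolerance = 1e-9)
  expect_error(systolic_metrics(w, waveform(rep(-5, 200), unit = "mmHg")),
               "positive maximum")
})

test_that("waveform CSV round-trips to full precision", {
  w <- synthesize_pulse(velocity_pulse_spec(), 100, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_waveform_csv(w, path)
  back <- read_waveform_csv(path)
  expect_identical(wf_unit(back), "m/s")
  expect_equal(back$value, w$value, tolerance = 1e-12)
  expect_equal(wf_period(back), 1, tolerance = 1e-9)
})
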