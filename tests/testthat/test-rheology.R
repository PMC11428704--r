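test_that("Carreau-Yasuda viscosity hits its plateaus and stays bounded", {
  blood <- rheology_params()
  expect_identical(apparent_viscosity(0, blood), 0.056)
  expect_lt(abs(apparent_viscosity(1e8, blood) - 0.0035), 1e-6)
  # regression constant frozen from an independent high-precision
  # evaluation of the closed form at 100 1/s
  expect_equal(apparent_viscosity(100, blood), 0.004756468494695937,
               tolerance = 1e-12)
  # Newtonian limit: plateau everywhere
  newt <- rheology_params(mu_inf = 0.0035, mu_zero = 0.0035)
  expect_equal(apparent_viscosity(c(0, 1, 1e4, 1e8), newt),
               rep(0.0035, 4))
})

test_that("viscosity is monotone non-increasing and within [mu_inf, mu_zero]", {
  blood <- rheology_params()
  withr::with_seed(42, {
    for (rep in 1:20) {
      g <- sort(stats::runif(50, 0, 10^stats::runif(1, 0, 6)))
      mu <- apparent_viscosity(g, blood)
      expect_true(all(diff(mu) <= 1e-15))
      expect_true(all(mu >= blood$mu_inf - 1e-15))
      expect_true(all(mu <= blood$mu_zero + 1e-15))
    }
  })
})

test_that("invalid rheology parameters and shear rates are rejected", {
  expect_error(rheology_params(density = -1), "density")
  expect_error(rheology_params(mu_zero = 0.001), "mu_zero")
  expect_error(rheology_params(power_n = 1.5), "power_n")
  expect_error(apparent_viscosity(-1, rheology_params()), "non-negative")
  expect_error(apparent_viscosity(NaN, rheology_params()), "finite")
})

test_that("shear-rate magnitude follows sqrt(2 D:D)", {
  expect_identical(shear_rate_magnitude(matrix(0, 3, 3)), 0)
  # rigid rotation: antisymmetric gradient has no deformation
  rot <- matrix(c(0, -2, 2, 0), 2, 2)
  expect_identical(shear_rate_magnitude(rot), 0)
  # simple shear du/dy = s gives exactly s
  s <- 5
  g <- matrix(0, 3, 3); g[1, 2] <- s
  expect_equal(shear_rate_magnitude(g), s)
  expect_error(shear_rate_magnitude(matrix(c(1, Inf, 0, 0), 2, 2)), "finite")
  expect_error(shear_rate_magnitude(matrix(0, 2, 3)), "matrix")
})

test_that("SST blending function F2 behaves across its regimes", {
  # both branches vanish: far from the wall with no turbulence
  far <- sst_closure_params(0, 10, 100, kinematic_viscosity = 3.3e-6)
  expect_lt(sst_blending_f2(far), 1e-6)
  # tight to the wall: tanh saturation
  near <- sst_closure_params(1, 100, 1e-4)
  expect_equal(sst_blending_f2(near), 1)
  # hand-evaluated closed form at k=1, omega=100, d=1, nu=3.3e-6
  cl <- sst_closure_params(1, 100, 1, kinematic_viscosity = 3.3e-6)
  arg2 <- max(2 * sqrt(1) / (0.09 * 100 * 1), 500 * 3.3e-6 / (100 * 1^2))
  expect_equal(sst_blending_f2(cl), tanh(arg2^2))
  expect_true(sst_blending_f2(cl) > 0 && sst_blending_f2(cl) <= 1)
  expect_error(sst_closure_params(1, -5, 1), "omega")
  expect_error(sst_closure_params(1, 5, -1), "wall_distance")
})

test_that("eddy viscosity follows the SST limiter", {
  expect_identical(turbulent_viscosity(sst_closure_params(0, 50, 0.01), 1060),
                   0)
  # S = 0: reduces to rho k / omega exactly
  cl <- sst_closure_params(0.5, 200, 0.01, strain_rate = 0)
  expect_equal(turbulent_viscosity(cl, 1060), 1060 * 0.5 / 200)
  # strain limiter active: hand evaluation with F2 supplied
  cl2 <- sst_closure_params(0.5, 200, 0.01, strain_rate = 1000)
  expect_equal(turbulent_viscosity(cl2, 1060, f2 = 0.9),
               0.31 * 1060 * 0.5 / max(0.31 * 200, 1000 * 0.9))
})

test_that("turbulent stress tensor is symmetric with the correct trace", {
  expect_equal(turbulent_stress(0.1, matrix(0, 3, 3), 0, 1060),
               matrix(0, 3, 3))
  # zero gradient, k > 0: isotropic -2/3 rho k I
  tau <- turbulent_stress(0.1, matrix(0, 3, 3), 0.2, 1060)
  expect_equal(tau, diag(3) * (-2 / 3 * 1060 * 0.2))
  # simple shear, k = 0: symmetric off-diagonal mu_t * s
  g <- matrix(0, 3, 3); g[1, 2] <- 4
  tau <- turbulent_stress(0.05, g, 0, 1060)
  expect_equal(tau[1, 2], 0.05 * 4)
  expect_equal(tau, t(tau))
  # property: trace = -2 rho k for traceless gradients
  withr::with_seed(7, {
    for (rep in 1:25) {
      g <- matrix(stats::rnorm(9), 3, 3)
      g[3, 3] <- -(g[1, 1] + g[2, 2])
      k <- stats::runif(1, 0, 2)
      tau <- turbulent_stress(stats::runif(1, 0, 1), g, k, 1060)
      expect_equal(tau, t(tau))
      expect_equal(sum(diag(tau)), -2 * 1060 * k)
    }
  })
})
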