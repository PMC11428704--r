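test_that("steady tube flow reproduces the Poiseuille profile", {
  lad <- steady_tube_ladder()
  fine <- lad$levels[[3]]
  mesh <- fine$mesh; state <- fine$result
  # centreline / mean velocity ratio = 2 within 2 percent
  ic <- round(mesh$nx / 2)
  expect_equal(max(state$u[ic, ]) / lad$U, 2, tolerance = 0.02)
  # no-slip holds exactly on wall faces
  expect_true(all(state$v[, mesh$ny + 1L] == 0))
  # residual met
  expect_lt(state$residual, 1e-5)
})

test_that("zero inflow gives a zero field with uniform pressure", {
  mesh <- steady_tube_ladder()$levels[[1]]$mesh
  rh <- steady_tube_ladder()$rheology
  st0 <- solve_steady(mesh, 0, 50, rh)
  expect_equal(max(abs(st0$u)), 0)
  expect_equal(max(abs(st0$v)), 0)
  expect_equal(range(st0$p[mesh$fluid]), c(50, 50), tolerance = 1e-9)
})

test_that("every converged state conserves mass to round-off", {
  lad <- steady_tube_ladder()
  for (lv in lad$levels) {
    mb <- mass_balance(lv$result, lv$mesh)
    expect_lt(mb$relative_imbalance, 1e-8)
  }
  wom <- womersley_case()
  for (s in wom$series$states[c(1, 25, 50)]) {
    expect_lt(mass_balance(s, wom$mesh)$relative_imbalance, 1e-8)
  }
  dis <- dissected_case()
  last <- dis$series$states[[length(dis$series$states)]]
  expect_lt(mass_balance(last, dis$mesh)$relative_imbalance, 1e-8)
})

test_that("transient solve with constant boundaries matches the steady solve", {
  spec <- vessel_spec("straight", inlet_diameter = 20, length = 40)
  mesh <- build_vessel(spec, 8)
  rh <- rheology_params(mu_inf = 0.035, mu_zero = 0.035)
  stt <- solve_steady(mesh, 0.05, 0, rh,
                      solver_config(inlet_profile = "parabolic"))
  win <- waveform(rep(0.05, 50), period = 1, unit = "m/s")
  ser <- solve_transient(mesh, win, 0, rh,
                         solver_config(time_step = 2e-3, cycles = 4,
                                       inlet_profile = "parabolic",
                                       store_per_cycle = 10))
  last <- ser$states[[length(ser$states)]]
  ic <- round(mesh$nx / 2)
  expect_equal(last$u[ic, ], stt$u[ic, ], tolerance = 0.01)
  expect_lt(ser$diagnostics$cycle_drift, 0.01)
})

test_that("transient Newtonian tube flow matches the Womersley series", {
  wom <- womersley_case()
  mesh <- wom$mesh
  yc <- (seq_len(mesh$ny) - 0.5) * mesh$dy
  ic <- round(mesh$nx / 2)
  num <- sapply(wom$series$states,
                function(s) (s$u[ic, ] + s$u[ic + 1L, ]) / 2)
  ref <- womersley_velocity(wom$R, wom$kh, wom$rheology, yc,
                            wom$series$times, period = 1)
  expect_lt(sqrt(sum((num - ref)^2) / sum(ref^2)), 0.03)
})

test_that("wall shear stress reverses within an oscillatory cycle", {
  wom <- womersley_case()
  wss <- wall_shear_stress(wom$series, wom$mesh, wom$rheology)
  mid <- dplyr::filter(wss, abs(arc_length_m - wom$L / 2) < 2 * wom$mesh$dx)
  expect_lt(min(mid$wss_x), 0)
  expect_gt(max(mid$wss_x), 0)
  # and the analytic wall gradient agrees with that reversal pattern
  dr <- 1e-7
  uw <- womersley_velocity(wom$R, wom$kh, wom$rheology,
                           c(wom$R - dr, wom$R), wom$series$times)
  tau_ref <- wom$rheology$mu_inf * (uw[1, ] - uw[2, ]) / dr
  one_pt <- dplyr::filter(mid, point_id == mid$point_id[1])
  picks <- c(which.max(tau_ref), which.min(tau_ref))
  expect_equal(sign(one_pt$wss_x[picks]), sign(tau_ref[picks]))
})

test_that("steady WSS is uniform away from the ends and matches the oracle", {
  lad <- steady_tube_ladder()
  fine <- lad$levels[[3]]
  wss <- wall_shear_stress(fine$result, fine$mesh, lad$rheology)
  mid <- dplyr::filter(wss, arc_length_m > 0.02, arc_length_m < 0.04,
                       time_s == 0)
  expect_lt(stats::sd(mid$wss_x) / mean(mid$wss_x), 0.01)
  expect_equal(mean(mid$wss_x), lad$tau_ref, tolerance = 0.02)
  # a zero-flow state has zero WSS
  mesh0 <- lad$levels[[1]]$mesh
  st0 <- solve_steady(mesh0, 0, 0, lad$rheology)
  wss0 <- wall_shear_stress(st0, mesh0, lad$rheology)
  expect_equal(max(abs(wss0$wss_x)), 0)
})

test_that("wall y+ scales with the square root of wall shear", {
  lad <- steady_tube_ladder()
  mesh <- lad$levels[[2]]$mesh
  state <- lad$levels[[2]]$result
  yp <- wall_y_plus(state, mesh, lad$rheology)
  wall <- yp[grepl("wall", wall_points(mesh)$tag), ]
  # hand evaluation from the analytic wall shear and the mesh spacing
  u_tau <- sqrt(lad$tau_ref / lad$rheology$density)
  nu <- lad$rheology$mu_inf / lad$rheology$density
  y_ref <- (mesh$dy / 2) * u_tau / nu
  mid <- dplyr::filter(yp, arc_length_m > 0.02, arc_length_m < 0.04)
  expect_equal(mean(mid$y_plus), y_ref, tolerance = 0.02)
  # quadrupling the wall shear doubles y+ (square-root scaling)
  state4 <- state
  state4$u <- 4 * state$u; state4$v <- 4 * state$v
  yp4 <- wall_y_plus(state4, mesh, lad$rheology)
  expect_equal(yp4$y_plus, 2 * yp$y_plus, tolerance = 1e-10)
  # zero WSS gives y+ = 0
  stz <- state; stz$u[] <- 0; stz$v[] <- 0
  expect_equal(max(wall_y_plus(stz, mesh, lad$rheology)$y_plus), 0)
})

test_that("a single tear feeds the false lumen", {
  dis <- dissected_case()
  fx <- cycle_mean_flux(dis$series, dis$mesh, 0.045)
  expect_gt(fx$mean_flux[fx$lumen == "true"], 0)
  expect_gt(fx$mean_flux[fx$lumen == "false"], 0)
  # upstream of the tear the false lumen is sealed: flux is negligible
  up <- cycle_mean_flux(dis$series, dis$mesh, 0.005)
  expect_lt(abs(up$mean_flux[up$lumen == "false"]),
            1e-6 * fx$mean_flux[fx$lumen == "true"])
})

test_that("over-large time steps raise a CFL error with a suggestion", {
  mesh <- build_vessel(vessel_spec("straight", inlet_diameter = 10,
                                   length = 30), 16)
  win <- waveform(rep(0.3, 50), period = 1, unit = "m/s")
  err <- tryCatch(
    solve_transient(mesh, win, 0, rheology_params(),
                    solver_config(time_step = 0.05, cycles = 1)),
    hemoflow_cfl_error = function(e) e)
  expect_s3_class(err, "hemoflow_cfl_error")
  expect_true(is.finite(err$suggested_dt) && err$suggested_dt < 0.05)
})

test_that("identical configurations produce bitwise-identical results", {
  spec <- vessel_spec("straight", inlet_diameter = 10, length = 20)
  mesh <- build_vessel(spec, 8)
  rh <- rheology_params()
  win <- synthesize_pulse(velocity_pulse_spec(systolic_level = 0.2,
                                              diastolic_level = 0.02), 50)
  cfg <- solver_config(time_step = 5e-4, cycles = 1, inlet_profile = "flat",
                       store_per_cycle = 10)
  s1 <- solve_transient(mesh, win, 0, rh, cfg)
  s2 <- solve_transient(mesh, win, 0, rh, cfg)
  expect_identical(s1$states[[10]]$u, s2$states[[10]]$u)
  expect_identical(s1$states[[10]]$p, s2$states[[10]]$p)
})

test_that("the solver refuses meshes it cannot honour", {
  arch <- build_vessel(vessel_spec("arch", inlet_diameter = 20,
                                   length = 150), 10)
  expect_error(solve_steady(arch, 0.1), "arch")
})
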