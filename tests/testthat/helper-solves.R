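# Expensive solver fixtures, computed once per test run and shared
# between files. Problem sizes are chosen so the whole suite stays at
# desk scale while exercising every solver path.

.solve_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .solve_cache)) {
    assign(key, force(expr), envir = .solve_cache)
  }
  get(key, envir = .solve_cache)
}

# Newtonian steady tube at three refinement levels (Poiseuille case):
# R = 10 mm, L = 60 mm, mean velocity 0.05 m/s, mu = 0.035 Pa s (Re ~ 30)
steady_tube_ladder <- function() {
  memo("steady_ladder", {
    spec <- vessel_spec("straight", inlet_diameter = 20, length = 60)
    rh <- rheology_params(mu_inf = 0.035, mu_zero = 0.035)
    cfg <- solver_config(inlet_profile = "parabolic")
    U <- 0.05
    levels <- lapply(c(8L, 16L, 32L), function(res) {
      mesh <- build_vessel(spec, res)
      list(mesh = mesh,
           result = solve_steady(mesh, U, 0, rh, cfg))
    })
    list(levels = levels, rheology = rh, U = U, R = 0.01,
         tau_ref = poiseuille_wss(U * pi * 0.01^2, 0.01, 0.035))
  })
}

# Newtonian pulsatile tube driven by an oscillating pressure difference:
# R = 2 mm, L = 10 mm, Womersley number 2.76 at the fundamental. The
# oscillatory amplitude is large enough that wall shear reverses in part
# of the cycle.
womersley_case <- function() {
  memo("womersley", {
    rh <- rheology_params(mu_inf = 0.0035, mu_zero = 0.0035)
    R <- 0.002; L <- 0.01
    spec <- vessel_spec("straight", inlet_diameter = 2 * R * 1000,
                        length = L * 1000)
    kh <- c(complex(real = -700), complex(real = -1800, imaginary = 600))
    n <- 200
    tt <- (seq_len(n) - 1) / n
    pin <- -L * (Re(kh[1]) + Re(kh[2] * exp(2i * pi * tt)))
    win <- waveform(Pa_to_mmHg(pin), period = 1, unit = "mmHg", time_s = tt)
    mesh <- build_vessel(spec, 32L)
    cfg <- solver_config(time_step = 2e-4, cycles = 3L,
                         store_per_cycle = 50L)
    series <- solve_transient(mesh, win, 0, rh, cfg)
    list(series = series, mesh = mesh, rheology = rh, R = R, L = L, kh = kh)
  })
}

# Dissected two-lumen channel with one proximal tear, full blood
# rheology, two cycles of a physiological velocity pulse.
dissected_case <- function() {
  memo("dissected", {
    spec <- vessel_spec("dissected", length = 60,
                        true_lumen_diameter = 8, false_lumen_diameter = 6,
                        septum_thickness = 1.5,
                        tears = data.frame(position = 15, opening = 6))
    mesh <- build_vessel(spec, 10L)
    rh <- rheology_params()
    win <- synthesize_pulse(velocity_pulse_spec(systolic_level = 0.3,
                                                diastolic_level = 0.02),
                            n_samples = 200L)
    cfg <- solver_config(time_step = 8e-4, cycles = 3L,
                         inlet_profile = "flat", store_per_cycle = 40L)
    series <- solve_transient(mesh, win, 0, rh, cfg)
    list(series = series, mesh = mesh, rheology = rh)
  })
}
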