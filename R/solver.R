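#' Solver configuration
#'
#' Controls the transient incompressible solver: the time step, the number
#' of cardiac cycles to march (earlier cycles are washout; the final cycle
#' is reported), the scaled residual tolerance (default 1e-5, applied to
#' momentum and continuity alike), the Picard iteration cap for the
#' viscosity coupling, the advection scheme, and the inlet velocity
#' profile (`parabolic` for tubes, `flat` for channels, `womersley` for a
#' fully developed pulsatile profile; Newtonian only).
#'
#' @param time_step Time step, s.
#' @param cycles Number of cardiac cycles to march (>= 1).
#' @param residual_tolerance Scaled residual target, dimensionless.
#' @param max_inner_iterations Picard cap per time step for the
#'   generalized-Newtonian viscosity lag.
#' @param advection_scheme `"upwind"` (first-order, default) or
#'   `"central-blend"` (deferred-correction blend, 90 percent central).
#' @param inlet_profile Shape of the prescribed inlet velocity profile.
#' @param store_per_cycle How many uniformly spaced states of the final
#'   cycle to retain.
#' @param max_steps Hard cap on pseudo-time steps for [solve_steady()].
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(time_step = 1e-3, cycles = 3L,
                          residual_tolerance = 1e-5,
                          max_inner_iterations = 5L,
                          advection_scheme = c("upwind", "central-blend"),
                          inlet_profile = c("parabolic", "flat", "womersley"),
                          store_per_cycle = 100L,
                          max_steps = 50000L) {
  advection_scheme <- match.arg(advection_scheme)
  inlet_profile <- match.arg(inlet_profile)
  if (!is.finite(time_step) || time_step <= 0) {
    stop("`time_step` must be positive", call. = FALSE)
  }
  if (!is.finite(residual_tolerance) || residual_tolerance <= 0) {
    stop("`residual_tolerance` must be positive", call. = FALSE)
  }
  cycles <- as.integer(cycles)
  if (cycles < 1L) stop("`cycles` must be >= 1", call. = FALSE)
  structure(
    list(time_step = time_step, cycles = cycles,
         residual_tolerance = residual_tolerance,
         max_inner_iterations = as.integer(max_inner_iterations),
         advection_scheme = advection_scheme,
         inlet_profile = inlet_profile,
         store_per_cycle = as.integer(store_per_cycle),
         max_steps = as.integer(max_steps)),
    class = "solver_config")
}

# ---- internal solver machinery ------------------------------------------

# Static geometric/topological precomputation shared by all time steps.
solver_setup <- function(mesh, rheology, config) {
  nx <- mesh$nx; ny <- mesh$ny
  dx <- mesh$dx; dy <- mesh$dy
  F <- mesh$fluid
  yc <- mesh_yc(mesh)
  if (mesh$axisymmetric) {
    rc <- yc                      # cell-centre radius
    rf <- mesh$y0 + dy * (0:ny)   # y-face radius
  } else {
    rc <- rep(1, ny)
    rf <- rep(1, ny + 1L)
  }
  act_u <- matrix(FALSE, nx + 1L, ny)
  if (nx >= 2L) act_u[2:nx, ] <- F[1:(nx - 1L), ] & F[2:nx, ]
  inlet_u <- c(mesh$inlet_open & F[1, ])   # logical over j at i = 1
  outlet_u <- c(mesh$outlet_open & F[nx, ])
  act_v <- matrix(FALSE, nx, ny + 1L)
  if (ny >= 2L) act_v[, 2:ny] <- F[, 1:(ny - 1L)] & F[, 2:ny]

  # wall masks for tangential diffusion of u (slab i = 2..nx); the wall
  # flux uses a quadratic ghost (exact for parabolic profiles) when the
  # inner neighbour exists, else the linear reflection ghost
  au <- act_u[2:nx, , drop = FALSE]
  nbN_u <- cbind(act_u[2:nx, -1, drop = FALSE], FALSE)
  nbS_u <- cbind(FALSE, act_u[2:nx, -ny, drop = FALSE])
  wallN_u <- au & !nbN_u
  wallS_u <- au & !nbS_u
  if (mesh$axisymmetric) wallS_u[, 1] <- FALSE  # axis, not a wall

  # wall masks for lateral diffusion of v (slab j = 2..ny)
  av <- act_v[, 2:ny, drop = FALSE]
  nbE_v <- rbind(act_v[-1, 2:ny, drop = FALSE], FALSE)
  nbW_v <- rbind(FALSE, act_v[-nx, 2:ny, drop = FALSE])
  # open in/out boundaries impose zero tangential stress, not a wall
  open_E <- matrix(FALSE, nx, ny - 1L)
  open_E[nx, ] <- outlet_u[2:ny] & outlet_u[1:(ny - 1L)]
  open_W <- matrix(FALSE, nx, ny - 1L)
  open_W[1, ] <- inlet_u[2:ny] & inlet_u[1:(ny - 1L)]
  wallE_v <- av & !nbE_v & !open_E
  wallW_v <- av & !nbW_v & !open_W

  # cell-neighbour solidity for viscosity gradients
  solidN_c <- cbind(!F[, -1, drop = FALSE], TRUE) & F
  solidS_c <- cbind(TRUE, !F[, -ny, drop = FALSE]) & F
  solidE_c <- rbind(!F[-1, , drop = FALSE], TRUE) & F
  solidE_c[nx, ] <- F[nx, ] & !outlet_u
  solidW_c <- rbind(TRUE, !F[-nx, , drop = FALSE]) & F
  solidW_c[1, ] <- F[1, ] & !inlet_u

  # pressure Poisson matrix (constant in time)
  id <- matrix(0L, nx, ny)
  id[F] <- seq_len(sum(F))
  n_p <- sum(F)
  AE <- matrix(rep(rc * dy, each = nx), nx, ny)         # east/west face area
  AN <- matrix(rep(rf[2:(ny + 1L)] * dx, each = nx), nx, ny)
  AS <- matrix(rep(rf[1:ny] * dx, each = nx), nx, ny)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  diag_v <- numeric(n_p)
  rhs_dirich <- numeric(n_p)   # coefficient only; BC values applied per step
  dir_out_coef <- numeric(n_p) # 2*A/dx at outlet cells
  dir_in_coef <- numeric(n_p)
  add_pair <- function(pa, pb, a) {
    ii <<- c(ii, pa, pb); jj <<- c(jj, pb, pa); vv <<- c(vv, -a, -a)
    diag_v[pa] <<- diag_v[pa] + a
    diag_v[pb] <<- diag_v[pb] + a
  }
  # east connections
  conE <- which(F & rbind(F[-1, , drop = FALSE], FALSE), arr.ind = TRUE)
  if (nrow(conE)) {
    pa <- id[conE]; pb <- id[cbind(conE[, 1] + 1L, conE[, 2])]
    a <- AE[conE] / dx
    ii <- c(ii, pa, pb); jj <- c(jj, pb, pa); vv <- c(vv, -a, -a)
    diag_add <- tapply(c(a, a), c(pa, pb), sum)
    diag_v[as.integer(names(diag_add))] <-
      diag_v[as.integer(names(diag_add))] + as.numeric(diag_add)
  }
  conN <- which(F & cbind(F[, -1, drop = FALSE], FALSE), arr.ind = TRUE)
  if (nrow(conN)) {
    pa <- id[conN]; pb <- id[cbind(conN[, 1], conN[, 2] + 1L)]
    a <- AN[conN] / dy
    ii <- c(ii, pa, pb); jj <- c(jj, pb, pa); vv <- c(vv, -a, -a)
    diag_add <- tapply(c(a, a), c(pa, pb), sum)
    diag_v[as.integer(names(diag_add))] <-
      diag_v[as.integer(names(diag_add))] + as.numeric(diag_add)
  }
  jo <- which(outlet_u)
  if (length(jo)) {
    po <- id[cbind(rep(nx, length(jo)), jo)]
    a <- 2 * AE[cbind(rep(nx, length(jo)), jo)] / dx
    diag_v[po] <- diag_v[po] + a
    dir_out_coef[po] <- a
  }
  list(mesh = mesh, rheology = rheology, config = config,
       nx = nx, ny = ny, dx = dx, dy = dy,
       rc = rc, rf = rf, F = F, id = id, n_p = n_p,
       act_u = act_u, act_v = act_v,
       inlet_u = inlet_u, outlet_u = outlet_u,
       wallN_u = wallN_u, wallS_u = wallS_u,
       nbN_u = nbN_u, nbS_u = nbS_u,
       wallE_v = wallE_v, wallW_v = wallW_v,
       nbE_v = nbE_v, nbW_v = nbW_v,
       open_E = open_E, open_W = open_W,
       solidN_c = solidN_c, solidS_c = solidS_c,
       solidE_c = solidE_c, solidW_c = solidW_c,
       AE = AE, AN = AN, AS = AS,
       poisson = list(ii = ii, jj = jj, vv = vv, diag_v = diag_v,
                      dir_out_coef = dir_out_coef, dir_in_coef = dir_in_coef))
}

# finalize the Poisson matrix once the inlet mode is known
poisson_factor <- function(setup, inlet_mode) {
  p <- setup$poisson
  diag_v <- p$diag_v
  dir_in_coef <- p$dir_in_coef
  if (inlet_mode == "pressure") {
    ji <- which(setup$inlet_u)
    pi_ <- setup$id[cbind(rep(1L, length(ji)), ji)]
    a <- 2 * setup$AE[cbind(rep(1L, length(ji)), ji)] / setup$dx
    diag_v[pi_] <- diag_v[pi_] + a
    dir_in_coef[pi_] <- a
  }
  if (all(diag_v == 0)) stop("degenerate pressure system", call. = FALSE)
  M <- Matrix::sparseMatrix(i = c(p$ii, seq_len(setup$n_p)),
                            j = c(p$jj, seq_len(setup$n_p)),
                            x = c(p$vv, diag_v),
                            dims = c(setup$n_p, setup$n_p))
  # all-Neumann systems (no outlet) are excluded by mesh audit
  list(chol = Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE),
       dir_out_coef = p$dir_out_coef, dir_in_coef = dir_in_coef)
}

# cell-centre velocity gradients (with wall/axis ghosts) and shear rate
shear_rate_field <- function(u, v, st) {
  nx <- st$nx; ny <- st$ny; dx <- st$dx; dy <- st$dy
  ucc <- (u[1:nx, , drop = FALSE] + u[2:(nx + 1L), , drop = FALSE]) / 2
  vcc <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1L), drop = FALSE]) / 2
  dudx <- (u[2:(nx + 1L), , drop = FALSE] - u[1:nx, , drop = FALSE]) / dx
  dvdy <- (v[, 2:(ny + 1L), drop = FALSE] - v[, 1:ny, drop = FALSE]) / dy
  uN <- cbind(ucc[, -1, drop = FALSE], 0)
  uS <- cbind(0, ucc[, -ny, drop = FALSE])
  uN[st$solidN_c] <- -ucc[st$solidN_c]
  if (st$mesh$axisymmetric) {
    ss <- st$solidS_c
    ss[, 1] <- FALSE
    uS[, 1] <- ucc[, 1]   # symmetry across the axis
    uS[ss] <- -ucc[ss]
  } else {
    uS[st$solidS_c] <- -ucc[st$solidS_c]
  }
  dudy <- (uN - uS) / (2 * dy)
  vE <- rbind(vcc[-1, , drop = FALSE], 0)
  vW <- rbind(0, vcc[-nx, , drop = FALSE])
  vE[st$solidE_c] <- -vcc[st$solidE_c]
  vW[st$solidW_c] <- -vcc[st$solidW_c]
  # open in/out boundaries: zero-gradient ghost
  vE[nx, st$outlet_u] <- vcc[nx, st$outlet_u]
  vW[1, st$inlet_u] <- vcc[1, st$inlet_u]
  dvdx <- (vE - vW) / (2 * dx)
  hoop <- if (st$mesh$axisymmetric) {
    vcc / matrix(rep(st$rc, each = nx), nx, ny)
  } else 0
  sqrt(2 * (dudx^2 + dvdy^2 + hoop^2) + (dudy + dvdx)^2)
}

viscosity_fields <- function(u, v, st) {
  nx <- st$nx; ny <- st$ny
  rh <- st$rheology
  if (is_newtonian(rh)) {
    mu_c <- matrix(rh$mu_inf, nx, ny)
  } else {
    gam <- shear_rate_field(u, v, st)
    mu_c <- matrix(apparent_viscosity(as.numeric(gam), rh), nx, ny)
  }
  mu_c[!st$F] <- 0
  # node viscosities: average over adjacent fluid cells
  wt <- matrix(0, nx + 2L, ny + 2L)
  sm <- matrix(0, nx + 2L, ny + 2L)
  wt[2:(nx + 1L), 2:(ny + 1L)] <- st$F * 1
  sm[2:(nx + 1L), 2:(ny + 1L)] <- mu_c
  nodes_sum <- sm[1:(nx + 1L), 1:(ny + 1L)] + sm[2:(nx + 2L), 1:(ny + 1L)] +
    sm[1:(nx + 1L), 2:(ny + 2L)] + sm[2:(nx + 2L), 2:(ny + 2L)]
  nodes_wt <- wt[1:(nx + 1L), 1:(ny + 1L)] + wt[2:(nx + 2L), 1:(ny + 1L)] +
    wt[1:(nx + 1L), 2:(ny + 2L)] + wt[2:(nx + 2L), 2:(ny + 2L)]
  mu_n <- nodes_sum / pmax(nodes_wt, 1)
  list(mu_c = mu_c, mu_n = mu_n)
}

# one explicit predictor for u and v given viscosity fields
predictor <- function(u, v, mu, st, dt) {
  nx <- st$nx; ny <- st$ny; dx <- st$dx; dy <- st$dy
  rho <- st$rheology$density
  blend <- if (st$config$advection_scheme == "central-blend") 0.9 else 0
  mu_c <- mu$mu_c; mu_n <- mu$mu_n
  us <- u; vs <- v

  if (nx >= 2L) {
    U <- u[2:nx, , drop = FALSE]
    UE <- u[3:(nx + 1L), , drop = FALSE]
    UW <- u[1:(nx - 1L), , drop = FALSE]
    UN <- cbind(U[, -1, drop = FALSE], 0)
    US <- cbind(0, U[, -ny, drop = FALSE])
    vbar <- (v[1:(nx - 1L), 1:ny, drop = FALSE] +
               v[1:(nx - 1L), 2:(ny + 1L), drop = FALSE] +
               v[2:nx, 1:ny, drop = FALSE] +
               v[2:nx, 2:(ny + 1L), drop = FALSE]) / 4
    dx_up <- ifelse(U > 0, (U - UW) / dx, (UE - U) / dx)
    dy_up <- ifelse(vbar > 0, (U - US) / dy, (UN - U) / dy)
    if (blend > 0) {
      dx_up <- (1 - blend) * dx_up + blend * (UE - UW) / (2 * dx)
      dy_up <- (1 - blend) * dy_up + blend * (UN - US) / (2 * dy)
    }
    conv <- U * dx_up + vbar * dy_up
    muE <- mu_c[2:nx, , drop = FALSE]
    muW <- mu_c[1:(nx - 1L), , drop = FALSE]
    difx <- (muE * (UE - U) - muW * (U - UW)) / dx^2
    munN <- mu_n[2:nx, 2:(ny + 1L), drop = FALSE]
    munS <- mu_n[2:nx, 1:ny, drop = FALSE]
    RN <- matrix(rep(st$rf[2:(ny + 1L)], each = nx - 1L), nx - 1L, ny)
    RS <- matrix(rep(st$rf[1:ny], each = nx - 1L), nx - 1L, ny)
    RC <- matrix(rep(st$rc, each = nx - 1L), nx - 1L, ny)
    # wall fluxes: quadratic ghost through the no-slip wall when the inner
    # neighbour is available, linear reflection otherwise
    GN <- UN - U
    GN[st$wallN_u] <- ifelse(st$nbS_u, -3 * U + US / 3, -2 * U)[st$wallN_u]
    GS <- US - U
    GS[st$wallS_u] <- ifelse(st$nbN_u, -3 * U + UN / 3, -2 * U)[st$wallS_u]
    dify <- (RN * munN * GN + RS * munS * GS) / (RC * dy^2)
    upd <- U + dt * (-conv + (difx + dify) / rho)
    us[2:nx, ] <- ifelse(st$act_u[2:nx, , drop = FALSE], upd, 0)
  }

  if (ny >= 2L) {
    V <- v[, 2:ny, drop = FALSE]
    VN <- v[, 3:(ny + 1L), drop = FALSE]
    VS <- v[, 1:(ny - 1L), drop = FALSE]
    VE <- rbind(V[-1, , drop = FALSE], 0)
    VW <- rbind(0, V[-nx, , drop = FALSE])
    ubar <- (u[1:nx, 1:(ny - 1L), drop = FALSE] +
               u[1:nx, 2:ny, drop = FALSE] +
               u[2:(nx + 1L), 1:(ny - 1L), drop = FALSE] +
               u[2:(nx + 1L), 2:ny, drop = FALSE]) / 4
    dx_up <- ifelse(ubar > 0, (V - VW) / dx, (VE - V) / dx)
    dy_up <- ifelse(V > 0, (V - VS) / dy, (VN - V) / dy)
    if (blend > 0) {
      dx_up <- (1 - blend) * dx_up + blend * (VE - VW) / (2 * dx)
      dy_up <- (1 - blend) * dy_up + blend * (VN - VS) / (2 * dy)
    }
    conv <- ubar * dx_up + V * dy_up
    munE <- mu_n[2:(nx + 1L), 2:ny, drop = FALSE]
    munW <- mu_n[1:nx, 2:ny, drop = FALSE]
    GE <- VE - V
    GE[st$wallE_v] <- ifelse(st$nbW_v, -3 * V + VW / 3, -2 * V)[st$wallE_v]
    GE[st$open_E] <- 0
    GW <- VW - V
    GW[st$wallW_v] <- ifelse(st$nbE_v, -3 * V + VE / 3, -2 * V)[st$wallW_v]
    GW[st$open_W] <- 0
    difx <- (munE * GE + munW * GW) / dx^2
    mucN <- mu_c[, 2:ny, drop = FALSE]
    mucS <- mu_c[, 1:(ny - 1L), drop = FALSE]
    RcN <- matrix(rep(st$rc[2:ny], each = nx), nx, ny - 1L)
    RcS <- matrix(rep(st$rc[1:(ny - 1L)], each = nx), nx, ny - 1L)
    Rv <- matrix(rep(st$rf[2:ny], each = nx), nx, ny - 1L)
    dify <- (RcN * mucN * (VN - V) - RcS * mucS * (V - VS)) / (Rv * dy^2)
    axi <- if (st$mesh$axisymmetric) {
      ((mucN + mucS) / 2) * V / Rv^2
    } else 0
    upd <- V + dt * (-conv + (difx + dify - axi) / rho)
    vs[, 2:ny] <- ifelse(st$act_v[, 2:ny, drop = FALSE], upd, 0)
  }
  list(u = us, v = vs)
}

# cell divergence weighted by face areas (area-integrated net outflow)
div_star <- function(u, v, st) {
  nx <- st$nx; ny <- st$ny
  st$AE * (u[2:(nx + 1L), , drop = FALSE] - u[1:nx, , drop = FALSE]) +
    (st$AN * v[, 2:(ny + 1L), drop = FALSE] -
       st$AS * v[, 1:ny, drop = FALSE])
}

# projection: returns corrected (u, v) and the pressure field (Pa)
project <- function(us, vs, st, pois, dt, p_out, p_in = NULL) {
  nx <- st$nx; ny <- st$ny
  rho <- st$rheology$density
  dv <- div_star(us, vs, st)
  b <- -(rho / dt) * dv[st$F]
  jo <- which(st$outlet_u)
  if (length(jo)) {
    po <- st$id[cbind(rep(nx, length(jo)), jo)]
    b[po] <- b[po] + pois$dir_out_coef[po] * p_out
  }
  if (!is.null(p_in)) {
    ji <- which(st$inlet_u)
    pi_ <- st$id[cbind(rep(1L, length(ji)), ji)]
    b[pi_] <- b[pi_] + pois$dir_in_coef[pi_] * p_in
  }
  pv <- as.numeric(Matrix::solve(pois$chol, b))
  P <- matrix(0, nx, ny)
  P[st$F] <- pv
  fac <- dt / rho
  u <- us; v <- vs
  if (nx >= 2L) {
    gpx <- (P[2:nx, , drop = FALSE] - P[1:(nx - 1L), , drop = FALSE]) / st$dx
    u[2:nx, ] <- ifelse(st$act_u[2:nx, , drop = FALSE],
                        us[2:nx, , drop = FALSE] - fac * gpx, 0)
  }
  jo <- which(st$outlet_u)
  if (length(jo)) {
    u[nx + 1L, jo] <- us[nx + 1L, jo] -
      fac * (p_out - P[nx, jo]) * 2 / st$dx
  }
  if (!is.null(p_in)) {
    ji <- which(st$inlet_u)
    u[1L, ji] <- us[1L, ji] - fac * (P[1L, ji] - p_in) * 2 / st$dx
  }
  if (ny >= 2L) {
    gpy <- (P[, 2:ny, drop = FALSE] - P[, 1:(ny - 1L), drop = FALSE]) / st$dy
    v[, 2:ny] <- ifelse(st$act_v[, 2:ny, drop = FALSE],
                        vs[, 2:ny, drop = FALSE] - fac * gpy, 0)
  }
  list(u = u, v = v, p = P)
}

# stability limits for the explicit predictor
stability_dt <- function(st, u_scale) {
  nu_max <- st$rheology$mu_zero / st$rheology$density
  dt_diff <- 0.5 / (nu_max * (3 / st$dx^2 + 3 / st$dy^2))
  dt_adv <- if (u_scale > 0) 0.9 * min(st$dx, st$dy) / u_scale else Inf
  min(dt_diff, dt_adv)
}

check_cfl <- function(u, v, st, dt) {
  umax <- max(abs(u)); vmax <- max(abs(v))
  cfl <- dt * (umax / st$dx + vmax / st$dy)
  nu_max <- st$rheology$mu_zero / st$rheology$density
  dnum <- dt * nu_max * (3 / st$dx^2 + 3 / st$dy^2)
  if (cfl > 1 || dnum > 0.55) {
    sug <- 0.4 * min(st$dx / max(umax, 1e-12), st$dy / max(vmax, 1e-12),
                     0.5 / (nu_max * (3 / st$dx^2 + 3 / st$dy^2)))
    rlang::abort(
      sprintf(paste0("time step violates stability (CFL %.2f, ",
                     "diffusion number %.2f); suggested dt <= %.3g s"),
              cfl, dnum, sug),
      class = "hemoflow_cfl_error", suggested_dt = sug)
  }
  invisible(TRUE)
}

inlet_profile_values <- function(st, value, profile, yc_open) {
  # distribute a mean velocity `value` over the open inlet rows
  mesh <- st$mesh
  if (profile == "flat") return(rep(value, length(yc_open)))
  if (mesh$axisymmetric) {
    R <- max(yc_open) + st$dy / 2
    prof <- 2 * (1 - (yc_open / R)^2)
  } else {
    y0 <- min(yc_open) - st$dy / 2
    y1 <- max(yc_open) + st$dy / 2
    c0 <- (y0 + y1) / 2
    h2 <- (y1 - y0) / 2
    prof <- 1.5 * (1 - ((yc_open - c0) / h2)^2)
  }
  # renormalize so the discrete area-weighted mean equals `value`
  w <- if (mesh$axisymmetric) yc_open else rep(1, length(yc_open))
  prof * value / (sum(prof * w) / sum(w))
}

new_flow_state <- function(u, v, p, time, residual = NA_real_) {
  structure(list(u = u, v = v, p = p, time = time, residual = residual),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  cat(sprintf("<flow_state> t=%.4g s, max|u|=%.3g m/s, p range [%.4g, %.4g] Pa\n",
              x$time, max(abs(x$u), abs(x$v)), min(x$p), max(x$p)))
  invisible(x)
}

new_flow_series <- function(states, times, period, mesh, diagnostics) {
  structure(list(states = states, times = times, period = period,
                 mesh = mesh, diagnostics = diagnostics),
            class = "flow_series")
}

#' @export
print.flow_series <- function(x, ...) {
  cat(sprintf("<flow_series> %d states over one %g s cycle (%s mesh)\n",
              length(x$states), x$period, x$mesh$kind))
  invisible(x)
}

as_flow_series <- function(state, mesh) {
  new_flow_series(list(state, state), c(0, 0.5), 1, mesh,
                  list(steady = TRUE))
}

#' Steady incompressible flow
#'
#' Marches the transient solver in pseudo-time with constant boundary
#' conditions until the scaled momentum residual drops below the
#' configured tolerance. Used for mesh testing and as the consistency
#' limit of [solve_transient()].
#'
#' @param mesh A [vessel_mesh][build_vessel()] (straight or dissected kind;
#'   arch meshes are geometry-only in this release).
#' @param inlet_velocity Mean inlet velocity, m/s.
#' @param outlet_pressure Outlet pressure, Pa.
#' @param rheology A [rheology_params()].
#' @param config A [solver_config()]; `time_step` is chosen automatically
#'   from the stability limit when `NULL` is passed via `auto_dt`.
#' @param auto_dt Pick the pseudo-time step from the stability limit
#'   (default `TRUE`; otherwise `config$time_step` is used).
#' @return A `flow_state` with fields `u`, `v` (staggered face velocities,
#'   m/s), `p` (cell pressures, Pa) and the final scaled residual.
#' @export
solve_steady <- function(mesh, inlet_velocity, outlet_pressure = 0,
                         rheology = rheology_params(),
                         config = solver_config(), auto_dt = TRUE) {
  st <- check_solvable(mesh, rheology, config)
  pois <- poisson_factor(st, "velocity")
  u_scale <- max(abs(inlet_velocity) * 2.5, 1e-9)
  dt <- if (auto_dt) 0.8 * stability_dt(st, u_scale) else config$time_step
  nx <- st$nx; ny <- st$ny
  u <- matrix(0, nx + 1L, ny)
  v <- matrix(0, nx, ny + 1L)
  ji <- which(st$inlet_u)
  yc <- mesh_yc(mesh)[ji]
  uin <- inlet_profile_values(st, inlet_velocity, config$inlet_profile, yc)
  L <- nx * st$dx
  tol <- config$residual_tolerance
  res <- Inf
  hist <- numeric(0)
  for (step in seq_len(config$max_steps)) {
    u[1L, ] <- 0; u[1L, ji] <- uin
    mu <- viscosity_fields(u, v, st)
    pr <- predictor(u, v, mu, st, dt)
    pr$u[1L, ] <- u[1L, ]
    pr$u[nx + 1L, ] <- 0
    pr$u[nx + 1L, st$outlet_u] <- pr$u[nx, st$outlet_u]
    newuv <- project(pr$u, pr$v, st, pois, dt, outlet_pressure)
    dmax <- max(abs(newuv$u - u), abs(newuv$v - v))
    res <- dmax * L / (dt * u_scale^2)
    # absolute floor: numerically quiescent fields are converged
    if (dmax < 1e-13 * (1 + max(abs(newuv$u)))) res <- 0
    u <- newuv$u; v <- newuv$v
    if (step %% 50L == 0L || res < tol) hist <- c(hist, res)
    if (res < tol) {
      check_cfl(u, v, st, dt)
      return(new_flow_state(u, v, newuv$p, time = step * dt, residual = res))
    }
  }
  rlang::abort(
    sprintf("steady solve did not reach residual %.1e in %d steps (last %.2e)",
            tol, config$max_steps, res),
    class = "hemoflow_convergence_error", residual_history = hist)
}

check_solvable <- function(mesh, rheology, config) {
  stopifnot(inherits(mesh, "vessel_mesh"))
  if (mesh$kind == "arch") {
    stop(paste("arch meshes are supported for geometry and export only;",
               "the flow solver requires a grid-aligned inlet/outlet",
               "(straight or dissected kinds)"), call. = FALSE)
  }
  aud <- mesh_audit(mesh)
  if (!aud$ok) {
    stop(paste("mesh failed validity audit:",
               paste(aud$problems, collapse = "; ")), call. = FALSE)
  }
  solver_setup(mesh, rheology, config)
}

#' Transient pulsatile incompressible flow
#'
#' Integrates the incompressible momentum and continuity equations with
#' generalized-Newtonian (Carreau-Yasuda) viscosity on a staggered
#' structured grid, using an explicit predictor and an exact pressure
#' projection per time step. The inlet is driven either by a mean-velocity
#' waveform (unit `"m/s"`; profile per `config$inlet_profile`) or by a
#' pressure waveform (unit `"mmHg"`, e.g. for pressure-difference driven
#' flow); the outlet is always a prescribed-pressure boundary with zero
#' tangential stress. The solver marches `config$cycles` cardiac cycles
#' (washout) and returns uniformly sampled states of the final cycle.
#'
#' @param mesh A [vessel_mesh][build_vessel()].
#' @param inlet_waveform A [waveform()] with unit `"m/s"` or `"mmHg"`.
#' @param outlet_waveform A [waveform()] with unit `"mmHg"` (or a single
#'   number in Pa for a constant outlet pressure).
#' @param rheology A [rheology_params()].
#' @param config A [solver_config()].
#' @return A `flow_series`: states of the final cycle, their within-cycle
#'   times, the period, the mesh, and convergence diagnostics (per-step
#'   scaled residuals and cycle-to-cycle drift).
#' @export
solve_transient <- function(mesh, inlet_waveform, outlet_waveform,
                            rheology = rheology_params(),
                            config = solver_config()) {
  st <- check_solvable(mesh, rheology, config)
  stopifnot(inherits(inlet_waveform, "waveform"))
  period <- wf_period(inlet_waveform)
  if (inherits(outlet_waveform, "waveform")) {
    if (!isTRUE(all.equal(period, wf_period(outlet_waveform)))) {
      stop("inlet and outlet waveform periods differ", call. = FALSE)
    }
    if (!identical(wf_unit(outlet_waveform), "mmHg")) {
      stop("outlet waveform must be a pressure in mmHg", call. = FALSE)
    }
    p_out_fun <- function(t) {
      mmHg_to_Pa(interp_periodic(outlet_waveform$time_s,
                                 outlet_waveform$value, period, t))
    }
  } else {
    p_out_const <- as.numeric(outlet_waveform)
    p_out_fun <- function(t) p_out_const
  }
  inlet_mode <- switch(wf_unit(inlet_waveform),
                       "m/s" = "velocity", "mmHg" = "pressure",
                       stop("inlet waveform must be m/s or mmHg",
                            call. = FALSE))
  pois <- poisson_factor(st, inlet_mode)
  n_steps <- max(8L, as.integer(round(period / config$time_step)))
  dt <- period / n_steps
  nx <- st$nx; ny <- st$ny
  ji <- which(st$inlet_u)
  yc_in <- mesh_yc(mesh)[ji]

  if (inlet_mode == "velocity") {
    uin_fun <- function(t) {
      interp_periodic(inlet_waveform$time_s, inlet_waveform$value, period, t)
    }
    u_scale <- max(abs(inlet_waveform$value)) * 2.5
    womersley_cache <- NULL
    if (config$inlet_profile == "womersley") {
      if (!is_newtonian(rheology)) {
        stop("womersley inlet profile requires a Newtonian rheology",
             call. = FALSE)
      }
      if (!mesh$axisymmetric) {
        stop("womersley inlet profile requires an axisymmetric tube",
             call. = FALSE)
      }
      nh <- min(8L, floor((nrow(inlet_waveform) - 1) / 2))
      cf <- fourier_decompose(inlet_waveform, nh)
      ub <- cf * c(1, rep(2, nh))
      R <- max(yc_in) + st$dy / 2
      kh <- womersley_gradient_for_flow(ub, R, rheology, period)
      tgrid <- dt * seq_len(n_steps)
      womersley_cache <- womersley_velocity(R, kh, rheology, yc_in,
                                            tgrid, period)
      if (is.null(dim(womersley_cache))) {
        womersley_cache <- matrix(womersley_cache, nrow = length(yc_in))
      }
    }
  } else {
    p_in_fun <- function(t) {
      mmHg_to_Pa(interp_periodic(inlet_waveform$time_s,
                                 inlet_waveform$value, period, t))
    }
    u_scale <- 1  # refined after the first cycle
  }

  dt_lim <- stability_dt(st, 0)
  if (dt > dt_lim) {
    rlang::abort(sprintf(
      "time step %.3g s exceeds the diffusive stability limit %.3g s",
      dt, dt_lim), class = "hemoflow_cfl_error", suggested_dt = 0.8 * dt_lim)
  }

  u <- matrix(0, nx + 1L, ny)
  v <- matrix(0, nx, ny + 1L)
  stride <- max(1L, n_steps %/% config$store_per_cycle)
  while (n_steps %% stride != 0L) stride <- stride - 1L
  states <- list(); times <- numeric(0)
  resid_hist <- list()
  cycle_pmean <- numeric(0)
  newtonian <- is_newtonian(rheology)
  tol <- config$residual_tolerance

  for (cyc in seq_len(config$cycles)) {
    psum <- 0
    for (s in seq_len(n_steps)) {
      t_new <- (s) * dt
      if (inlet_mode == "velocity") {
        u[1L, ] <- 0
        if (!is.null(config$inlet_profile) &&
            config$inlet_profile == "womersley" &&
            !is.null(womersley_cache)) {
          u[1L, ji] <- womersley_cache[, s]
        } else {
          u[1L, ji] <- inlet_profile_values(st, uin_fun(t_new),
                                            config$inlet_profile, yc_in)
        }
        p_in <- NULL
      } else {
        p_in <- p_in_fun(t_new)
      }
      p_out <- p_out_fun(t_new)
      u_prev <- u; v_prev <- v
      picard <- Inf
      uk <- u; vk <- v
      for (it in seq_len(max(1L, config$max_inner_iterations))) {
        mu <- viscosity_fields(uk, vk, st)
        pr <- predictor(u_prev, v_prev, mu, st, dt)
        pr$u[1L, ] <- 0
        if (inlet_mode == "velocity") {
          pr$u[1L, ] <- u[1L, ]
        } else {
          pr$u[1L, ji] <- u_prev[2L, ji]
        }
        pr$u[nx + 1L, ] <- 0
        pr$u[nx + 1L, st$outlet_u] <- pr$u[nx, st$outlet_u]
        sol <- project(pr$u, pr$v, st, pois, dt, p_out, p_in)
        picard <- max(abs(sol$u - uk), abs(sol$v - vk)) / max(u_scale, 1e-12)
        uk <- sol$u; vk <- sol$v
        if (newtonian || picard < tol) break
      }
      u <- uk; v <- vk; p <- sol$p
      if (inlet_mode == "pressure") {
        u_scale <- max(u_scale, 2.5 * max(abs(u)))
      }
      check_cfl(u, v, st, dt)
      dv <- div_star(u, v, st)
      q_in <- sum(abs(u[1L, ji]) * st$AE[1L, ji]) +
        sum(abs(u[nx + 1L, st$outlet_u]) * st$AE[nx, st$outlet_u])
      cont <- max(abs(dv[st$F])) / max(q_in, 1e-12)
      psum <- psum + mean(p[st$F])
      if (cyc == config$cycles && s %% stride == 0L) {
        states[[length(states) + 1L]] <-
          new_flow_state(u, v, p, time = t_new,
                         residual = max(cont, if (newtonian) 0 else picard))
        times <- c(times, t_new)
      }
      if (cyc >= config$cycles - 1L && s %% max(1L, n_steps %/% 20L) == 0L) {
        resid_hist[[length(resid_hist) + 1L]] <-
          tibble::tibble(cycle = cyc, time = t_new, continuity = cont,
                         momentum = if (newtonian) 0 else picard)
      }
    }
    cycle_pmean <- c(cycle_pmean, psum / n_steps)
  }
  drift <- if (length(cycle_pmean) >= 2L) {
    denom <- max(abs(cycle_pmean[length(cycle_pmean)]), 133.322)
    abs(diff(utils::tail(cycle_pmean, 2L))) / denom
  } else NA_real_
  if (isTRUE(drift > 0.01)) {
    warning(sprintf("cycle-to-cycle mean-pressure drift %.2f%% exceeds 1%%",
                    100 * drift), call. = FALSE)
  }
  new_flow_series(states, times, period, mesh,
                  diagnostics = list(residuals = dplyr::bind_rows(resid_hist),
                                     cycle_mean_pressure = cycle_pmean,
                                     cycle_drift = drift,
                                     dt = dt, n_steps = n_steps))
}

# ---- wall quantities -----------------------------------------------------

#' Wall points of a mesh
#'
#' Enumerates the wall (and septum) boundary faces as wall points with an
#' arc-length coordinate along each boundary component (walls in the
#' supported geometries are monotone in the axial coordinate, which serves
#' as the arc-length parameter; vertical stair-step segments use the
#' transverse coordinate).
#'
#' @param mesh A [vessel_mesh][build_vessel()].
#' @return A tibble: `point_id`, cell indices `i, j`, `side`, `tag`,
#'   face-centre coordinates `x, y` (m), `arc_length_m`, and the
#'   wall-normal spacing `h` (m).
#' @export
wall_points <- function(mesh) {
  f <- dplyr::filter(mesh$faces, .data$tag %in% c("wall", "septum"))
  f <- dplyr::mutate(f,
                     component = paste(.data$tag, .data$side, sep = "_"),
                     coord = ifelse(.data$side %in% c("N", "S"),
                                    .data$x, .data$y),
                     h = ifelse(.data$side %in% c("N", "S"),
                                mesh$dy, mesh$dx))
  f <- dplyr::arrange(f, .data$component, .data$coord)
  f$arc_length_m <- f$coord
  f$point_id <- seq_len(nrow(f))
  f[, c("point_id", "i", "j", "side", "tag", "x", "y", "arc_length_m", "h")]
}

# tangential velocity at the first and second cell centres off a wall face
wall_tangential <- function(state, mesh, wp) {
  nx <- mesh$nx; ny <- mesh$ny
  ucc <- (state$u[1:nx, , drop = FALSE] +
            state$u[2:(nx + 1L), , drop = FALSE]) / 2
  vcc <- (state$v[, 1:ny, drop = FALSE] +
            state$v[, 2:(ny + 1L), drop = FALSE]) / 2
  n <- nrow(wp)
  u1 <- numeric(n); u2 <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    i <- wp$i[k]; j <- wp$j[k]
    if (wp$side[k] %in% c("N", "S")) {
      u1[k] <- ucc[i, j]
      j2 <- if (wp$side[k] == "N") j - 1L else j + 1L
      if (j2 >= 1L && j2 <= ny && mesh$fluid[i, j2]) u2[k] <- ucc[i, j2]
    } else {
      u1[k] <- vcc[i, j]
      i2 <- if (wp$side[k] == "E") i - 1L else i + 1L
      if (i2 >= 1L && i2 <= nx && mesh$fluid[i2, j]) u2[k] <- vcc[i2, j]
    }
  }
  list(u1 = u1, u2 = u2)
}

wall_gradient <- function(u1, u2, h) {
  # quadratic one-sided fit through the wall (u = 0) and two cell centres
  # at h/2 and 3h/2; falls back to the linear one-point form at stair steps
  g <- ifelse(is.na(u2), 2 * u1 / h, (9 * u1 - u2) / (3 * h))
  g
}

#' Wall shear stress time series
#'
#' Extracts the wall shear stress vector at every wall point and stored
#' time of a flow solution: \eqn{\tau_w = \mu(\dot\gamma_w)\,\partial u_t/
#' \partial n} with the wall-normal gradient of the tangential velocity
#' evaluated by a one-sided quadratic fit through the no-slip wall (exact
#' for parabolic profiles). The sign encodes the direction along the wall
#' tangent (+x for horizontal wall segments, +y for vertical ones).
#'
#' @param series A `flow_series` from [solve_transient()] (or a single
#'   `flow_state`, treated as one steady snapshot).
#' @param mesh The [vessel_mesh][build_vessel()] the solution lives on.
#' @param rheology A [rheology_params()] for the wall viscosity.
#' @return A [wss_series()] tibble: `point_id`, `arc_length_m`, `time_s`,
#'   `wss_x`, `wss_y` (Pa), with the period as attribute.
#' @export
wall_shear_stress <- function(series, mesh, rheology = rheology_params()) {
  if (inherits(series, "flow_state")) {
    series <- as_flow_series(series, mesh)
  }
  stopifnot(inherits(series, "flow_series"))
  wp <- wall_points(mesh)
  out <- purrr::map_dfr(seq_along(series$states), function(k) {
    stt <- series$states[[k]]
    tg <- wall_tangential(stt, mesh, wp)
    g <- wall_gradient(tg$u1, tg$u2, wp$h)
    mu_w <- apparent_viscosity(abs(g), rheology)
    tau <- mu_w * g
    tibble::tibble(point_id = wp$point_id,
                   arc_length_m = wp$arc_length_m,
                   time_s = series$times[k],
                   wss_x = ifelse(wp$side %in% c("N", "S"), tau, 0),
                   wss_y = ifelse(wp$side %in% c("N", "S"), 0, tau),
                   x = wp$x, y = wp$y)
  })
  wss_series(out, period = series$period)
}

#' Wall Y+ of a flow state
#'
#' Dimensionless first-node wall distance \eqn{y^+ = y\,u_\tau/\nu} with
#' friction velocity \eqn{u_\tau = \sqrt{|\tau_w|/\rho}} and `y` the
#' distance of the first cell centre from the wall, the standard check of
#' near-wall mesh resolution.
#'
#' @param state A `flow_state`.
#' @param mesh The mesh it lives on.
#' @param rheology A [rheology_params()].
#' @return A tibble of wall points with columns `point_id`,
#'   `arc_length_m`, `tau_w` (Pa) and `y_plus`.
#' @export
wall_y_plus <- function(state, mesh, rheology = rheology_params()) {
  stopifnot(inherits(state, "flow_state"))
  wp <- wall_points(mesh)
  tg <- wall_tangential(state, mesh, wp)
  g <- wall_gradient(tg$u1, tg$u2, wp$h)
  mu_w <- apparent_viscosity(abs(g), rheology)
  tau <- abs(mu_w * g)
  u_tau <- sqrt(tau / rheology$density)
  nu_w <- mu_w / rheology$density
  tibble::tibble(point_id = wp$point_id, arc_length_m = wp$arc_length_m,
                 tau_w = tau, y_plus = (wp$h / 2) * u_tau / nu_w)
}

# ---- diagnostics ---------------------------------------------------------

speed_cc <- function(state, mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  ucc <- (state$u[1:nx, , drop = FALSE] +
            state$u[2:(nx + 1L), , drop = FALSE]) / 2
  vcc <- (state$v[, 1:ny, drop = FALSE] +
            state$v[, 2:(ny + 1L), drop = FALSE]) / 2
  sqrt(ucc^2 + vcc^2)
}

#' Net boundary mass flux of a flow state
#'
#' Integrates the velocity over the inlet and outlet boundaries and
#' returns the net flux relative to the inlet flux; for a converged state
#' of the projection solver this is at round-off level, verifying discrete
#' mass conservation.
#'
#' @param state A `flow_state`.
#' @param mesh The mesh it lives on.
#' @return A tibble with `q_in`, `q_out` (m^3/s for axisymmetric meshes,
#'   m^2/s per unit depth for planar ones) and `relative_imbalance`.
#' @export
mass_balance <- function(state, mesh) {
  st_areas <- face_areas(mesh)
  ji <- which(mesh$inlet_open & mesh$fluid[1, ])
  jo <- which(mesh$outlet_open & mesh$fluid[mesh$nx, ])
  q_in <- sum(state$u[1L, ji] * st_areas$A_in[ji])
  q_out <- sum(state$u[mesh$nx + 1L, jo] * st_areas$A_out[jo])
  tibble::tibble(q_in = q_in, q_out = q_out,
                 relative_imbalance = abs(q_in - q_out) /
                   max(abs(q_in), 1e-300))
}

face_areas <- function(mesh) {
  yc <- mesh_yc(mesh)
  w <- if (mesh$axisymmetric) 2 * pi * yc else rep(1, mesh$ny)
  list(A_in = w * mesh$dy, A_out = w * mesh$dy)
}

#' Flux through an axial station, split by lumen
#'
#' Integrates the axial velocity over the cross-section at the grid face
#' closest to `x_station`. For dissected meshes the rows below the septum
#' band count as the true lumen and rows above as the false lumen; where
#' no septum is present the whole section is reported as `lumen = "all"`.
#'
#' @param state A `flow_state`.
#' @param mesh The mesh.
#' @param x_station Axial position, m.
#' @return A tibble with columns `lumen` and `flux` (m^3/s axisymmetric,
#'   m^2/s planar).
#' @export
lumen_flux <- function(state, mesh, x_station) {
  i <- max(1L, min(mesh$nx + 1L,
                   as.integer(round((x_station - mesh$x0) / mesh$dx)) + 1L))
  icell <- max(1L, min(mesh$nx, i))
  yc <- mesh_yc(mesh)
  w <- if (mesh$axisymmetric) 2 * pi * yc else rep(1, mesh$ny)
  uface <- state$u[i, ]
  sep <- which(mesh$septum[icell, ])
  fl <- mesh$fluid[icell, ]
  if (length(sep) == 0L) {
    return(tibble::tibble(lumen = "all",
                          flux = sum(uface[fl] * w[fl] * mesh$dy)))
  }
  below <- seq_len(mesh$ny) < min(sep)
  above <- seq_len(mesh$ny) > max(sep)
  tibble::tibble(
    lumen = c("true", "false"),
    flux = c(sum(uface[fl & below] * w[fl & below] * mesh$dy),
             sum(uface[fl & above] * w[fl & above] * mesh$dy)))
}

#' Cycle-mean flux per lumen over a flow series
#'
#' @param series A `flow_series`.
#' @param mesh The mesh.
#' @param x_station Axial position, m.
#' @return A tibble with `lumen` and `mean_flux`.
#' @export
cycle_mean_flux <- function(series, mesh, x_station) {
  all <- purrr::map_dfr(series$states, lumen_flux, mesh = mesh,
                        x_station = x_station)
  dplyr::summarise(dplyr::group_by(all, .data$lumen),
                   mean_flux = mean(.data$flux), .groups = "drop")
}
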