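#' Blood rheology parameters
#'
#' Container for the material constants of a generalized-Newtonian blood
#' model: mass density plus the four Carreau-Yasuda constants. The defaults
#' are the standard whole-blood values used in aortic CFD studies
#' (density 1060 kg/m^3, infinite-shear viscosity 0.0035 Pa s, zero-shear
#' viscosity 0.056 Pa s, relaxation time 3.313 s, power-law exponent 0.3568).
#' Setting `mu_zero = mu_inf` recovers a Newtonian fluid, in which case
#' `lambda_time` and `power_n` are irrelevant.
#'
#' @param density Mass density in kg/m^3. Must be positive.
#' @param mu_inf Infinite-shear (high shear rate plateau) viscosity, Pa s.
#' @param mu_zero Zero-shear (low shear rate plateau) viscosity, Pa s.
#'   Must satisfy `mu_zero >= mu_inf`.
#' @param lambda_time Relaxation time constant, s. Non-negative.
#' @param power_n Power-law exponent, dimensionless, in (0, 1]. Values
#'   below 1 give shear-thinning; 1 is the Newtonian limit.
#'
#' @return An object of class `rheology_params` (a named list).
#' @examples
#' blood <- rheology_params()
#' apparent_viscosity(0, blood)     # zero-shear plateau, 0.056 Pa s
#' apparent_viscosity(1e8, blood)   # high-shear plateau, ~0.0035 Pa s
#' @export
rheology_params <- function(density = 1060,
                            mu_inf = 0.0035,
                            mu_zero = 0.056,
                            lambda_time = 3.313,
                            power_n = 0.3568) {
  stopifnot(is.numeric(density), length(density) == 1L,
            is.numeric(mu_inf), length(mu_inf) == 1L,
            is.numeric(mu_zero), length(mu_zero) == 1L,
            is.numeric(lambda_time), length(lambda_time) == 1L,
            is.numeric(power_n), length(power_n) == 1L)
  if (!is.finite(density) || density <= 0) {
    stop("`density` must be positive and finite", call. = FALSE)
  }
  if (!is.finite(mu_inf) || mu_inf <= 0) {
    stop("`mu_inf` must be positive and finite", call. = FALSE)
  }
  if (!is.finite(mu_zero) || mu_zero < mu_inf) {
    stop("`mu_zero` must be finite and >= `mu_inf`", call. = FALSE)
  }
  if (!is.finite(lambda_time) || lambda_time < 0) {
    stop("`lambda_time` must be non-negative", call. = FALSE)
  }
  if (!is.finite(power_n) || power_n <= 0 || power_n > 1) {
    stop("`power_n` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(density = density, mu_inf = mu_inf, mu_zero = mu_zero,
         lambda_time = lambda_time, power_n = power_n),
    class = "rheology_params"
  )
}

#' @export
print.rheology_params <- function(x, ...) {
  cat("<rheology_params>\n")
  cat(sprintf("  density     %g kg/m^3\n", x$density))
  cat(sprintf("  mu_inf      %g Pa s\n", x$mu_inf))
  cat(sprintf("  mu_zero     %g Pa s\n", x$mu_zero))
  cat(sprintf("  lambda_time %g s\n", x$lambda_time))
  cat(sprintf("  power_n     %g\n", x$power_n))
  if (is_newtonian(x)) cat("  (Newtonian: mu_zero == mu_inf)\n")
  invisible(x)
}

#' Is a rheology Newtonian?
#'
#' @param params A [rheology_params()] object.
#' @return `TRUE` when the zero-shear and infinite-shear plateaus coincide.
#' @export
is_newtonian <- function(params) {
  stopifnot(inherits(params, "rheology_params"))
  isTRUE(all.equal(params$mu_zero, params$mu_inf, tolerance = 1e-12))
}

#' Carreau-Yasuda apparent viscosity
#'
#' Evaluates the shear-thinning viscosity law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
#'   \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2}}
#' which interpolates between the zero-shear plateau \eqn{\mu_0} at rest and
#' the infinite-shear plateau \eqn{\mu_\infty} at high shear rate. The
#' exponent `(n - 1)/2` is negative for shear-thinning blood (`n < 1`), so
#' the result is monotone non-increasing in the shear rate and bounded in
#' \eqn{[\mu_\infty, \mu_0]}.
#'
#' @param shear_rate Shear-rate magnitude(s) \eqn{\dot\gamma} in 1/s;
#'   vectorized, all values must be non-negative and finite.
#' @param params A [rheology_params()] object.
#' @return Apparent viscosity in Pa s, same length as `shear_rate`.
#' @seealso [shear_rate_magnitude()] for computing \eqn{\dot\gamma} from a
#'   velocity gradient.
#' @export
apparent_viscosity <- function(shear_rate, params = rheology_params()) {
  stopifnot(inherits(params, "rheology_params"), is.numeric(shear_rate))
  if (any(!is.finite(shear_rate)) || any(shear_rate < 0)) {
    stop("`shear_rate` must be non-negative and finite", call. = FALSE)
  }
  mu_inf <- params$mu_inf
  dmu <- params$mu_zero - mu_inf
  if (dmu == 0) {
    return(rep(mu_inf, length(shear_rate)))
  }
  mu_inf + dmu * (1 + (params$lambda_time * shear_rate)^2)^((params$power_n - 1) / 2)
}

#' Shear-rate magnitude of a velocity gradient tensor
#'
#' Computes \eqn{\dot\gamma = \sqrt{2\,D : D}} where
#' \eqn{D = (\nabla u + \nabla u^T)/2} is the rate-of-deformation tensor,
#' the standard scalar shear measure for generalized-Newtonian fluids. For
#' simple shear (a single off-diagonal entry `s`) the result is `s`; any
#' purely antisymmetric (rigid rotation) gradient gives zero.
#'
#' @param velocity_gradient A 2x2 or 3x3 numeric matrix of velocity
#'   derivatives in 1/s, entry (i, j) holding \eqn{\partial u_i/\partial x_j}.
#' @return Scalar shear-rate magnitude in 1/s (non-negative).
#' @export
shear_rate_magnitude <- function(velocity_gradient) {
  g <- velocity_gradient
  if (!is.matrix(g) || nrow(g) != ncol(g) || !nrow(g) %in% c(2L, 3L)) {
    stop("`velocity_gradient` must be a 2x2 or 3x3 matrix", call. = FALSE)
  }
  if (any(!is.finite(g))) {
    stop("`velocity_gradient` must have finite entries", call. = FALSE)
  }
  d <- (g + t(g)) / 2
  sqrt(2 * sum(d * d))
}

#' Parameters of the algebraic SST closure
#'
#' Bundles the local quantities entering the shear-stress-transport (SST)
#' eddy-viscosity closure: turbulent kinetic energy `k`, specific
#' dissipation `omega`, wall distance `d`, strain-rate magnitude `S`,
#' kinematic viscosity `nu`, and the model constants `a1` and `beta_star`.
#' The constants default to the standard literature values a1 = 0.31 and
#' beta* = 0.09. Only the algebraic pieces of the closure are evaluated
#' here (blending function, eddy viscosity, stress tensor); the k and omega
#' transport equations are not solved by this package.
#'
#' @param turbulent_kinetic_energy k, m^2/s^2, non-negative.
#' @param specific_dissipation omega, 1/s, positive.
#' @param wall_distance d, distance to the nearest wall, m, positive.
#' @param strain_rate S, strain-rate magnitude, 1/s, non-negative.
#' @param kinematic_viscosity nu, m^2/s, positive.
#' @param a1 Structure constant, dimensionless.
#' @param beta_star The beta* model constant, dimensionless.
#' @return An object of class `sst_closure_params`.
#' @export
sst_closure_params <- function(turbulent_kinetic_energy,
                               specific_dissipation,
                               wall_distance,
                               strain_rate = 0,
                               kinematic_viscosity = 3.3e-6,
                               a1 = 0.31,
                               beta_star = 0.09) {
  k <- turbulent_kinetic_energy
  omega <- specific_dissipation
  if (!is.finite(k) || k < 0) stop("k must be non-negative", call. = FALSE)
  if (!is.finite(omega) || omega <= 0) {
    stop("`specific_dissipation` (omega) must be positive", call. = FALSE)
  }
  if (!is.finite(wall_distance) || wall_distance <= 0) {
    stop("`wall_distance` must be positive", call. = FALSE)
  }
  if (!is.finite(strain_rate) || strain_rate < 0) {
    stop("`strain_rate` must be non-negative", call. = FALSE)
  }
  if (!is.finite(kinematic_viscosity) || kinematic_viscosity <= 0) {
    stop("`kinematic_viscosity` must be positive", call. = FALSE)
  }
  structure(
    list(turbulent_kinetic_energy = k,
         specific_dissipation = omega,
         wall_distance = wall_distance,
         strain_rate = strain_rate,
         kinematic_viscosity = kinematic_viscosity,
         a1 = a1, beta_star = beta_star),
    class = "sst_closure_params"
  )
}

#' SST second blending function F2
#'
#' Evaluates \eqn{F_2 = \tanh(\mathrm{arg}_2^2)} with
#' \deqn{\mathrm{arg}_2 = \max\!\left(\frac{2\sqrt{k}}{\beta^* \omega d},
#'   \frac{500\,\nu}{\omega d^2}\right)}
#' the wall-proximity argument of the SST model. The result lies in (0, 1]
#' and decreases with wall distance for fixed k, omega and nu.
#'
#' @param closure An [sst_closure_params()] object.
#' @return F2, dimensionless, in (0, 1].
#' @export
sst_blending_f2 <- function(closure) {
  stopifnot(inherits(closure, "sst_closure_params"))
  tanh(sst_arg2(closure)^2)
}

#' @rdname sst_blending_f2
#' @export
sst_arg2 <- function(closure) {
  stopifnot(inherits(closure, "sst_closure_params"))
  k <- closure$turbulent_kinetic_energy
  omega <- closure$specific_dissipation
  d <- closure$wall_distance
  max(2 * sqrt(k) / (closure$beta_star * omega * d),
      500 * closure$kinematic_viscosity / (omega * d^2))
}

#' SST eddy (turbulent) viscosity
#'
#' Evaluates \eqn{\mu_t = a_1 \rho k / \max(a_1 \omega, S F_2)}. When
#' \eqn{S F_2 \le a_1 \omega} this reduces to the k-omega form
#' \eqn{\rho k / \omega}; otherwise the strain-rate limiter is active.
#'
#' @param closure An [sst_closure_params()] object.
#' @param density Fluid density in kg/m^3.
#' @param f2 Optional blending function value; computed from `closure` via
#'   [sst_blending_f2()] when missing.
#' @return Eddy viscosity in Pa s (non-negative).
#' @export
turbulent_viscosity <- function(closure, density, f2 = NULL) {
  stopifnot(inherits(closure, "sst_closure_params"))
  if (!is.finite(density) || density <= 0) {
    stop("`density` must be positive", call. = FALSE)
  }
  if (is.null(f2)) f2 <- sst_blending_f2(closure)
  a1 <- closure$a1
  k <- closure$turbulent_kinetic_energy
  omega <- closure$specific_dissipation
  a1 * density * k / max(a1 * omega, closure$strain_rate * f2)
}

#' Turbulent (Reynolds) stress tensor
#'
#' Boussinesq-form turbulent stress
#' \deqn{\tau_{ij} = \mu_t\left(\partial_j u_i + \partial_i u_j
#'   - \tfrac{2}{3}\,\partial_k u_k\,\delta_{ij}\right)
#'   - \tfrac{2}{3}\rho k\,\delta_{ij}.}
#' The result is symmetric and, for a divergence-free velocity field, has
#' trace \eqn{-2\rho k}.
#'
#' @param mu_t Eddy viscosity, Pa s.
#' @param velocity_gradient 2x2 or 3x3 velocity-gradient matrix, 1/s.
#' @param k Turbulent kinetic energy, m^2/s^2.
#' @param density Fluid density, kg/m^3.
#' @return A symmetric stress matrix in Pa, same dimension as the gradient.
#' @export
turbulent_stress <- function(mu_t, velocity_gradient, k, density) {
  g <- velocity_gradient
  if (!is.matrix(g) || nrow(g) != ncol(g) || !nrow(g) %in% c(2L, 3L)) {
    stop("`velocity_gradient` must be a 2x2 or 3x3 matrix", call. = FALSE)
  }
  if (any(!is.finite(g)) || !is.finite(mu_t) || !is.finite(k) ||
      !is.finite(density)) {
    stop("inputs must be finite", call. = FALSE)
  }
  n <- nrow(g)
  id <- diag(n)
  div <- sum(diag(g))
  mu_t * (g + t(g) - (2 / 3) * div * id) - (2 / 3) * density * k * id
}
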