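#' Carreau blood rheology and generalized-Newtonian tube flow
#'
#' Blood in the portal venous system flows slowly, especially after
#' splenectomy, so its shear-thinning rheology matters: apparent viscosity
#' rises steeply at the low shear rates found in near-stagnant regions. The
#' Carreau law
#' \deqn{\mu(\dot\gamma) = \mu_\infty + (\mu_0-\mu_\infty)
#'       \left[1+(\lambda\dot\gamma)^2\right]^{(n-1)/2}}
#' interpolates between a zero-shear plateau `mu0` and an infinite-shear
#' plateau `mu_inf` with relaxation time `lambda_s` and power index `n`.
#'
#' For steady, fully developed flow of a generalized Newtonian fluid in a
#' circular tube, the Weissenberg-Rabinowitsch-Mooney relation ties the
#' volumetric flow rate to the wall shear stress:
#' \deqn{Q(\tau_w) = \frac{\pi R^3}{\tau_w^3}
#'       \int_0^{\tau_w} \tau^2 \, \dot\gamma(\tau)\, d\tau,}
#' where \eqn{\dot\gamma(\tau)} inverts the constitutive law
#' \eqn{\tau = \mu(\dot\gamma)\dot\gamma}. `Q(tau_w)` is strictly
#' increasing, so the inversion for `tau_w` at prescribed `Q` is a
#' globally convergent bracketed root find.
#'
#' @name rheology
NULL

#' Carreau viscosity parameters
#'
#' Defaults are a widely used four-parameter Carreau fit for human blood.
#' All parameters are configuration-overridable.
#'
#' @param mu0 zero-shear viscosity, Pa.s.
#' @param mu_inf infinite-shear viscosity, Pa.s (`0 < mu_inf <= mu0`).
#' @param lambda_s relaxation time, s (>= 0).
#' @param n power index in (0, 1].
#' @return an object of class `carreau_params`.
#' @export
carreau_params <- function(mu0 = 0.056, mu_inf = 0.00345,
                           lambda_s = 3.313, n = 0.3568) {
  if (!(mu_inf > 0) || !(mu0 >= mu_inf))
    stop("require mu0 >= mu_inf > 0", call. = FALSE)
  if (lambda_s < 0) stop("lambda_s must be >= 0", call. = FALSE)
  if (!(n > 0 && n <= 1)) stop("n must be in (0, 1]", call. = FALSE)
  structure(list(mu0 = mu0, mu_inf = mu_inf, lambda_s = lambda_s, n = n),
            class = "carreau_params")
}

#' Carreau apparent viscosity at a shear rate
#'
#' @param gamma_dot shear rate, 1/s (vectorized, >= 0).
#' @param params a [carreau_params()] object.
#' @return apparent viscosity in Pa.s, bounded by `mu_inf` and `mu0` and
#'   non-increasing in `gamma_dot` for `n < 1`.
#' @export
carreau_viscosity <- function(gamma_dot, params = carreau_params()) {
  if (any(gamma_dot < 0)) stop("gamma_dot must be >= 0", call. = FALSE)
  with(params, mu_inf + (mu0 - mu_inf) *
         (1 + (lambda_s * gamma_dot)^2)^((n - 1) / 2))
}

# shear stress tau(gamma) = mu(gamma) * gamma, and its derivative
carreau_stress <- function(gamma_dot, params) {
  carreau_viscosity(gamma_dot, params) * gamma_dot
}

carreau_stress_deriv <- function(gamma_dot, params) {
  with(params, {
    u <- 1 + (lambda_s * gamma_dot)^2
    mu <- mu_inf + (mu0 - mu_inf) * u^((n - 1) / 2)
    dmu <- (mu0 - mu_inf) * (n - 1) * lambda_s^2 * gamma_dot * u^((n - 3) / 2)
    mu + gamma_dot * dmu
  })
}

#' Invert the constitutive law: shear rate from shear stress
#'
#' Finds the unique `gamma_dot >= 0` with
#' `carreau_viscosity(gamma_dot) * gamma_dot == tau`. Because
#' `mu_inf <= mu <= mu0`, the root is bracketed in
#' `[tau/mu0, tau/mu_inf]`; `tau(gamma)` is strictly increasing for valid
#' parameters, so the bracketed solve converges globally.
#'
#' @param tau shear stress, Pa (>= 0).
#' @param params a [carreau_params()] object.
#' @param tol relative tolerance on the returned shear rate.
#' @return shear rate in 1/s.
#' @export
shear_rate_from_stress <- function(tau, params = carreau_params(),
                                   tol = 1e-12) {
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  if (tau == 0) return(0)
  lo <- tau / params$mu0
  hi <- tau / params$mu_inf
  if (lo == hi) return(lo)  # Newtonian degenerate case
  r <- uniroot(function(g) carreau_stress(g, params) - tau,
               interval = c(lo, hi), tol = tol * hi, maxiter = 1000L)
  # Newton polish to push the residual to machine precision
  g <- r$root
  for (i in 1:3) {
    f <- carreau_stress(g, params) - tau
    g <- g - f / carreau_stress_deriv(g, params)
  }
  g
}

# WRM flow rate at a prescribed wall shear *rate* gamma_w, via the
# substitution tau = tau(gamma): Q = pi R^3 / tau_w^3 *
# int_0^{gamma_w} tau(g)^2 g tau'(g) dg  (avoids nested root finds).
wrm_flow_at_wall_rate <- function(gamma_w, R, params) {
  if (gamma_w <= 0) return(0)
  tau_w <- carreau_stress(gamma_w, params)
  integrand <- function(g)
    carreau_stress(g, params)^2 * g * carreau_stress_deriv(g, params)
  val <- integrate(integrand, lower = 0, upper = gamma_w,
                   rel.tol = 1e-12, abs.tol = 1e-300,
                   subdivisions = 400L)$value
  pi * R^3 * val / tau_w^3
}

#' Wall shear stress from flow rate in a circular tube
#'
#' Solves the Weissenberg-Rabinowitsch-Mooney relation for the wall shear
#' stress of steady, fully developed generalized-Newtonian flow at
#' volumetric rate `Q` in a tube of radius `R`. Reduces to the Poiseuille
#' closed form `4*mu*Q/(pi*R^3)` in the Newtonian limit. The cross-sectional
#' mean velocity fully determines `tau_w` in fully developed flow, so a
#' parabolic (or any developed) inlet profile needs no separate treatment.
#'
#' @param Q volumetric flow rate, m^3/s (>= 0).
#' @param R tube radius, m (> 0).
#' @param params a [carreau_params()] object.
#' @return wall shear stress in Pa; strictly increasing in `Q`.
#' @export
wall_shear_stress_tube <- function(Q, R, params = carreau_params()) {
  if (Q < 0) stop("Q must be >= 0", call. = FALSE)
  if (R <= 0) stop("R must be > 0", call. = FALSE)
  if (Q == 0) return(0)
  # Newtonian bounds on tau_w bracket the wall shear rate
  tau_lo <- 4 * params$mu_inf * Q / (pi * R^3)
  tau_hi <- 4 * params$mu0 * Q / (pi * R^3)
  g_lo <- 0.999999 * tau_lo / params$mu0
  g_hi <- 1.000001 * tau_hi / params$mu_inf
  r <- uniroot(function(g) wrm_flow_at_wall_rate(g, R, params) - Q,
               interval = c(g_lo, g_hi), tol = 1e-11 * g_hi,
               maxiter = 1000L)
  carreau_stress(r$root, params)
}
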