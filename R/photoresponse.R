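#' Convert a whole-cell current into a concentration rate
#'
#' `J` pA crossing the membrane of a compartment of volume `V` um^3 as ions
#' of charge `z` changes concentration at `J * 1e9 / (z * F * V)` uM/s.
#' Buffering is applied by the caller.
#'
#' @param J Current (pA).
#' @param z_charge Ion charge (>= 1).
#' @param V Compartment volume (um^3, > 0).
#' @param F_const Faraday constant (C/mol).
#' @return Rate in uM/s.
#' @examples
#' current_to_conc_rate(1, 2, 4.2)  # ~ 1233 uM/s
#' @export
current_to_conc_rate <- function(J, z_charge, V, F_const = 96500) {
  if (any(V <= 0)) stop("current_to_conc_rate: volume must be positive")
  if (any(z_charge < 1)) stop("current_to_conc_rate: charge must be >= 1")
  J * 1e9 / (z_charge * F_const * V)
}

#' Light-driven cGMP hydrolysis rate coefficient
#'
#' Volumetric hydrolysis rate contributed by activated PDE at subunit
#' surface density `Estar_sigma`: the per-dimer surface rate
#' `k_sigma_hyd_star` acts on `Estar_sigma / 2` dimers per um^2, converted
#' to a volumetric rate by the same volume-to-surface factor `eta` used for
#' density conversions.
#'
#' @param Estar_sigma Activated-subunit density (um^-2, >= 0); may be a vector.
#' @param p A [cone_params()] object.
#' @param derived Optional precomputed [resolve_alpha_min()] result.
#' @return First-order hydrolysis rate (s^-1).
#' @export
beta_light <- function(Estar_sigma, p, derived = resolve_alpha_min(p)) {
  if (any(Estar_sigma < 0)) stop("beta_light: Estar_sigma must be nonnegative")
  derived$k_sigma_hyd_star * (Estar_sigma / 2) / (derived$eta * NM_TO_UM)
}

#' Simulate a flash response
#'
#' Couples the activation cascade one-way into well-stirred cGMP/calcium
#' dynamics, starting from the dark steady state:
#' \deqn{d[cG]/dt = \alpha([Ca]) - (\beta_{dark} + \beta_{light}(E^*))[cG]}
#' \deqn{d[Ca]/dt = \frac{1}{B_{Ca}}\left(\frac{f_{Ca} J_{cG}([cG])}{2FV} -
#'   \frac{J_{ex}([Ca])}{FV}\right) \cdot 10^9}
#' CNG influx carries charge 2 per calcium ion, exchanger efflux charge 1.
#'
#' @inheritParams simulate_cascade
#' @param dark Optional precomputed [solve_dark_state()] result.
#' @return A `photoresponse_trace` data frame with columns `t`, cascade
#'   densities, `cG`, `Ca` (uM), currents `J_cG`, `J_ex`, `J` (pA), the
#'   response `drop = J_dark - J` (pA) and `Estar_total` (molecules).
#'   Attributes: `phi`, `J_dark`, `params`, solver settings.
#' @examples
#' tr <- simulate_response(cone_params(), phi = 940, t_end = 0.05, dt = 1e-3)
#' max(tr$drop) / attr(tr, "J_dark")
#' @export
simulate_response <- function(p, phi, t_end = 0.5, dt = 1e-4,
                              rtol = 1e-8, atol = 1e-10,
                              dark = solve_dark_state(p)) {
  stopifnot(inherits(p, "cone_params"), phi >= 0, t_end > 0, dt > 0)
  if (!dark$exists)
    stop("simulate_response: no dark steady state for these parameters")
  d <- resolve_alpha_min(p)
  geom <- derive_geometry(p)
  times <- seq(0, t_end, by = dt)
  y0 <- c(cascade_y0(p, phi, geom), cG = dark$cG_dark, Ca = dark$Ca_dark)
  parms <- c(p$k_R, p$nu_RG, p$k_GE, p$k_E, p$G_sigma, 2 * p$PDE_sigma,
             p$beta_dark, d$k_sigma_hyd_star / (2 * d$eta * NM_TO_UM),
             d$alpha_min, p$alpha_max, p$K_cyc * 1e-3, p$m_cyc,
             p$JcG_max, p$K_cG, p$m_cG, p$f_Ca, p$Jex_sat, p$K_ex,
             p$B_Ca, 1e9 / (p$F_const * geom$V_cyto))
  sol <- deSolve::ode(y = y0, times = times, func = "photo_derivs",
                      parms = parms, dllname = "conesens",
                      initfunc = "photo_init", rtol = rtol, atol = atol)
  cG <- sol[, "cG"]; Ca <- sol[, "Ca"]
  if (any(!is.finite(cG)) || any(!is.finite(Ca)) ||
      any(cG < -atol) || any(Ca < -atol))
    stop("simulate_response: integration produced negative concentrations")
  JcG <- cng_current(pmax(cG, 0), p)
  Jex <- exchanger_current(pmax(Ca, 0), p)
  E <- pmax(sol[, "Estar"], 0)
  out <- data.frame(t = sol[, "time"],
                    Rstar_sigma = pmax(sol[, "Rstar"], 0),
                    Gstar_sigma = pmax(sol[, "Gstar"], 0),
                    Estar_sigma = E,
                    Estar_total = E * geom$S_disc,
                    cG = cG, Ca = Ca,
                    J_cG = JcG, J_ex = Jex, J = JcG + Jex,
                    drop = dark$J_dark - (JcG + Jex))
  attr(out, "phi") <- phi
  attr(out, "J_dark") <- dark$J_dark
  attr(out, "params") <- p
  attr(out, "solver") <- list(rtol = rtol, atol = atol, dt = dt, t_end = t_end)
  class(out) <- c("photoresponse_trace", "data.frame")
  out
}

#' Write a response or cascade trace to CSV
#'
#' @param trace A trace data frame.
#' @param file Output path.
#' @export
write_trace <- function(trace, file) {
  utils::write.csv(unclass_df(trace), file, row.names = FALSE)
  invisible(file)
}
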