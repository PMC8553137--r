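#' Derived outer-segment geometry
#'
#' Continuum frustum approximation of the disc stack: the outer segment
#' tapers linearly from base radius `R_b` to tip radius `R_t` over length
#' `H`, carrying `n_discs` discs with two active faces each. The cytosolic
#' volume is the interdiscal fraction `nu / (1 + nu)` of the frustum volume,
#' and the channel-bearing lateral area is the `omega0 / (2 pi)` fraction of
#' the frustum's lateral surface (carried for completeness; whole-cell
#' currents make it inert in the well-stirred reduction).
#'
#' @param p A [cone_params()] object.
#' @return List with `S_disc` (um^2), `V_cyto` (um^3), `Sigma_S` (um^2).
#' @examples
#' derive_geometry(cone_params())$V_cyto  # ~ 4.2 um^3
#' @export
derive_geometry <- function(p) {
  stopifnot(inherits(p, "cone_params"))
  quad <- (p$R_b^2 + p$R_b * p$R_t + p$R_t^2) / 3
  slant <- sqrt(p$H^2 + (p$R_b - p$R_t)^2)
  list(
    S_disc = 2 * p$n_discs * pi * quad,
    V_cyto = (p$nu / (1 + p$nu)) * pi * p$H * quad,
    Sigma_S = (p$omega0 / (2 * pi)) * pi * (p$R_b + p$R_t) * slant
  )
}

cascade_y0 <- function(p, phi, geom = derive_geometry(p)) {
  c(Rstar = phi / geom$S_disc, Gstar = 0, Estar = 0)
}

#' Simulate the disc-surface activation cascade
#'
#' Integrates the R* -> G* -> E* front-end with first-order shutoffs:
#' \deqn{dR^*/dt = -k_R R^*}
#' \deqn{dG^*/dt = \nu_{RG} R^* (G_\sigma - G^* - E^*)/G_\sigma - k_{GE}(E_{tot} - E^*) G^*}
#' \deqn{dE^*/dt = k_{GE}(E_{tot} - E^*) G^* - k_E E^*}
#' where `E_tot = 2 PDE_sigma` is the activatable-subunit density (each
#' holoenzyme carries two independently activatable catalytic subunits, and
#' one G* is consumed per activated subunit). A uniform flash of `phi`
#' photoisomerizations starts `R*` at `phi / S_disc`.
#'
#' @param p A [cone_params()] object.
#' @param phi Flash strength in photoisomerizations (>= 0).
#' @param t_end End of integration (s).
#' @param dt Output grid spacing (s).
#' @param rtol,atol Integrator tolerances (stiff-capable `lsoda`).
#' @return A `cascade_trace` data frame: `t`, surface densities `Rstar_sigma`,
#'   `Gstar_sigma`, `Estar_sigma` (um^-2) and `Estar_total` (molecules,
#'   density times total disc area).
#' @examples
#' tr <- simulate_cascade(cone_params(), phi = 940, t_end = 0.05)
#' max(tr$Estar_total)
#' @export
simulate_cascade <- function(p, phi, t_end = 0.5, dt = 1e-4,
                             rtol = 1e-8, atol = 1e-12) {
  stopifnot(inherits(p, "cone_params"), phi >= 0, t_end > 0, dt > 0)
  geom <- derive_geometry(p)
  times <- seq(0, t_end, by = dt)
  y0 <- cascade_y0(p, phi, geom)
  if (phi == 0) {
    out <- data.frame(t = times, Rstar_sigma = 0, Gstar_sigma = 0,
                      Estar_sigma = 0, Estar_total = 0)
    class(out) <- c("cascade_trace", "data.frame")
    return(out)
  }
  parms <- c(p$k_R, p$nu_RG, p$k_GE, p$k_E, p$G_sigma, 2 * p$PDE_sigma)
  sol <- deSolve::ode(y = y0, times = times, func = "cascade_derivs",
                      parms = parms, dllname = "conesens",
                      initfunc = "cascade_init", rtol = rtol, atol = atol)
  E <- pmax(sol[, "Estar"], 0)
  tolE <- max(rtol * 2 * p$PDE_sigma, 1e-6)
  if (any(sol[, "Estar"] > 2 * p$PDE_sigma + tolE) ||
      any(sol[, "Gstar"] + sol[, "Estar"] > p$G_sigma * (1 + 1e-6) + tolE))
    stop("simulate_cascade: invariant violation beyond integrator tolerance")
  out <- data.frame(t = sol[, "time"],
                    Rstar_sigma = pmax(sol[, "Rstar"], 0),
                    Gstar_sigma = pmax(sol[, "Gstar"], 0),
                    Estar_sigma = E,
                    Estar_total = E * geom$S_disc)
  class(out) <- c("cascade_trace", "data.frame")
  out
}

#' Peak total activated-subunit production
#'
#' Convenience evaluator: maximum of `Estar_total` over a cascade trace,
#' with 3-point parabolic refinement around the grid maximum.
#'
#' @inheritParams simulate_cascade
#' @return Peak E* (molecules).
#' @export
peak_Estar <- function(p, phi = 940, t_end = 0.5, dt = 5e-4, ...) {
  tr <- simulate_cascade(p, phi, t_end = t_end, dt = dt, ...)
  refine_max(tr$t, tr$Estar_total)$y
}
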