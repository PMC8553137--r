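#' Construct a cone outer segment parameter set
#'
#' Bundles every symbol of the well-stirred cone phototransduction model with
#' a fixed unit normalization (uM, um, s, pA; `K_cyc` in nM; membrane
#' thicknesses in nm). Defaults are the best-fit mouse cone values obtained
#' by constrained stochastic optimization against a half-saturating flash
#' (940 photoisomerizations); they reproduce a circulating dark current of
#' about 26 pA.
#'
#' The minimum cyclase rate can be given three ways, recorded in
#' `alpha_min_mode`:
#' \describe{
#'   \item{`"a_min"`}{`a_min` in \[0, 1\] is authoritative; `alpha_min` is
#'     resolved as `a_min * xi` where `xi` is the largest admissible minimum
#'     cyclase rate compatible with a dark steady state (see
#'     [resolve_alpha_min()]). This is the parameterization used for global
#'     sensitivity sampling because it keeps coordinates independent.}
#'   \item{`"ratio"`}{`alpha_ratio = alpha_max/alpha_min` is authoritative
#'     (the form in which experimental constraints are usually quoted).}
#'   \item{`"direct"`}{`alpha_min` in uM/s is authoritative.}
#' }
#'
#' @param R_b,R_t,H Base radius, tip radius and length of the outer segment (um).
#' @param eps0 Disc thickness (nm).
#' @param nu Interdiscal-space to disc thickness ratio (unitless).
#' @param sigma Disc to sliver thickness ratio (unitless).
#' @param omega0 Open margin angle of the sliver (rad).
#' @param n_discs Number of discs (integer).
#' @param R_sigma,G_sigma,PDE_sigma Surface densities of pigment, transducin
#'   and PDE holoenzyme on disc membrane (um^-2).
#' @param k_R,k_E First-order shutoff rates of R* and of activated PDE
#'   subunits (s^-1).
#' @param nu_RG Rate of G* formation per R* (s^-1).
#' @param k_GE Coupling coefficient for PDE* formation by G* (um^2 s^-1).
#' @param beta_dark Dark turnover rate of cGMP (s^-1).
#' @param B_cG Cytoplasmic buffering power for cGMP (unitless).
#' @param kcat_Km Hydrolytic efficiency of the activated PDE dimer (uM^-1 s^-1).
#' @param alpha_max Maximum cGMP synthesis rate at zero calcium (uM s^-1).
#' @param a_min Relative position of the minimum cyclase rate inside its
#'   admissible interval \[0, xi\] (unitless, in \[0, 1\]).
#' @param alpha_ratio Ratio `alpha_max/alpha_min` (unitless); used when
#'   `alpha_min_mode = "ratio"`.
#' @param alpha_min Minimum cGMP synthesis rate at saturating calcium
#'   (uM s^-1); used when `alpha_min_mode = "direct"`.
#' @param alpha_min_mode Which of `a_min`, `alpha_ratio`, `alpha_min` is
#'   authoritative.
#' @param m_cyc Hill coefficient of cyclase inhibition by calcium.
#' @param K_cyc Half-saturating calcium for cyclase (nM).
#' @param B_Ca Cytoplasmic buffering power for calcium (unitless).
#' @param JcG_max Saturated CNG channel current (pA).
#' @param m_cG Hill coefficient of CNG channel opening by cGMP.
#' @param K_cG Half-activating cGMP for the CNG channel (uM).
#' @param f_Ca Fraction of CNG current carried by calcium (unitless, in (0,1)).
#' @param Jex_sat Saturated exchanger current (pA).
#' @param K_ex Half-saturating calcium for the exchanger (uM).
#' @param D_R,D_G,D_E,D_cG,D_Ca Diffusion coefficients (um^2 s^-1), carried
#'   for completeness; dynamically inert in the well-stirred reduction.
#' @param F_const Faraday constant (C mol^-1).
#' @param N_Av Avogadro number (mol^-1).
#'
#' @return An object of class `cone_params`: a named list of the above fields.
#' @examples
#' p <- cone_params()
#' derive_params(p)$nu_GE
#' @export
cone_params <- function(R_b = 0.6, R_t = 0.4, H = 13.4, eps0 = 16.8,
                        nu = 0.65, sigma = 1, omega0 = pi, n_discs = 400,
                        R_sigma = 10000, G_sigma = 253.82, PDE_sigma = 115,
                        k_R = 87.1, k_E = 82.3, nu_RG = 212, k_GE = 0.33,
                        beta_dark = 8.57, B_cG = 1.8, kcat_Km = 540,
                        alpha_max = 55.8,
                        a_min = NA_real_, alpha_ratio = 5.51,
                        alpha_min = NA_real_,
                        alpha_min_mode = c("ratio", "a_min", "direct"),
                        m_cyc = 2.3, K_cyc = 134,
                        B_Ca = 25.3, JcG_max = 3138, m_cG = 2.9, K_cG = 14.2,
                        f_Ca = 0.26, Jex_sat = 8.79, K_ex = 0.4,
                        D_R = 1.71, D_G = 1.42, D_E = 1.47, D_cG = 89.2,
                        D_Ca = 15,
                        F_const = 96500, N_Av = 6.02e23) {
  alpha_min_mode <- match.arg(alpha_min_mode)
  p <- list(
    R_b = R_b, R_t = R_t, H = H, eps0 = eps0, nu = nu, sigma = sigma,
    omega0 = omega0, n_discs = n_discs,
    R_sigma = R_sigma, G_sigma = G_sigma, PDE_sigma = PDE_sigma,
    k_R = k_R, k_E = k_E, nu_RG = nu_RG, k_GE = k_GE,
    beta_dark = beta_dark, B_cG = B_cG, kcat_Km = kcat_Km,
    alpha_max = alpha_max, a_min = a_min, alpha_ratio = alpha_ratio,
    alpha_min = alpha_min, alpha_min_mode = alpha_min_mode,
    m_cyc = m_cyc, K_cyc = K_cyc,
    B_Ca = B_Ca, JcG_max = JcG_max, m_cG = m_cG, K_cG = K_cG,
    f_Ca = f_Ca, Jex_sat = Jex_sat, K_ex = K_ex,
    D_R = D_R, D_G = D_G, D_E = D_E, D_cG = D_cG, D_Ca = D_Ca,
    F_const = F_const, N_Av = N_Av
  )
  class(p) <- "cone_params"
  validate_cone_params(p)
  p
}

#' @export
print.cone_params <- function(x, ...) {
  cat("<cone_params>\n")
  d <- tryCatch(derive_params(x), error = function(e) NULL)
  cat(sprintf("  geometry: R_b=%.3g R_t=%.3g um, H=%.3g um, %d discs\n",
              x$R_b, x$R_t, x$H, x$n_discs))
  cat(sprintf("  cascade:  nu_RG=%.3g /s, k_R=%.3g /s, k_E=%.3g /s\n",
              x$nu_RG, x$k_R, x$k_E))
  cat(sprintf("  cGMP:     beta_dark=%.3g /s, alpha_max=%.3g uM/s (alpha_min via '%s')\n",
              x$beta_dark, x$alpha_max, x$alpha_min_mode))
  if (!is.null(d))
    cat(sprintf("  resolved: alpha_min=%.4g uM/s, xi=%.4g uM/s, a_min=%.4g\n",
                d$alpha_min, d$xi, d$a_min))
  invisible(x)
}

validate_cone_params <- function(p) {
  pos <- c("R_b", "R_t", "H", "eps0", "nu", "sigma", "omega0", "n_discs",
           "R_sigma", "G_sigma", "PDE_sigma", "beta_dark", "B_cG", "kcat_Km",
           "alpha_max", "m_cyc", "K_cyc", "B_Ca", "JcG_max", "m_cG", "K_cG",
           "Jex_sat", "K_ex", "F_const", "N_Av")
  for (nm in pos) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a single positive finite number")
  }
  nonneg <- c("k_R", "k_E", "nu_RG", "k_GE", "D_R", "D_G", "D_E", "D_cG", "D_Ca")
  for (nm in nonneg) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("parameter '", nm, "' must be a single nonnegative finite number")
  }
  if (p$R_t > p$R_b) stop("tip radius R_t must not exceed base radius R_b")
  if (p$f_Ca <= 0 || p$f_Ca >= 1) stop("f_Ca must lie strictly in (0, 1)")
  if (p$m_cG < 1 || p$m_cyc < 1) stop("Hill coefficients m_cG, m_cyc must be >= 1")
  switch(p$alpha_min_mode,
    a_min = {
      if (is.na(p$a_min) || p$a_min < 0 || p$a_min > 1)
        stop("a_min must be in [0, 1] when alpha_min_mode = 'a_min'")
    },
    ratio = {
      if (is.na(p$alpha_ratio) || p$alpha_ratio < 1)
        stop("alpha_ratio = alpha_max/alpha_min must be >= 1")
    },
    direct = {
      if (is.na(p$alpha_min) || p$alpha_min < 0 || p$alpha_min > p$alpha_max)
        stop("alpha_min must satisfy 0 <= alpha_min <= alpha_max")
    }
  )
  invisible(p)
}

#' Modify fields of a parameter set
#'
#' @param p A [cone_params()] object.
#' @param ... Named fields to replace.
#' @return A revalidated `cone_params` object.
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "cone_params"))
  mods <- list(...)
  if (length(mods)) {
    bad <- setdiff(names(mods), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(mods)] <- mods
  }
  validate_cone_params(p)
  p
}

#' Volume-to-surface conversion factor
#'
#' Half the interdiscal-space thickness, `eta = nu * eps0 / 2`: the factor
#' converting a volumic concentration in the thin interdiscal space into an
#' equivalent surface density on the bounding disc membrane.
#'
#' @param nu Interdiscal/disc thickness ratio (> 0).
#' @param eps0 Disc thickness (nm, > 0).
#' @return eta in nm.
#' @examples
#' eta_factor(0.65, 16.8)  # 5.46 nm
#' @export
eta_factor <- function(nu, eps0) {
  if (any(!is.finite(nu)) || any(!is.finite(eps0)) || any(nu <= 0) || any(eps0 <= 0))
    stop("eta_factor: nu and eps0 must be positive")
  0.5 * nu * eps0
}

#' Convert a volumic concentration to a disc-surface density
#'
#' @param c_vol Concentration (uM).
#' @param eta Volume-to-surface factor (nm), from [eta_factor()].
#' @return Surface density (um^-2): `c_vol` in molecules/um^3 times eta in um.
#' @examples
#' surface_density_from_volumic(210, 5.5)  # ~ 700 um^-2 (transducin)
#' @export
surface_density_from_volumic <- function(c_vol, eta) {
  if (any(c_vol < 0) || any(eta <= 0))
    stop("surface_density_from_volumic: inputs must be positive")
  c_vol * UM_TO_MOLEC_PER_UM3 * (eta * NM_TO_UM)
}

#' Surface hydrolysis rate of cGMP by light-activated PDE
#'
#' Per-molecule volumetric hydrolytic efficiency of the activated dimer
#' divided by the cGMP buffering power: `(kcat_Km / (N_Av 1e-21)) / B_cG`.
#'
#' @param kcat_Km Hydrolytic efficiency of the PDE* dimer (uM^-1 s^-1).
#' @param B_cG Buffering power for cGMP (> 0).
#' @return Rate in um^3 s^-1.
#' @examples
#' k_hyd_light(540, 1.8)  # ~ 0.50
#' @export
k_hyd_light <- function(kcat_Km, B_cG) {
  if (any(kcat_Km < 0)) stop("k_hyd_light: kcat_Km must be nonnegative")
  if (any(B_cG <= 0)) stop("k_hyd_light: B_cG must be positive")
  (kcat_Km / UM_TO_MOLEC_PER_UM3) / B_cG
}

#' Surface hydrolysis rate of cGMP by dark-activated PDE
#'
#' Solves the dark hydrolysis balance `beta_dark [cG] = k_hyd PDE_sigma / eta [cG]`
#' for the surface rate constant.
#'
#' @param beta_dark Dark cGMP turnover (s^-1, >= 0).
#' @param eta Volume-to-surface factor (nm, > 0).
#' @param PDE_sigma PDE surface density (um^-2, > 0).
#' @return Rate in um^3 s^-1.
#' @examples
#' k_hyd_dark(8.57, 5.46, 115)  # ~ 4.1e-4
#' @export
k_hyd_dark <- function(beta_dark, eta, PDE_sigma) {
  if (any(beta_dark < 0)) stop("k_hyd_dark: beta_dark must be nonnegative")
  if (any(eta <= 0)) stop("k_hyd_dark: eta must be positive")
  if (any(PDE_sigma <= 0)) stop("k_hyd_dark: PDE_sigma must be positive")
  beta_dark * (eta * NM_TO_UM) / PDE_sigma
}

#' Rate of PDE* formation per G*
#'
#' @param k_GE Coupling coefficient (um^2 s^-1, >= 0).
#' @param PDE_sigma PDE surface density (um^-2, >= 0).
#' @return nu_GE in s^-1.
#' @examples
#' nu_GE_of(0.33, 115)  # 37.95
#' @export
nu_GE_of <- function(k_GE, PDE_sigma) {
  if (any(k_GE < 0) || any(PDE_sigma < 0))
    stop("nu_GE_of: inputs must be nonnegative")
  k_GE * PDE_sigma
}

#' Dark cGMP turnover from fractional PDE activity
#'
#' Converts a fractional dark activity of PDE (relative to its maximal
#' per-pigment activity) into a first-order dark turnover rate:
#' `frac_dark * max_activity * R_vol / cG_dark`.
#'
#' @param frac_dark Fraction of maximal activity expressed in darkness, in (0, 1)
#'   (0 allowed as a degenerate input).
#' @param max_activity Maximal activity (cGMP per pigment per s).
#' @param R_vol Volumic pigment concentration (uM).
#' @param cG_dark Dark cGMP concentration (uM, > 0).
#' @return beta_dark in s^-1.
#' @examples
#' beta_dark_from_activity(0.003, 18, 3000, 3)  # 54
#' beta_dark_from_activity(0.047, 18, 3000, 3)  # 846
#' @export
beta_dark_from_activity <- function(frac_dark, max_activity, R_vol, cG_dark) {
  if (any(frac_dark < 0) || any(frac_dark >= 1))
    stop("beta_dark_from_activity: frac_dark must be in [0, 1)")
  if (any(max_activity < 0) || any(R_vol < 0))
    stop("beta_dark_from_activity: inputs must be nonnegative")
  if (any(cG_dark <= 0)) stop("beta_dark_from_activity: cG_dark must be positive")
  frac_dark * max_activity * R_vol / cG_dark
}

#' Estimate cyclase rate bounds from enzyme pools and turnover numbers
#'
#' The minimum synthesis rate assumes the whole cyclase pool runs at the
#' basal turnover; the maximum assumes the GCAP-bound fraction runs at the
#' activated turnover.
#'
#' @param GC_free Free cyclase pool (uM).
#' @param rate_basal Basal turnover (cGMP per enzyme per s).
#' @param GC_GCAP GCAP-bound cyclase pool (uM).
#' @param rate_active Activated turnover (cGMP per enzyme per s).
#' @return List with `alpha_min_est`, `alpha_max_est` (uM s^-1) and their
#'   `ratio`.
#' @examples
#' cyclase_bounds_estimate(39, 1.7, 33, 5.7)$ratio  # ~ 2
#' @export
cyclase_bounds_estimate <- function(GC_free, rate_basal, GC_GCAP, rate_active) {
  if (any(c(GC_free, rate_basal, GC_GCAP, rate_active) < 0))
    stop("cyclase_bounds_estimate: inputs must be nonnegative")
  amin <- (GC_free + GC_GCAP) * rate_basal
  amax <- GC_free * rate_basal + GC_GCAP * rate_active
  if (GC_free + GC_GCAP == 0 || amin == 0)
    stop("cyclase_bounds_estimate: zero total cyclase pool, ratio undefined")
  list(alpha_min_est = amin, alpha_max_est = amax, ratio = amax / amin)
}

#' Upper admissible minimum cyclase rate
#'
#' `chi` solves `1 + (chi / (beta_dark K_cG))^m_cG = (1 - 2 Jex_sat /
#' (JcG_max f_Ca))^-1`; a dark steady state exists iff the minimum cyclase
#' rate lies strictly below `xi = min(alpha_max, chi)`. Solved by monotone
#' root bracketing (the left side is strictly increasing in `chi`).
#'
#' @param p A [cone_params()] object.
#' @param tol Relative root tolerance.
#' @return List with `chi` and `xi` (uM s^-1).
#' @keywords internal
chi_xi_of <- function(p, tol = 1e-12) {
  r <- 2 * p$Jex_sat / (p$JcG_max * p$f_Ca)
  if (!is.finite(r) || r >= 1)
    stop("no dark steady state possible: 2*Jex_sat/(JcG_max*f_Ca) = ",
         format(r), " >= 1")
  if (r <= 0) return(list(chi = 0, xi = 0))
  rhs <- 1 / (1 - r)
  bK <- p$beta_dark * p$K_cG
  g <- function(chi) 1 + (chi / bK)^p$m_cG - rhs
  hi <- bK
  while (g(hi) < 0) hi <- hi * 2
  chi <- stats::uniroot(g, c(0, hi), tol = tol * max(hi, 1))$root
  list(chi = chi, xi = min(p$alpha_max, chi))
}

#' Resolve the minimum cyclase rate and derived rate constants
#'
#' Computes the volume-to-surface factor, dark and light surface hydrolysis
#' rates, the PDE* formation rate per G*, and resolves `alpha_min` from
#' whichever of `a_min`, `alpha_ratio` or a direct value is authoritative in
#' `p` (see [cone_params()]). Under the `a_min` parameterization the
#' existence inequality for the dark steady state holds by construction for
#' every `a_min < 1`.
#'
#' @param p A [cone_params()] object.
#' @return List of class `derived_params` with fields `eta` (nm),
#'   `k_sigma_hyd`, `k_sigma_hyd_star` (um^3 s^-1), `nu_GE` (s^-1), `chi`,
#'   `xi`, `alpha_min` (uM s^-1) and the back-computed `a_min`.
#' @examples
#' d <- resolve_alpha_min(cone_params())
#' d$xi   # ~ 32.6 uM/s
#' @export
resolve_alpha_min <- function(p) {
  stopifnot(inherits(p, "cone_params"))
  cx <- chi_xi_of(p)
  alpha_min <- switch(p$alpha_min_mode,
    a_min = p$a_min * cx$xi,
    ratio = p$alpha_max / p$alpha_ratio,
    direct = p$alpha_min
  )
  eta <- eta_factor(p$nu, p$eps0)
  out <- list(
    eta = eta,
    k_sigma_hyd = k_hyd_dark(p$beta_dark, eta, p$PDE_sigma),
    k_sigma_hyd_star = k_hyd_light(p$kcat_Km, p$B_cG),
    nu_GE = nu_GE_of(p$k_GE, p$PDE_sigma),
    chi = cx$chi,
    xi = cx$xi,
    alpha_min = alpha_min,
    a_min = if (cx$xi > 0) alpha_min / cx$xi else 0
  )
  class(out) <- "derived_params"
  out
}

#' @rdname resolve_alpha_min
#' @export
derive_params <- resolve_alpha_min
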