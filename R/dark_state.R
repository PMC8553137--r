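#' Component currents and cyclase rate
#'
#' Whole-cell Hill/Michaelis-Menten current models. Currents are totals in
#' pA, so channel localization drops out of the well-stirred steady state.
#'
#' @param cG cGMP concentration (uM, >= 0); may be a vector.
#' @param Ca Calcium concentration (uM, >= 0); may be a vector.
#' @param p A [cone_params()] object.
#' @return Current in pA ([cng_current()], [exchanger_current()]) or a
#'   synthesis rate in uM/s ([cyclase_rate()]).
#' @examples
#' p <- cone_params()
#' cng_current(p$K_cG, p)  # half of JcG_max
#' @export
cng_current <- function(cG, p) {
  if (any(cG < 0)) stop("cng_current: cG must be nonnegative")
  x <- (cG / p$K_cG)^p$m_cG
  p$JcG_max * x / (1 + x)
}

#' @rdname cng_current
#' @export
exchanger_current <- function(Ca, p) {
  if (any(Ca < 0)) stop("exchanger_current: Ca must be nonnegative")
  p$Jex_sat * Ca / (p$K_ex + Ca)
}

#' @rdname cng_current
#' @param derived Optional precomputed [resolve_alpha_min()] result.
#' @export
cyclase_rate <- function(Ca, p, derived = resolve_alpha_min(p)) {
  if (any(Ca < 0)) stop("cyclase_rate: Ca must be nonnegative")
  K <- p$K_cyc * 1e-3  # nM -> uM
  derived$alpha_min +
    (p$alpha_max - derived$alpha_min) / (1 + (Ca / K)^p$m_cyc)
}

#' Existence of the dark-adapted steady state
#'
#' The dark steady state exists iff the current balance admits a solution:
#' `1 + (alpha_min / (beta_dark K_cG))^m_cG < (1 - 2 Jex_sat / (JcG_max
#' f_Ca))^-1`, with the right side requiring `2 Jex_sat < JcG_max f_Ca`.
#' Degenerate denominators return `FALSE` rather than erroring so that
#' sampling pipelines can count rejections.
#'
#' @param p A [cone_params()] object.
#' @return `TRUE` iff a dark steady state exists.
#' @export
check_existence <- function(p) {
  r <- 2 * p$Jex_sat / (p$JcG_max * p$f_Ca)
  if (!is.finite(r) || r >= 1) return(FALSE)
  alpha_min <- tryCatch(resolve_alpha_min(p)$alpha_min, error = function(e) NA)
  if (!is.finite(alpha_min)) return(FALSE)
  lhs <- 1 + (alpha_min / (p$beta_dark * p$K_cG))^p$m_cG
  lhs < 1 / (1 - r)
}

#' Solve the dark-adapted steady state
#'
#' Solves the 2x2 balance system: cGMP synthesis equals dark hydrolysis,
#' `cyclase_rate(Ca) = beta_dark * cG`, and calcium influx equals efflux,
#' `exchanger_current(Ca) = f_Ca/2 * cng_current(cG)`. The inner equation is
#' closed-form in `cG` given `Ca`; the outer residual is strictly increasing
#' in `Ca`, so a bracketed root search is guaranteed to converge.
#'
#' @param p A [cone_params()] object.
#' @param tol Relative tolerance for the outer root.
#' @return An object of class `dark_state`: list with `cG_dark`, `Ca_dark`
#'   (uM), component currents `J_cG_dark`, `J_ex_dark` and their sum `J_dark`
#'   (pA), `alpha_min`, `xi` (uM/s), `exists`, and `residuals` (synthesis
#'   minus hydrolysis in uM/s; flux imbalance in pA). When no steady state
#'   exists the state is returned flagged `exists = FALSE` rather than as an
#'   error, to support rejection accounting in samplers.
#' @examples
#' solve_dark_state(cone_params())$J_dark  # ~ 26 pA
#' @export
solve_dark_state <- function(p, tol = 1e-10) {
  stopifnot(inherits(p, "cone_params"))
  if (!check_existence(p)) {
    out <- list(cG_dark = NA_real_, Ca_dark = NA_real_, J_cG_dark = NA_real_,
                J_ex_dark = NA_real_, J_dark = NA_real_,
                alpha_min = NA_real_, xi = NA_real_, exists = FALSE,
                residuals = c(synthesis = NA_real_, flux = NA_real_))
    class(out) <- "dark_state"
    return(out)
  }
  d <- resolve_alpha_min(p)
  cG_of_Ca <- function(Ca) cyclase_rate(Ca, p, d) / p$beta_dark
  g <- function(Ca) exchanger_current(Ca, p) -
    0.5 * p$f_Ca * cng_current(cG_of_Ca(Ca), p)
  lo <- 1e-9
  hi <- 10
  while (g(hi) < 0 && hi < 1e6) hi <- hi * 10
  root <- stats::uniroot(g, c(lo, hi), tol = tol * hi)
  Ca <- root$root
  cG <- cG_of_Ca(Ca)
  JcG <- cng_current(cG, p)
  Jex <- exchanger_current(Ca, p)
  out <- list(
    cG_dark = cG, Ca_dark = Ca,
    J_cG_dark = JcG, J_ex_dark = Jex, J_dark = JcG + Jex,
    alpha_min = d$alpha_min, xi = d$xi, exists = TRUE,
    residuals = c(synthesis = cyclase_rate(Ca, p, d) - p$beta_dark * cG,
                  flux = 0.5 * p$f_Ca * JcG - Jex)
  )
  class(out) <- "dark_state"
  out
}

#' @export
print.dark_state <- function(x, ...) {
  if (!x$exists) {
    cat("<dark_state> no admissible dark steady state\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<dark_state> cG = %.4g uM, Ca = %.4g uM, ",
                     "J_dark = %.4g pA (CNG %.4g + exchanger %.4g)\n"),
              x$cG_dark, x$Ca_dark, x$J_dark, x$J_cG_dark, x$J_ex_dark))
  invisible(x)
}

#' Vectorized dark-current evaluation over a design matrix
#'
#' Solves the dark steady state for each row of a parameter draw matrix by
#' vectorized monotone bisection (same system as [solve_dark_state()],
#' bisected simultaneously across rows). Rows are interpreted with the
#' `a_min` parameterization when an `a_min` column is present; otherwise an
#' `alpha_min` column is required.
#'
#' @param X Numeric matrix or data frame; columns named after
#'   [cone_params()] fields (unreferenced fields fall back to `base`).
#' @param base Base parameter set for columns not in `X`.
#' @param iters Number of bisection iterations (each halves the bracket).
#' @return Data frame with columns `cG_dark`, `Ca_dark`, `J_cG_dark`,
#'   `J_ex_dark`, `J_dark`, `exists`.
#' @export
dark_state_batch <- function(X, base = cone_params(), iters = 80L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  pull <- function(nm) if (nm %in% names(X)) X[[nm]] else rep(base[[nm]], n)
  beta_dark <- pull("beta_dark"); K_cG <- pull("K_cG"); m_cG <- pull("m_cG")
  JcG_max <- pull("JcG_max"); Jex_sat <- pull("Jex_sat"); K_ex <- pull("K_ex")
  f_Ca <- pull("f_Ca"); alpha_max <- pull("alpha_max")
  m_cyc <- pull("m_cyc"); K_cyc_uM <- pull("K_cyc") * 1e-3
  r <- 2 * Jex_sat / (JcG_max * f_Ca)
  ok <- is.finite(r) & r < 1
  chi <- ifelse(ok & r > 0,
                beta_dark * K_cG * pmax(1 / (1 - r) - 1, 0)^(1 / m_cG), 0)
  xi <- pmin(alpha_max, chi)
  if ("a_min" %in% names(X)) {
    alpha_min <- X[["a_min"]] * xi
  } else if ("alpha_min" %in% names(X)) {
    alpha_min <- X[["alpha_min"]]
  } else if ("alpha_ratio" %in% names(X)) {
    alpha_min <- alpha_max / X[["alpha_ratio"]]
  } else {
    alpha_min <- rep(resolve_alpha_min(base)$alpha_min, n)
  }
  ok <- ok & alpha_min < xi & alpha_min >= 0
  g_of <- function(Ca) {
    cyc <- alpha_min + (alpha_max - alpha_min) / (1 + (Ca / K_cyc_uM)^m_cyc)
    cG <- cyc / beta_dark
    x <- (cG / K_cG)^m_cG
    Jex_sat * Ca / (K_ex + Ca) - 0.5 * f_Ca * JcG_max * x / (1 + x)
  }
  lo <- rep(0, n)
  hi <- rep(10, n)
  for (k in 1:30) {  # expand brackets where the root lies above hi
    bad <- ok & g_of(hi) < 0
    if (!any(bad)) break
    lo[bad] <- hi[bad]
    hi[bad] <- hi[bad] * 2
  }
  for (k in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    up <- g_of(mid) > 0
    hi[up] <- mid[up]
    lo[!up] <- mid[!up]
  }
  Ca <- 0.5 * (lo + hi)
  cyc <- alpha_min + (alpha_max - alpha_min) / (1 + (Ca / K_cyc_uM)^m_cyc)
  cG <- cyc / beta_dark
  x <- (cG / K_cG)^m_cG
  JcG <- JcG_max * x / (1 + x)
  Jex <- Jex_sat * Ca / (K_ex + Ca)
  res <- data.frame(cG_dark = cG, Ca_dark = Ca, J_cG_dark = JcG,
                    J_ex_dark = Jex, J_dark = JcG + Jex, exists = ok)
  res[!ok, c("cG_dark", "Ca_dark", "J_cG_dark", "J_ex_dark", "J_dark")] <- NA_real_
  res
}
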