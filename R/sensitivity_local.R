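#' Local (gradient-based) sensitivity index
#'
#' Normalized forward-difference sensitivity of a scalar functional `y` to a
#' relative perturbation of one parameter at a base point:
#' `Q = (y(x + dx) / y(x) - 1) / rel_step`, i.e. the relative change in the
#' functional per unit relative change in the parameter.
#'
#' @param evaluator Function taking a `cone_params` object and returning a
#'   scalar.
#' @param p Base [cone_params()] point.
#' @param name Parameter field to perturb.
#' @param rel_step Relative step (default 5%).
#' @param y0 Optional cached base evaluation `evaluator(p)`.
#' @return Unitless `Q`, or `NA_real_` when the base value is 0 (undefined).
#' @examples
#' local_Q(function(p) p$k_R^2, cone_params(), "k_R")  # (1.05^2 - 1)/0.05
#' @export
local_Q <- function(evaluator, p, name, rel_step = 0.05,
                    y0 = evaluator(p)) {
  stopifnot(inherits(p, "cone_params"))
  if (!name %in% names(p)) stop("unknown parameter '", name, "'")
  if (!is.finite(y0) || y0 == 0) return(NA_real_)
  args <- stats::setNames(list(p[[name]] * (1 + rel_step)), name)
  p2 <- do.call(update_params, c(list(p), args))
  y1 <- evaluator(p2)
  if (!is.finite(y1)) return(NA_real_)
  (y1 / y0 - 1) / rel_step
}

#' Local sensitivity matrix over parameters and functionals
#'
#' Evaluates all nine flash-response functionals once at the base point and
#' once per 5%-perturbed parameter, with deterministic solver settings so
#' differences are not noise-dominated.
#'
#' @param p Base [cone_params()] point.
#' @param names Parameters to perturb (default: all kinetic, cGMP/calcium,
#'   channel and geometry parameters).
#' @param phi Flash strength (photoisomerizations).
#' @param target Optional target trace for the L2 functional.
#' @param rel_step Relative step.
#' @param t_end,dt Simulation window and output grid (s).
#' @return Matrix (parameters x functionals) of class `local_sensitivity`,
#'   with the step recorded as an attribute.
#' @export
local_sensitivity_matrix <- function(p, names = local_sens_params(),
                                     phi = 940, target = NULL,
                                     rel_step = 0.05,
                                     t_end = 0.5, dt = 1e-4) {
  eval_all <- function(pp) {
    tr <- simulate_response(pp, phi, t_end = t_end, dt = dt)
    unclass(compute_functionals(tr, target = target))
  }
  base <- eval_all(p)
  fn <- functional_names()
  Q <- matrix(NA_real_, length(names), length(fn),
              dimnames = list(names, fn))
  for (nm in names) {
    args <- stats::setNames(list(p[[nm]] * (1 + rel_step)), nm)
    p2 <- do.call(update_params, c(list(p), args))
    pert <- tryCatch(eval_all(p2), error = function(e) rep(NA_real_, length(fn)))
    ok <- is.finite(base) & base != 0 & is.finite(pert)
    Q[nm, ok] <- (pert[ok] / base[ok] - 1) / rel_step
    Q[nm, is.finite(base) & base == 0] <- NA_real_
  }
  attr(Q, "rel_step") <- rel_step
  attr(Q, "phi") <- phi
  class(Q) <- c("local_sensitivity", "matrix")
  Q
}

local_sens_params <- function() {
  c("R_b", "R_t", "H", "omega0", "eps0", "nu", "sigma",
    "k_GE", "nu_RG", "k_R", "k_E", "D_R", "D_G", "D_E", "D_cG", "D_Ca",
    "G_sigma", "PDE_sigma", "beta_dark", "B_cG", "kcat_Km",
    "alpha_max", "m_cyc", "K_cyc",
    "B_Ca", "JcG_max", "m_cG", "K_cG", "f_Ca", "Jex_sat", "K_ex")
}

#' Write a local sensitivity matrix as CSV
#' @param Q A `local_sensitivity` matrix.
#' @param file Output path.
#' @export
write_local_sensitivity <- function(Q, file) {
  df <- data.frame(parameter = rownames(Q), unclass(Q), check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
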