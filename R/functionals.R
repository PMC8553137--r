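#' Quadratic activation fit
#'
#' Least-squares amplitude `A` of the early-rise model `y = A t^2 / 2` over
#' a time window; closed form `A = 2 sum(y t^2) / sum(t^4)`.
#'
#' @param t,y Sample times (s) and values.
#' @param window Fitting window `c(lo, hi)` in s.
#' @return The curvature `A` (units of y per s^2).
#' @examples
#' t <- seq(0, 0.01, 1e-4)
#' fit_half_quadratic(t, 0.5 * 3 * t^2)  # 3
#' @export
fit_half_quadratic <- function(t, y, window = c(0, 0.010)) {
  sel <- t >= window[1] & t <= window[2] & is.finite(y)
  if (sum(sel) < 3) stop("fit_half_quadratic: fewer than 3 samples in window")
  tt <- t[sel]; yy <- y[sel]
  s4 <- sum(tt^4)
  if (s4 == 0) return(0)
  2 * sum(yy * tt^2) / s4
}

#' Exponential recovery fit
#'
#' Fits `c * exp(-alpha t)` to the positive samples in a late-time window by
#' log-linear regression and returns the decay rate `alpha = -slope`.
#' Nonpositive samples are dropped; if fewer than 3 positive samples remain
#' the functional is undefined and `NA` is returned (so that sampling
#' pipelines can exclude it from the affected statistic).
#'
#' @param t,y Sample times (s) and values.
#' @param window Fitting window `c(lo, hi)` in s.
#' @return Decay rate alpha (s^-1), or `NA_real_` if undefined.
#' @examples
#' t <- seq(0.135, 0.5, 1e-3)
#' fit_exp_recovery(t, 2 * exp(-5 * t))  # 5
#' @export
fit_exp_recovery <- function(t, y, window = c(0.135, 0.5)) {
  sel <- t >= window[1] & t <= window[2] & is.finite(y) & y > 0
  if (sum(sel) < 3) return(NA_real_)
  tt <- t[sel]; ly <- log(y[sel])
  -unname(stats::coef(stats::lm.fit(cbind(1, tt), ly))[2])
}

#- grid argmax with 3-point parabolic refinement
refine_max <- function(t, y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) return(list(t = t[i], y = y[i]))
  dt <- t[i + 1] - t[i]
  den <- y[i - 1] - 2 * y[i] + y[i + 1]
  if (den >= 0) return(list(t = t[i], y = y[i]))
  s <- 0.5 * (y[i - 1] - y[i + 1]) / den
  s <- max(min(s, 0.5), -0.5)
  list(t = t[i] + s * dt, y = y[i] - 0.25 * s * (y[i - 1] - y[i + 1]))
}

#' Scalar functionals of one flash response
#'
#' Computes the nine descriptors used for sensitivity analysis:
#' \describe{
#'   \item{I_act}{curvature of the early current drop, `drop ~ I_act t^2/2`
#'     on \[0, 10 ms\] (pA/s^2).}
#'   \item{E_act}{same quadratic fit applied to total E* (molecules/s^2).}
#'   \item{I_drop}{maximum current drop as a fraction of the dark current.}
#'   \item{E_peak}{maximum total E* (molecules).}
#'   \item{E_rec}{exponential decay rate of the current drop on
#'     \[0.135 s, 0.5 s\] (s^-1); `NA` when the drop is nonpositive there.}
#'   \item{T_peak}{time of maximum current drop (s), parabolically refined.}
#'   \item{J_dark}{circulating dark current (pA).}
#'   \item{J_over}{largest excess of the current above the dark current
#'     (overshoot), as a fraction of the dark current.}
#'   \item{L2}{rms difference between the model drop and a target drop at
#'     the target's sample times (pA); `NA` without a target.}
#' }
#'
#' @param trace A [simulate_response()] trace (must carry `J_dark`).
#' @param target Optional target: list/data frame with `t` and `drop`.
#' @param act_window,rec_window Fitting windows (s).
#' @return Named numeric vector of class `functional_vector`.
#' @export
compute_functionals <- function(trace, target = NULL,
                                act_window = c(0, 0.010),
                                rec_window = c(0.135, 0.5)) {
  J_dark <- attr(trace, "J_dark")
  if (is.null(J_dark)) stop("compute_functionals: trace lacks a J_dark attribute")
  t <- trace$t
  drop <- trace$drop
  pk <- refine_max(t, drop)
  L2 <- NA_real_
  if (!is.null(target)) {
    md <- stats::approx(t, drop, xout = target$t, rule = 2)$y
    L2 <- sqrt(mean((md - target$drop)^2))
  }
  out <- c(
    I_act = fit_half_quadratic(t, drop, act_window),
    E_act = fit_half_quadratic(t, trace$Estar_total, act_window),
    I_drop = max(drop) / J_dark,
    E_peak = refine_max(t, trace$Estar_total)$y,
    E_rec = fit_exp_recovery(t, drop, rec_window),
    T_peak = pk$t,
    J_dark = J_dark,
    J_over = max(0, max(-drop)) / J_dark,
    L2 = L2
  )
  class(out) <- c("functional_vector", "numeric")
  out
}

#' @export
print.functional_vector <- function(x, ...) {
  y <- unclass(x)
  cat("<functional_vector>\n")
  print(signif(y, 4))
  invisible(x)
}

#' Names of the functionals, in canonical order
#' @return Character vector.
#' @export
functional_names <- function() {
  c("I_act", "E_act", "I_drop", "E_peak", "E_rec", "T_peak",
    "J_dark", "J_over", "L2")
}

#' Write a functional vector as one-row CSV or JSON
#' @param fv A `functional_vector`.
#' @param file Path ending in `.csv` or `.json`.
#' @export
write_functionals <- function(fv, file) {
  v <- as.list(unclass(fv))
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    jsonlite::write_json(v, file, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(v), file, row.names = FALSE)
  }
  invisible(file)
}
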