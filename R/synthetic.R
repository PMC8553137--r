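#' Generate a synthetic family of flash responses
#'
#' Stand-in for recorded cone flash-response families (transducin-knockout
#' mouse cones, flashes of roughly 40 to 6,000 photoisomerizations with a
#' half-maximal response near 940): simulates the model at a known
#' parameter vector and adds iid Gaussian current noise. Used as the fitting
#' target for parameter-recovery experiments where the truth is known.
#'
#' @param theta_true A [cone_params()] object (must admit a dark state).
#' @param intensities Flash strengths in photoisomerizations, sorted
#'   ascending.
#' @param t_end,dt Time window and sampling interval (s).
#' @param noise_sd Additive Gaussian noise on the current (pA).
#' @param seed Integer seed for the noise.
#' @return An `experiment_trace` data frame: column `t` plus one
#'   `drop_<phi>` column per intensity. Attributes: `intensities`,
#'   `noise_sd`, `seed`, `theta_true`, `J_dark`, and `clean` (the noise-free
#'   drops).
#' @examples
#' tg <- generate_experiment(cone_params(), intensities = 940,
#'                           t_end = 0.05, noise_sd = 0)
#' max(tg$drop_940)
#' @export
generate_experiment <- function(theta_true = cone_params(),
                                intensities = c(40, 235, 940, 6000),
                                t_end = 0.5, dt = 1e-3,
                                noise_sd = 0.3, seed = 1) {
  stopifnot(inherits(theta_true, "cone_params"), noise_sd >= 0)
  intensities <- sort(intensities)
  dark <- solve_dark_state(theta_true)
  if (!dark$exists)
    stop("generate_experiment: theta_true admits no dark steady state")
  set.seed(seed)
  times <- seq(0, t_end, by = dt)
  out <- data.frame(t = times)
  clean <- data.frame(t = times)
  for (phi in intensities) {
    tr <- simulate_response(theta_true, phi, t_end = t_end, dt = dt,
                            dark = dark)
    nm <- paste0("drop_", format(phi, scientific = FALSE, trim = TRUE))
    clean[[nm]] <- tr$drop
    out[[nm]] <- tr$drop + stats::rnorm(length(times), sd = noise_sd)
  }
  attr(out, "intensities") <- intensities
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  attr(out, "theta_true") <- theta_true
  attr(out, "J_dark") <- dark$J_dark
  attr(out, "clean") <- clean
  class(out) <- c("experiment_trace", "data.frame")
  out
}

#' Write an experiment trace with a metadata sidecar
#'
#' The trace goes to `file` as CSV; generation metadata (intensities, noise
#' sd, seed, parameter hash) to `<file>.json`.
#'
#' @param trace An `experiment_trace`.
#' @param file Output CSV path.
#' @export
write_experiment <- function(trace, file) {
  utils::write.csv(unclass_df(trace), file, row.names = FALSE)
  theta <- attr(trace, "theta_true")
  num <- theta[vapply(theta, is.numeric, logical(1))]
  meta <- list(intensities = attr(trace, "intensities"),
               noise_sd = attr(trace, "noise_sd"),
               seed = attr(trace, "seed"),
               theta_hash = digest_vector(unlist(num)))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#- tiny stable content hash (sum of scaled bits); avoids extra dependencies
digest_vector <- function(x) {
  s <- paste(format(x, digits = 15), collapse = ",")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 0xFFFFFFFF)
}

#' Analytic test functions for Sobol estimator validation
#'
#' Bundles small test problems with known variance decompositions for
#' confidence-level testing of the Sobol estimators:
#' \describe{
#'   \item{additive}{`f = 3 x1 + x2` on independent uniforms; exact
#'     `S_i = S_tot_i = 9 w1 / (9 w1 + w2)` etc., with `w_i` the input
#'     variances.}
#'   \item{ishigami}{`f = sin x1 + a sin^2 x2 + b x3^4 sin x1` on
#'     \[-pi, pi\]^3 with `a = 7`, `b = 0.1`; closed-form indices from the
#'     standard variance decomposition.}
#'   \item{constant}{`f = 1`; estimators must refuse (zero variance).}
#' }
#'
#' @param which One of `"additive"`, `"ishigami"`, `"constant"`.
#' @return List with `f` (batch evaluator over a data frame), `ranges` (a
#'   `param_ranges`-shaped table reusing model parameter names as
#'   coordinates), and `exact` (named list of exact indices, where defined).
#' @export
make_gsa_smoke_fixture <- function(which = c("additive", "ishigami", "constant")) {
  which <- match.arg(which)
  rng <- function(names, lo, hi) {
    validate_param_ranges(data.frame(
      name = names, lo = lo, hi = hi, units = "",
      constraint_class = "gsa", species = ""))
  }
  if (which == "additive") {
    # x1 ~ U(0,1), x2 ~ U(0,2): w1 = 1/12, w2 = 4/12
    w1 <- 1 / 12; w2 <- 4 / 12
    list(
      f = function(X) 3 * X[[1]] + X[[2]],
      ranges = rng(c("k_R", "k_E"), c(0, 0), c(1, 2)),
      exact = list(S1 = 9 * w1 / (9 * w1 + w2), S2 = w2 / (9 * w1 + w2),
                   S_tot1 = 9 * w1 / (9 * w1 + w2))
    )
  } else if (which == "ishigami") {
    a <- 7; b <- 0.1
    V1 <- 0.5 * (1 + b * pi^4 / 5)^2
    V2 <- a^2 / 8
    V13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
    V <- V1 + V2 + V13
    list(
      f = function(X) sin(X[[1]]) + a * sin(X[[2]])^2 +
        b * X[[3]]^4 * sin(X[[1]]),
      ranges = rng(c("k_R", "k_E", "k_GE"), rep(-pi, 3), rep(pi, 3)),
      exact = list(S1 = V1 / V, S2 = V2 / V, S3 = 0,
                   S_tot1 = (V1 + V13) / V, S_tot2 = V2 / V,
                   S_tot3 = V13 / V)
    )
  } else {
    list(f = function(X) rep(1, nrow(X)),
         ranges = rng(c("k_R", "k_E"), c(0, 0), c(1, 1)),
         exact = list())
  }
}
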