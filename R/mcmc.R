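#' Configuration for Metropolis-Hastings parameter fitting
#'
#' @param gamma Penalty weight: stepping one interval-width outside a soft
#'   range multiplies the stationary density by `2^-gamma`.
#' @param beta Error exponent: the stationary density is proportional to
#'   `rms^-beta`, so larger `beta` concentrates the chain on low-error
#'   regions.
#' @param proposal_scale Componentwise Gaussian proposal standard deviation,
#'   as a fraction of each parameter's soft-range width.
#' @param n_steps Chain length.
#' @param seed Integer seed.
#' @param phi_fit Flash strength of the fitted trace (photoisomerizations).
#' @param max_start_attempts Rejection-sampling budget for finding a
#'   feasible start inside the hard constraint set.
#' @return A `mcmc_config` list.
#' @export
mcmc_config <- function(gamma = 5, beta = 2, proposal_scale = 0.02,
                        n_steps = 5000, seed = 1, phi_fit = 940,
                        max_start_attempts = 200000) {
  stopifnot(gamma > 0, beta > 0, all(proposal_scale > 0), n_steps >= 1)
  out <- list(gamma = gamma, beta = beta, proposal_scale = proposal_scale,
              n_steps = as.integer(n_steps), seed = seed, phi_fit = phi_fit,
              max_start_attempts = max_start_attempts)
  class(out) <- "mcmc_config"
  out
}

#' Root-mean-square error against a target flash response
#'
#' Simulates the flash response at the target's flash strength and sample
#' times and returns the rms difference of the current drops. A parameter
#' set without a dark steady state returns `Inf` (zero stationary density).
#'
#' @param p A [cone_params()] object.
#' @param target An [generate_experiment()] trace or any list with `t` and a
#'   drop column; see `drop_col`.
#' @param phi Flash strength; defaults to 940.
#' @param drop_col Name of the target drop column (default picks the column
#'   matching `phi` for experiment traces, or `"drop"`).
#' @return rms error in pA.
#' @export
rms_error <- function(p, target, phi = 940, drop_col = NULL) {
  dark <- tryCatch(solve_dark_state(p), error = function(e) NULL)
  if (is.null(dark) || !dark$exists) return(Inf)
  td <- target_drop(target, phi, drop_col)
  tr <- tryCatch(
    simulate_response(p, phi, t_end = max(td$t),
                      dt = stats::median(diff(td$t)), dark = dark),
    error = function(e) NULL)
  if (is.null(tr)) return(Inf)
  md <- stats::approx(tr$t, tr$drop, xout = td$t, rule = 2)$y
  sqrt(mean((md - td$drop)^2))
}

target_drop <- function(target, phi, drop_col = NULL) {
  if (is.null(drop_col)) {
    drop_col <- if ("drop" %in% names(target)) "drop" else paste0("drop_", phi)
  }
  if (!drop_col %in% names(target))
    stop("target has no column '", drop_col, "'")
  list(t = target$t, drop = target[[drop_col]])
}

#- distance to an interval, normalized by its width (0 inside)
interval_dist <- function(x, lo, hi) {
  w <- hi - lo
  out <- pmax(lo - x, 0, x - hi) / ifelse(w > 0, w, 1)
  out
}

#' Hard-constraint membership
#'
#' Checks a parameter set against the strict constraint table: bounds on
#' parameter fields (including the cyclase ratio `alpha_max/alpha_min`) and
#' on the derived dark-state quantities `cG_dark`, `Ca_dark`, `J_dark`.
#'
#' @param p A [cone_params()] object.
#' @param hard A `param_ranges` table of class `hard`.
#' @param dark Optional precomputed dark state.
#' @return `TRUE` iff all constraints hold (and the dark state exists).
#' @export
satisfies_hard <- function(p, hard = param_ranges("hard"),
                           dark = solve_dark_state(p)) {
  d <- tryCatch(resolve_alpha_min(p), error = function(e) NULL)
  if (is.null(d)) return(FALSE)
  vals <- unclass(p)
  vals$alpha_ratio <- if (d$alpha_min > 0) p$alpha_max / d$alpha_min else Inf
  if (!dark$exists) return(FALSE)
  vals$cG_dark <- dark$cG_dark
  vals$Ca_dark <- dark$Ca_dark
  vals$J_dark <- dark$J_dark
  for (i in seq_len(nrow(hard))) {
    v <- vals[[hard$name[i]]]
    if (is.null(v) || !is.finite(v) || v < hard$lo[i] || v > hard$hi[i])
      return(FALSE)
  }
  TRUE
}

#' Log stationary density for the fitting chain
#'
#' `log pi(x) = -gamma log(2) sum_i dist(x_i, I_i) - beta log ||e(x)||` on
#' the hard constraint set, `-Inf` off it; `dist` is the distance to the
#' soft interval in units of its width.
#'
#' @param p A [cone_params()] object.
#' @param target Target trace (see [rms_error()]).
#' @param soft,hard Soft and hard `param_ranges` tables.
#' @param config An [mcmc_config()].
#' @return Extended-real log density, with the rms error attached as
#'   attribute `rms`.
#' @export
log_density <- function(p, target, soft = param_ranges("soft"),
                        hard = param_ranges("hard"), config = mcmc_config()) {
  dark <- tryCatch(solve_dark_state(p), error = function(e) NULL)
  if (is.null(dark) || !satisfies_hard(p, hard, dark)) {
    out <- -Inf
    attr(out, "rms") <- Inf
    return(out)
  }
  d <- resolve_alpha_min(p)
  vals <- unclass(p)
  vals$alpha_ratio <- if (d$alpha_min > 0) p$alpha_max / d$alpha_min else Inf
  pen <- 0
  for (i in seq_len(nrow(soft))) {
    v <- vals[[soft$name[i]]]
    if (!is.null(v) && is.finite(v))
      pen <- pen + interval_dist(v, soft$lo[i], soft$hi[i])
  }
  e <- rms_error(p, target, phi = config$phi_fit)
  if (!is.finite(e)) {
    out <- -Inf
    attr(out, "rms") <- Inf
    return(out)
  }
  out <- -config$gamma * log(2) * pen - config$beta * log(max(e, 1e-12))
  attr(out, "rms") <- e
  out
}

#- componentwise (random-scan) Gaussian random-walk MH kernel on numeric
#- vectors: each step perturbs one uniformly chosen coordinate; logf returns
#- an extended-real log density
mh_kernel <- function(logf, x0, scales, n_steps) {
  d <- length(x0)
  X <- matrix(NA_real_, n_steps, d)
  acc <- logical(n_steps)
  lp <- logf(x0)
  if (!is.finite(lp)) stop("mh_kernel: start point has zero density")
  extras <- vector("list", n_steps)
  x <- x0
  for (s in seq_len(n_steps)) {
    i <- sample.int(d, 1L)
    prop <- x
    prop[i] <- prop[i] + stats::rnorm(1L, sd = scales[i])
    lp2 <- logf(prop)
    if (is.finite(lp2) && log(stats::runif(1)) < lp2 - lp) {
      x <- prop
      lp <- lp2
      acc[s] <- TRUE
    }
    X[s, ] <- x
    extras[[s]] <- attributes(lp)
  }
  list(samples = X, accepted = acc, extras = extras, last_lp = lp)
}

#' Rejection-sample a feasible start inside the hard constraint set
#'
#' Draws uniformly from the soft-range box until the induced parameter set
#' satisfies every hard constraint (including the derived dark-state
#' bounds). Draws are screened in vectorized blocks: the dark steady state
#' of each candidate block is solved by [dark_state_batch()] and the first
#' fully feasible row is verified again through the scalar path.
#'
#' @param soft,hard `param_ranges` tables.
#' @param base Base parameter set.
#' @param max_attempts Attempt budget.
#' @param block Candidates screened per vectorized block.
#' @return Named numeric vector of soft-range parameter values.
#' @export
find_feasible_start <- function(soft = param_ranges("soft"),
                                hard = param_ranges("hard"),
                                base = cone_params(),
                                max_attempts = 200000, block = 5000) {
  drawn <- 0
  while (drawn < max_attempts) {
    m <- min(block, max_attempts - drawn)
    drawn <- drawn + m
    X <- as.data.frame(lapply(seq_len(nrow(soft)), function(i)
      stats::runif(m, soft$lo[i], soft$hi[i])))
    names(X) <- soft$name
    ds <- dark_state_batch(X, base = base)
    ok <- ds$exists
    for (i in seq_len(nrow(hard))) {
      nm <- hard$name[i]
      v <- if (nm %in% names(X)) X[[nm]] else ds[[nm]]
      if (is.null(v)) v <- rep(base[[nm]], m)
      ok <- ok & is.finite(v) & v >= hard$lo[i] & v <= hard$hi[i]
    }
    for (j in which(ok)) {
      vals <- stats::setNames(as.numeric(X[j, ]), soft$name)
      p <- tryCatch(params_from_values(vals, base = base),
                    error = function(e) NULL)
      if (!is.null(p) && satisfies_hard(p, hard)) return(vals)
    }
  }
  stop("find_feasible_start: no feasible start in ", max_attempts,
       " attempts; supply `init` explicitly")
}

#' Run the Metropolis-Hastings fitting chain
#'
#' Componentwise Gaussian random walk in range-normalized coordinates over
#' the soft-range parameters (geometry and the calcium diffusion
#' coefficient stay fixed), with the stationary density of [log_density()].
#' The chain need not reach stationarity; the deliverable is the best-fit
#' (minimum-rms) sample.
#'
#' @param target Target trace (see [rms_error()]).
#' @param config An [mcmc_config()].
#' @param soft,hard `param_ranges` tables.
#' @param base Base parameter set for fields outside the walk.
#' @param init Optional named start vector over the soft-range parameters;
#'   found by rejection sampling when omitted.
#' @return An `mcmc_chain` list: `samples` (data frame, one row per step),
#'   `errors`, `accepted`, `best` (named vector), `best_rms`, `best_params`
#'   (a `cone_params` object), `config`.
#' @export
run_chain <- function(target, config = mcmc_config(),
                      soft = param_ranges("soft"),
                      hard = param_ranges("hard"),
                      base = cone_params(), init = NULL) {
  set.seed(config$seed)
  if (is.null(init))
    init <- find_feasible_start(soft, hard, base, config$max_start_attempts)
  init <- init[soft$name]
  if (any(is.na(init))) stop("init must cover every soft-range parameter")
  lo <- soft$lo; wd <- soft$hi - soft$lo
  to_params <- function(xn) {
    vals <- stats::setNames(lo + wd * xn, soft$name)
    tryCatch(params_from_values(vals, base = base), error = function(e) NULL)
  }
  logf <- function(xn) {
    p <- to_params(xn)
    if (is.null(p)) {
      out <- -Inf
      attr(out, "rms") <- Inf
      return(out)
    }
    log_density(p, target, soft, hard, config)
  }
  x0 <- (as.numeric(init) - lo) / wd
  scales <- rep_len(config$proposal_scale, length(x0))
  run <- mh_kernel(logf, x0, scales, config$n_steps)
  samples <- as.data.frame(sweep(sweep(run$samples, 2, wd, `*`), 2, lo, `+`))
  names(samples) <- soft$name
  errors <- vapply(run$extras, function(e) {
    if (is.null(e$rms)) NA_real_ else e$rms
  }, numeric(1))
  ibest <- which.min(errors)
  best <- stats::setNames(as.numeric(samples[ibest, ]), soft$name)
  out <- list(samples = samples, errors = errors, accepted = run$accepted,
              best = best, best_rms = errors[ibest],
              best_params = params_from_values(best, base = base),
              config = config)
  class(out) <- "mcmc_chain"
  out
}

#' @export
print.mcmc_chain <- function(x, ...) {
  cat(sprintf("<mcmc_chain> %d steps, acceptance %.1f%%, best rms %.4g pA\n",
              length(x$errors), 100 * mean(x$accepted), x$best_rms))
  invisible(x)
}

#' Write a fitting chain as CSV
#' @param chain An `mcmc_chain`.
#' @param file Output path.
#' @export
write_chain <- function(chain, file) {
  df <- cbind(chain$samples, rms = chain$errors, accepted = chain$accepted)
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
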