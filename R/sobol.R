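#' Saltelli sampling design for Sobol index estimation
#'
#' Draws two independent N x d matrices `A` and `B` of uniform samples over
#' the given ranges, plus, for every requested target (a single parameter or
#' a pair), the hybrid matrix `AB_y` equal to `A` with the target column(s)
#' replaced by `B`'s. The `a_min` coordinate (when present) is uniform on
#' \[0, 1\] and is resolved into a minimum cyclase rate per row at
#' evaluation time, which preserves independent sampling while guaranteeing
#' every row admits a dark steady state.
#'
#' @param ranges A `param_ranges` table (constraint class `gsa`); fixed rows
#'   are carried at their single value.
#' @param N Base sample count (>= 2).
#' @param seed Integer seed for the draws.
#' @param targets List of character vectors: length-1 for single indices,
#'   length-2 for closed pairwise indices.
#' @return A `sobol_design` list: `A`, `B` (data frames), `AB` (named list of
#'   data frames), `N`, `d`, `seed`, `targets`, `ranges`.
#' @examples
#' dsg <- sample_design(param_ranges("gsa"), N = 4, seed = 1,
#'                      targets = list("beta_dark"))
#' dim(dsg$A)
#' @export
sample_design <- function(ranges, N, seed, targets) {
  stopifnot(N >= 2)
  if (!is.list(targets)) targets <- as.list(targets)
  for (tg in targets) {
    if (!all(tg %in% ranges$name))
      stop("design target(s) missing from ranges: ",
           paste(setdiff(tg, ranges$name), collapse = ", "))
    if (!length(tg) %in% 1:2)
      stop("targets must be single parameters or pairs")
  }
  d <- nrow(ranges)
  draw <- function() {
    M <- matrix(stats::runif(N * d), N, d)
    M <- sweep(M, 2, ranges$hi - ranges$lo, `*`)
    M <- sweep(M, 2, ranges$lo, `+`)
    colnames(M) <- ranges$name
    as.data.frame(M)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  A <- draw()
  B <- draw()
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  AB <- lapply(targets, function(tg) {
    M <- A
    M[tg] <- B[tg]
    M
  })
  names(AB) <- vapply(targets, paste, "", collapse = ":")
  out <- list(A = A, B = B, AB = AB, N = as.integer(N), d = d,
              seed = seed, targets = targets, ranges = ranges)
  class(out) <- "sobol_design"
  out
}

#' Sobol index estimators on an evaluated Saltelli design
#'
#' First-order (or closed, for pairs) indices use the Saltelli (2010)
#' estimator `S_y = mean(f(B) * (f(AB_y) - f(A))) / V`; total-effect indices
#' use the Jansen estimator `S_tot_y = mean((f(A) - f(AB_y))^2) / (2 V)`,
#' with `V` the pooled sample variance of `c(f(A), f(B))`. Indices are
#' reported unclamped: small negative estimates are a legitimate feature of
#' the Monte Carlo approximation. Rows where `f(A)` or `f(B)` failed
#' (non-finite) are excluded everywhere; rows where `f(AB_y)` failed are
#' excluded from that target only, with counts reported.
#'
#' Confidence intervals: 95% normal intervals for the numerator and
#' denominator sample means are combined by the order-preserving properties
#' of division into a 90% interval for the ratio. A denominator interval
#' straddling zero yields an unbounded (infinite) interval.
#'
#' @param fA,fB Numeric vectors of model evaluations on `A` and `B`.
#' @param fAB Named list of evaluations on each `AB_y`.
#' @return A `sobol_result` data frame: one row per target with `S`,
#'   `S_tot`, `ci90_S_lo/hi`, `ci90_S_tot_lo/hi`, `N`, `n_failed`.
#' @export
estimate_indices <- function(fA, fB, fAB) {
  stopifnot(length(fA) == length(fB), is.list(fAB))
  keep <- is.finite(fA) & is.finite(fB)
  n_base_failed <- sum(!keep)
  pool <- c(fA[keep], fB[keep])
  V <- stats::var(pool)
  if (!is.finite(V) || V <= 0)
    stop("estimate_indices: constant functional, variance is zero")
  vterms <- (pool - mean(pool))^2
  res <- lapply(names(fAB), function(nm) {
    fab <- fAB[[nm]]
    ok <- keep & is.finite(fab)
    n <- sum(ok)
    u1 <- fB[ok] * (fab[ok] - fA[ok])          # Saltelli first-order terms
    u2 <- 0.5 * (fA[ok] - fab[ok])^2           # Jansen total terms
    ratio_ci(nm, u1, u2, vterms, V, n,
             n_failed = n_base_failed + sum(keep & !is.finite(fab)))
  })
  out <- do.call(rbind, res)
  class(out) <- c("sobol_result", "data.frame")
  out
}

#- 90% CI of a ratio of two MC means from 95% CIs of each
ratio_ci <- function(nm, u1, u2, vterms, V, n, n_failed) {
  z <- stats::qnorm(0.975)
  ci_mean <- function(x) {
    m <- mean(x)
    se <- stats::sd(x) / sqrt(length(x))
    c(m - z * se, m + z * se)
  }
  num1 <- ci_mean(u1); num2 <- ci_mean(u2)
  den <- mean(vterms) + z * c(-1, 1) * stats::sd(vterms) / sqrt(length(vterms))
  div_ci <- function(num, den) {
    if (den[1] <= 0) return(c(-Inf, Inf))
    range(c(num[1] / den[1], num[1] / den[2], num[2] / den[1], num[2] / den[2]))
  }
  c1 <- div_ci(num1, den)
  c2 <- div_ci(num2, den)
  data.frame(target = nm,
             S = mean(u1) / V, S_tot = mean(u2) / V,
             ci90_S_lo = c1[1], ci90_S_hi = c1[2],
             ci90_S_tot_lo = c2[1], ci90_S_tot_hi = c2[2],
             N = n, n_failed = n_failed)
}

#' Bootstrap confidence intervals for Sobol indices
#'
#' Percentile bootstrap over design rows, recomputing both estimators per
#' resample; a cross-check on the normal-approximation intervals of
#' [estimate_indices()].
#'
#' @inheritParams estimate_indices
#' @param target Name of one entry of `fAB`.
#' @param B_boot Number of resamples.
#' @param level Confidence level.
#' @param seed Seed for resampling.
#' @return List with `S` and `S_tot` length-2 interval vectors.
#' @export
bootstrap_ci <- function(fA, fB, fAB, target, B_boot = 1000, level = 0.90,
                         seed = 1) {
  fab <- fAB[[target]]
  ok <- is.finite(fA) & is.finite(fB) & is.finite(fab)
  fA <- fA[ok]; fB <- fB[ok]; fab <- fab[ok]
  n <- length(fA)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B_boot, replace = TRUE), n, B_boot)
  S <- numeric(B_boot); St <- numeric(B_boot)
  for (b in seq_len(B_boot)) {
    i <- idx[, b]
    V <- stats::var(c(fA[i], fB[i]))
    S[b] <- mean(fB[i] * (fab[i] - fA[i])) / V
    St[b] <- mean((fA[i] - fab[i])^2) / (2 * V)
  }
  a <- (1 - level) / 2
  list(S = unname(stats::quantile(S, c(a, 1 - a))),
       S_tot = unname(stats::quantile(St, c(a, 1 - a))))
}

#' One-call Sobol analysis of a batch evaluator
#'
#' Samples a Saltelli design, evaluates the model on `A`, `B` and every
#' `AB_y`, and returns index estimates.
#'
#' @param evaluator Function mapping a data frame of parameter draws (one
#'   row per sample) to a numeric vector of functional values; failures as
#'   `NA`.
#' @inheritParams sample_design
#' @return A `sobol_result` data frame (see [estimate_indices()]) with the
#'   design attached as attribute `design`.
#' @examples
#' rng <- validate_param_ranges(data.frame(
#'   name = c("k_R", "k_E"), lo = c(0, 0), hi = c(1, 1),
#'   units = "", constraint_class = "gsa"))
#' f <- function(X) 3 * X$k_R + X$k_E
#' sobol_indices(f, rng, N = 1000, seed = 1, targets = list("k_R"))
#' @export
sobol_indices <- function(evaluator, ranges, N, seed, targets) {
  dsg <- sample_design(ranges, N, seed, targets)
  fA <- evaluator(dsg$A)
  fB <- evaluator(dsg$B)
  fAB <- lapply(dsg$AB, evaluator)
  out <- estimate_indices(fA, fB, fAB)
  attr(out, "design") <- dsg[c("N", "d", "seed", "targets")]
  out
}

#' Write Sobol results as long-format CSV
#' @param res A `sobol_result` data frame.
#' @param file Output path.
#' @export
write_sobol <- function(res, file) {
  utils::write.csv(unclass_df(res), file, row.names = FALSE)
  invisible(file)
}
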