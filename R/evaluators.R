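#' Batch functional evaluators for sensitivity sampling
#'
#' Evaluators mapping a data frame of parameter draws (columns named after
#' [cone_params()] fields, an `a_min` column resolving the minimum cyclase
#' rate) to functional values, suitable for [sobol_indices()].
#'
#' `eval_J_dark` solves the dark steady state per row by vectorized
#' bisection; `eval_peak_Estar` integrates the activation cascade per row;
#' `eval_functionals` integrates the full photoresponse per row and returns
#' a matrix with one column per functional. Failed rows yield `NA`.
#'
#' @param X Data frame of parameter draws.
#' @param base Base parameter set supplying fields absent from `X`.
#' @param phi Flash strength (photoisomerizations).
#' @param t_end,dt Integration window and output grid (s).
#' @param target Optional target trace (for the L2 functional).
#' @return `eval_J_dark` and `eval_peak_Estar`: numeric vectors;
#'   `eval_functionals`: numeric matrix with [functional_names()] columns.
#' @export
eval_J_dark <- function(X, base = cone_params()) {
  dark_state_batch(X, base = base)$J_dark
}

#' @rdname eval_J_dark
#' @export
eval_peak_Estar <- function(X, base = cone_params(), phi = 940,
                            t_end = 0.5, dt = 5e-4) {
  X <- as.data.frame(X)
  vapply(seq_len(nrow(X)), function(i) {
    tryCatch({
      p <- params_from_values(unlist(X[i, , drop = FALSE]), base = base)
      peak_Estar(p, phi = phi, t_end = t_end, dt = dt)
    }, error = function(e) NA_real_)
  }, numeric(1))
}

#' @rdname eval_J_dark
#' @export
eval_functionals <- function(X, base = cone_params(), phi = 940,
                             t_end = 0.5, dt = 1e-3, target = NULL) {
  X <- as.data.frame(X)
  out <- matrix(NA_real_, nrow(X), length(functional_names()),
                dimnames = list(NULL, functional_names()))
  for (i in seq_len(nrow(X))) {
    fv <- tryCatch({
      p <- params_from_values(unlist(X[i, , drop = FALSE]), base = base)
      tr <- simulate_response(p, phi, t_end = t_end, dt = dt)
      unclass(compute_functionals(tr, target = target))
    }, error = function(e) NULL)
    if (!is.null(fv)) out[i, ] <- fv
  }
  out
}
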