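#' Read a run configuration from YAML or JSON
#'
#' @param file Path to `.yaml`/`.yml` (requires the yaml package) or
#'   `.json`.
#' @return Named list of configuration blocks.
#' @export
read_run_config <- function(file) {
  if (grepl("\\.ya?ml$", file, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the 'yaml' package")
    yaml::read_yaml(file)
  } else {
    jsonlite::read_json(file, simplifyVector = TRUE)
  }
}

write_manifest <- function(out_dir, stage, config) {
  meta <- list(
    stage = stage,
    package = "conesens",
    version = as.character(utils::packageVersion("conesens")),
    config = config
  )
  jsonlite::write_json(meta, file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the global sensitivity experiment
#'
#' Full Sobol pipeline at one flash strength: samples a Saltelli design over
#' the packaged uncertainty ranges, evaluates all nine functionals per draw
#' (full photoresponse integration; the L2 functional is measured against a
#' synthetic noise-free target generated from `base`), and writes per-
#' functional index estimates.
#'
#' Outputs in `out_dir`: `sobol_long.csv` (functional, target, S, S_tot,
#' CIs, N, n_failed), `sobol_S.csv` and `sobol_S_tot.csv` (wide parameter x
#' functional matrices), `ranked_<functional>.csv` (top-8 by |S_tot|), and a
#' manifest.
#'
#' @param out_dir Output directory (created if missing).
#' @param N Base sample count.
#' @param seed Integer seed.
#' @param phi Flash strength (photoisomerizations).
#' @param targets List of single names / pairs; default: every sampled
#'   parameter as a single target.
#' @param base Base parameter set.
#' @param t_end,dt Integration window and grid (s).
#' @return Invisibly, a named list of `sobol_result` tables (one per
#'   functional).
#' @export
reproduce_gsa <- function(out_dir, N = 256, seed = 1, phi = 940,
                          targets = NULL, base = cone_params(),
                          t_end = 0.5, dt = 1e-3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ranges <- param_ranges("gsa")
  if (is.null(targets)) targets <- as.list(ranges$name)
  target_trace <- generate_experiment(base, intensities = phi, t_end = t_end,
                                      dt = dt, noise_sd = 0, seed = seed)
  tgt <- list(t = target_trace$t,
              drop = target_trace[[paste0("drop_", phi)]])
  dsg <- sample_design(ranges, N, seed, targets)
  evalf <- function(X) eval_functionals(X, base = base, phi = phi,
                                        t_end = t_end, dt = dt, target = tgt)
  FA <- evalf(dsg$A)
  FB <- evalf(dsg$B)
  FAB <- lapply(dsg$AB, evalf)
  res <- list()
  for (fn in functional_names()) {
    res[[fn]] <- tryCatch(
      estimate_indices(FA[, fn], FB[, fn], lapply(FAB, function(M) M[, fn])),
      error = function(e) NULL)
  }
  long <- do.call(rbind, lapply(names(res), function(fn) {
    if (is.null(res[[fn]])) return(NULL)
    cbind(functional = fn, unclass_df(res[[fn]]))
  }))
  utils::write.csv(long, file.path(out_dir, "sobol_long.csv"), row.names = FALSE)
  singles <- vapply(targets, length, 1L) == 1L
  tnames <- vapply(targets[singles], identity, "")
  for (what in c("S", "S_tot")) {
    W <- sapply(res, function(r) {
      if (is.null(r)) return(rep(NA_real_, length(tnames)))
      r[[what]][match(tnames, r$target)]
    })
    rownames(W) <- tnames
    utils::write.csv(data.frame(parameter = tnames, W, check.names = FALSE),
                     file.path(out_dir, paste0("sobol_", what, ".csv")),
                     row.names = FALSE)
  }
  for (fn in names(res)) {
    r <- res[[fn]]
    if (is.null(r)) next
    r <- r[order(-abs(r$S_tot)), ]
    utils::write.csv(unclass_df(utils::head(r, 8)),
                     file.path(out_dir, paste0("ranked_", fn, ".csv")),
                     row.names = FALSE)
  }
  write_manifest(out_dir, "gsa",
                 list(N = N, seed = seed, phi = phi, t_end = t_end, dt = dt,
                      targets = vapply(targets, paste, "", collapse = ":")))
  invisible(res)
}

#' Run the parameter-fitting experiment
#'
#' Fits the model to a flash-response trace (by default a synthetic
#' 940-photoisomerization trace generated from `truth`) by the
#' Metropolis-Hastings random walk under the packaged hard and soft
#' constraints, and writes the chain, the best-fit parameter vector and a
#' manifest.
#'
#' @param out_dir Output directory.
#' @param target Optional `experiment_trace`; generated from `truth` when
#'   omitted.
#' @param config An [mcmc_config()].
#' @param truth Parameter set used to generate the default target.
#' @param noise_sd Noise for the default target (pA).
#' @param init Optional named start vector (see [run_chain()]).
#' @return Invisibly, the `mcmc_chain`.
#' @export
reproduce_fit <- function(out_dir, target = NULL, config = mcmc_config(),
                          truth = cone_params(), noise_sd = 0.3,
                          init = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(target)) {
    target <- generate_experiment(truth, intensities = config$phi_fit,
                                  noise_sd = noise_sd, seed = config$seed)
  }
  chain <- run_chain(target, config = config, init = init)
  write_chain(chain, file.path(out_dir, "chain.csv"))
  write_params(chain$best_params, file.path(out_dir, "best_fit.csv"))
  write_manifest(out_dir, "fit",
                 list(n_steps = config$n_steps, seed = config$seed,
                      gamma = config$gamma, beta = config$beta,
                      proposal_scale = config$proposal_scale,
                      phi_fit = config$phi_fit, noise_sd = noise_sd,
                      best_rms = chain$best_rms))
  invisible(chain)
}
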