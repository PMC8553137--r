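# Shared fixtures: the best-fit parameter point, cached range tables, and a
# fast flash-response helper (coarser grid than the analysis default).

best_fit <- cone_params()
gsa_ranges <- param_ranges("gsa")
soft_ranges <- param_ranges("soft")
hard_ranges <- param_ranges("hard")

quick_response <- function(p = best_fit, phi = 940, t_end = 0.5, dt = 1e-3) {
  simulate_response(p, phi, t_end = t_end, dt = dt)
}

# uniform draws over a range table, as a data frame
draw_ranges <- function(ranges, n, seed) {
  set.seed(seed)
  X <- as.data.frame(lapply(seq_len(nrow(ranges)), function(i)
    runif(n, ranges$lo[i], ranges$hi[i])))
  names(X) <- ranges$name
  X
}

# build a cone_params from one row of such a draw
row_params <- function(X, i, base = best_fit) {
  params_from_values(unlist(X[i, , drop = FALSE]), base = base)
}
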