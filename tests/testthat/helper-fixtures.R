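# Shared fixtures: small parameter sets and rate systems reused across
# test files. Grids are kept coarse so the whole suite stays fast; grid
# convergence is checked explicitly in test-solver.R.

fix_params <- function(q = 3, ...) {
  p <- default_params(q)
  tweaks <- list(...)
  for (nm in names(tweaks)) p[[nm]] <- tweaks[[nm]]
  as_xb_params(unclass(p))
}

# memoized coarse rate systems
.fix_cache <- new.env(parent = emptyenv())

fix_rs <- function(q = 3, n_points = 16) {
  key <- paste0("q", q, "n", n_points)
  if (is.null(.fix_cache[[key]])) {
    .fix_cache[[key]] <- build_rate_system(fix_params(q), n_points)
  }
  .fix_cache[[key]]
}

# parameters with zero tropomyosin coupling (non-cooperative limit)
fix_params_nocoop <- function(q = 1) {
  fix_params(q, U_TW = 0, U_WS = 0)
}
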