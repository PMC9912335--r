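# Shared small fixtures and oracle helpers.

# small geometry for fast solver tests (same physics, reduced domain)
small_geometry <- function() {
  pore_geometry(pore_radius = 10, membrane = 20, lipid = 5,
                reservoir_radius = 50, reservoir_height = 40)
}

small_mesh <- function(orientation = NULL, ...) {
  org <- if (is.null(orientation)) NULL else
    origami_model(radius = 14, orientation = orientation)
  build_domain(small_geometry(), org, min_cell = 1, max_cell = 6, ...)
}

fast_opts <- function(relax = 0.9, max_iter = 150, ...)
  solver_options(relax = relax, max_iter = max_iter, ...)

# noise-free rectangular-dip trace for detector tests
square_dip_trace <- function(baseline = 1000, depth = 200, fs = 10e3,
                             dips = list(c(0.2, 0.05), c(0.5, 0.02),
                                         c(0.8, 0.1)), duration = 1.2) {
  n <- round(duration * fs)
  x <- rep(baseline, n)
  for (d in dips) {
    i0 <- round(d[1] * fs) + 1
    i1 <- i0 + round(d[2] * fs) - 1
    x[i0:i1] <- baseline - depth
  }
  list(x = x, fs = fs, n = n)
}
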