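# Main coupled driver and post-processing of field solutions.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Solve the coupled Poisson-Nernst-Planck-Stokes-Brinkman problem
#'
#' Self-consistent electric potential, ion concentrations, velocity, and
#' pressure on an axisymmetric mesh, under an applied bias between the
#' reservoir boundaries (trans/bottom at +V/2, cis/top at -V/2) and an
#' optional imposed pressure difference. The electric body force acts on the
#' mobile space charge; the fixed origami charge enters the Poisson equation
#' and transmits momentum to the fluid through the screening cloud and the
#' Brinkman drag.
#'
#' @param mesh An `axi_mesh` from [build_domain()].
#' @param electrolyte An `electrolyte_spec`.
#' @param voltage Applied bias (V); |V| <= 1 V.
#' @param opts A `solver_options`.
#' @param pressure_drop Imposed pressure at the bottom boundary relative to
#'   the top (Pa), for purely hydrodynamic runs.
#' @param sigma_wall Surface charge density on membrane/lipid walls (C/m^2),
#'   default 0 (lipid passivation).
#' @return Object of class `field_solution`: potential `psi` (V), per-species
#'   concentrations `conc` (mol/m^3), face velocities `vr`, `vz` (m/s),
#'   pressure `p` (Pa), `converged`, `iterations`, `residual_history`, plus
#'   the mesh/electrolyte/voltage inputs. Non-convergence is flagged (with a
#'   warning), never silent.
#' @export
solve_coupled <- function(mesh, electrolyte, voltage, opts = solver_options(),
                          pressure_drop = 0, sigma_wall = 0) {
  stopifnot(inherits(mesh, "axi_mesh"), inherits(electrolyte, "electrolyte_spec"),
            inherits(opts, "solver_options"))
  if (abs(voltage) > 1)
    stop("solve_coupled: |V| must be <= 1 V (model validity range)")
  el <- electrolyte
  gr <- solver_grid(mesh)
  nr <- gr$nr; nz <- gr$nz
  nsp <- length(el$valence)
  RT <- gas_constant() * el$temperature

  # initial state: bulk concentrations, linear potential, no flow
  conc <- lapply(seq_len(nsp), function(s) {
    m <- matrix(0, nr, nz); m[gr$fluid] <- el$conc[s]; m
  })
  psi <- matrix(0, nr, nz)
  psi[gr$fluid] <- (voltage / 2) * (1 - 2 * (matrix(gr$zc, nr, nz, byrow = TRUE) -
                                               gr$zf[1]) /
                                      (gr$zf[nz + 1] - gr$zf[1]))[gr$fluid]
  vr <- matrix(0, nr + 1, nz); vz <- matrix(0, nr, nz + 1)
  p <- matrix(0, nr, nz)

  st <- stokes_setup(gr, mesh, el$eta, pressure_drop)

  w <- opts$relax
  hist <- numeric(0)
  converged <- FALSE
  vref <- max(abs(voltage), RT / .const$F)

  for (it in seq_len(opts$max_iter)) {
    rho_mob <- Reduce(`+`, Map(function(cm, z) z * .const$F * cm,
                               conc, as.list(el$valence)))
    Sdamp <- (.const$F^2 / RT) *
      Reduce(`+`, Map(function(cm, z) z^2 * cm, conc, as.list(el$valence)))

    psi_new <- poisson_step(gr, mesh, el, psi, rho_mob, Sdamp, voltage,
                            sigma_wall)
    d_psi <- max(abs(psi_new - psi)) / vref
    psi <- psi + w * (psi_new - psi)
    attr(psi, "voltage") <- voltage

    d_c <- 0
    for (s in seq_len(nsp)) {
      cn <- np_step(gr, mesh, el, s, psi, vr, vz)
      d_c <- max(d_c, max(abs(cn - conc[[s]])) / el$conc[s])
      conc[[s]] <- conc[[s]] + w * (cn - conc[[s]])
    }

    rho_mob <- Reduce(`+`, Map(function(cm, z) z * .const$F * cm,
                               conc, as.list(el$valence)))
    fl <- stokes_solve(st, gr, mesh, rho_mob, psi)
    # velocity scale floored at 1 um/s: flows below that are physically nil
    vsc <- max(max(abs(fl$vz)), max(abs(fl$vr)), 1e-6)
    d_v <- max(max(abs(fl$vz - vz)), max(abs(fl$vr - vr))) / vsc
    vr <- vr + w * (fl$vr - vr)
    vz <- vz + w * (fl$vz - vz)
    p <- p + w * (fl$p - p)

    res <- max(d_psi, d_c, d_v)
    hist <- c(hist, res)
    if (opts$verbose)
      message(sprintf("iter %3d: dpsi %.2e dc %.2e dv %.2e", it, d_psi, d_c, d_v))
    if (res < opts$tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("solve_coupled: not converged after %d iterations (residual %.3g)",
                    opts$max_iter, hist[length(hist)]))

  structure(list(mesh = mesh, electrolyte = el, voltage = voltage,
                 pressure_drop = pressure_drop, sigma_wall = sigma_wall,
                 psi = unclass(psi), conc = conc, vr = vr, vz = vz, p = p,
                 converged = converged, iterations = length(hist),
                 residual_history = hist),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("field_solution: V = %g mV, %s after %d iterations\n",
              x$voltage * 1e3,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

# index of the z-face row nearest a z position (nm), interior only
zface_index <- function(mesh, z_plane) {
  if (z_plane < mesh$zf[2] || z_plane > mesh$zf[mesh$nz])
    stop("plane outside the interior of the domain")
  which.min(abs(mesh$zf - z_plane))
}

#' Ionic current through a z-plane
#'
#' I = 2 pi int sum_i z_i F (flux_i)_z r dr across the plane, evaluated with
#' the solver's own exponentially fitted fluxes, so the value is
#' plane-independent (charge conservation) up to the nonlinear tolerance.
#'
#' @param sol A converged `field_solution`.
#' @param z_plane Axial position (nm); the nearest interior face row is used.
#'   Default: pore midplane.
#' @return Current (A), positive upward (trans to cis).
#' @export
ionic_current <- function(sol, z_plane = NULL) {
  stopifnot(inherits(sol, "field_solution"))
  mesh <- sol$mesh
  z_plane <- z_plane %||% (mesh$z_mem_bottom + mesh$geometry$slab / 2)
  jf <- zface_index(mesh, z_plane)
  gr <- solver_grid(mesh)
  el <- sol$electrolyte
  psi <- sol$psi; attr(psi, "voltage") <- sol$voltage
  itot <- 0
  for (s in seq_along(el$valence)) {
    fx <- np_zflux(gr, mesh, el, s, psi, sol$conc[[s]], sol$vz)
    itot <- itot + el$valence[s] * .const$F * sum(fx[, jf])
  }
  # positive current = conventional current flowing upward
  itot
}

#' Volumetric flow rate through a z-plane
#'
#' Q = 2 pi int v_z r dr. Incompressibility is enforced per cell, so Q is
#' plane-independent to machine precision in any connected flow region.
#'
#' @param sol A `field_solution`.
#' @param z_plane Axial position (nm); default pore midplane.
#' @return Flow rate (m^3/s), positive upward.
#' @export
flow_rate <- function(sol, z_plane = NULL) {
  stopifnot(inherits(sol, "field_solution"))
  mesh <- sol$mesh
  z_plane <- z_plane %||% (mesh$z_mem_bottom + mesh$geometry$slab / 2)
  jf <- zface_index(mesh, z_plane)
  Az <- pi * ((mesh$rf[-1] * 1e-9)^2 - (mesh$rf[-(mesh$nr + 1)] * 1e-9)^2)
  sum(Az * sol$vz[, jf])
}

#' Axial water velocity along the pore axis
#'
#' v_z sampled on the axis (first radial cell), with distance measured from
#' the bottom of the origami sphere pointing downward (into the pore and the
#' trans reservoir).
#'
#' @param sol A `field_solution`.
#' @return data.frame with `distance_nm`, `z_nm`, and `vz_ms`.
#' @export
axial_velocity_profile <- function(sol) {
  stopifnot(inherits(sol, "field_solution"))
  mesh <- sol$mesh
  z0 <- if (!is.na(mesh$sphere_bottom)) mesh$sphere_bottom else mesh$z_mem_top
  data.frame(distance_nm = z0 - mesh$zf, z_nm = mesh$zf,
             vz_ms = c(sol$vz[1, ]))
}

#' Export a field solution to CSV
#'
#' Tabular (r, z, psi, c_i, vr, vz, p) export, velocities averaged to cell
#' centers.
#'
#' @param sol A `field_solution`.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_field <- function(sol, path) {
  mesh <- sol$mesh
  nr <- mesh$nr; nz <- mesh$nz
  vrc <- (sol$vr[-1, , drop = FALSE] + sol$vr[-(nr + 1), , drop = FALSE]) / 2
  vzc <- (sol$vz[, -1, drop = FALSE] + sol$vz[, -(nz + 1), drop = FALSE]) / 2
  d <- data.frame(r_nm = rep(mesh$rc, nz), z_nm = rep(mesh$zc, each = nr),
                  psi_V = as.vector(sol$psi),
                  vr_ms = as.vector(vrc), vz_ms = as.vector(vzc),
                  p_Pa = as.vector(sol$p))
  for (s in seq_along(sol$conc))
    d[[paste0("c", s, "_mM")]] <- as.vector(sol$conc[[s]])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Field summary report
#'
#' Current, flow rate, conductance, and blockade-relevant quantities of a
#' run, as a plain list suitable for JSON export.
#'
#' @param sol A `field_solution`.
#' @return List with `voltage_V`, `current_A`, `flow_rate_m3s`,
#'   `conductance_S`, `converged`, `iterations`.
#' @export
field_summary <- function(sol) {
  i <- ionic_current(sol)
  list(voltage_V = sol$voltage, current_A = i,
       flow_rate_m3s = flow_rate(sol),
       conductance_S = if (sol$voltage != 0) i / sol$voltage else NA_real_,
       converged = sol$converged, iterations = sol$iterations)
}
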