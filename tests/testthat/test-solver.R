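# Solver verification against analytic limits. Meshes are kept small; the
# oracles are closed-form hydrodynamic/electrokinetic results.

test_that("zero bias and no pressure give identically quiescent fields", {
  m <- small_mesh()
  el <- electrolyte_spec()
  sol <- solve_coupled(m, el, voltage = 0, opts = fast_opts())
  expect_true(sol$converged)
  expect_equal(max(abs(sol$vz)), 0, tolerance = 1e-15)
  expect_equal(ionic_current(sol), 0, tolerance = 1e-18)
  expect_equal(flow_rate(sol), 0, tolerance = 1e-30)
  # equilibrium concentrations: bulk everywhere (uncharged walls)
  expect_equal(max(abs(sol$conc[[1]][m$label == 0L] - 1000)), 0,
               tolerance = 1e-6)
})

test_that("pressure-driven flow reproduces the Poiseuille profile and law", {
  g <- pore_geometry(pore_radius = 25, membrane = 90, lipid = 5,
                     reservoir_radius = 60, reservoir_height = 30)
  m <- build_domain(g, NULL, min_cell = 1, max_cell = 4)
  el <- electrolyte_spec()
  sol <- solve_coupled(m, el, voltage = 0, opts = fast_opts(),
                       pressure_drop = 2000)
  expect_true(sol$converged)
  zmid <- m$z_mem_bottom + g$slab / 2
  b <- 20e-9; L <- (g$membrane + 2 * g$lipid) * 1e-9

  # flow rate vs the Hagen-Poiseuille law at the channel pressure drop
  jb <- which.min(abs(m$zc - m$z_mem_bottom))
  jt <- which.min(abs(m$zc - m$z_mem_top))
  dp <- sol$p[1, jb] - sol$p[1, jt]
  Q_an <- pi * b^4 * dp / (8 * el$eta * L)
  expect_equal(flow_rate(sol, zmid), Q_an, tolerance = 0.02)

  # parabolic profile at the channel midplane
  jm <- which.min(abs(m$zf - zmid))
  lum <- m$rc < 20
  vz <- sol$vz[lum, jm]
  parab <- vz[1] * (1 - (m$rc[lum] / 20)^2)
  expect_lt(max(abs(vz - parab)) / max(vz), 0.02)
})

test_that("wall-charged channel EOF matches the cylindrical Helmholtz-Smoluchowski limit", {
  g <- pore_geometry(pore_radius = 15, membrane = 190, lipid = 5,
                     reservoir_radius = 60, reservoir_height = 40)
  el <- electrolyte_spec(conc = c(20, 20))
  m <- build_domain(g, NULL, electrolyte = el, resolution = 4,
                    min_cell = 0.5, max_cell = 5, min_cell_z = 4)
  sig <- -2e-3
  sol <- solve_coupled(m, el, voltage = 0.2, opts = fast_opts(relax = 0.5),
                       sigma_wall = sig)
  expect_true(sol$converged)
  zmid <- m$z_mem_bottom + g$slab / 2
  jm <- which.min(abs(m$zf - zmid))
  v_axis <- sol$vz[1, jm]
  # local axial field on the axis around the midplane
  jb <- which.min(abs(m$zc - (zmid - 40)))
  jt <- which.min(abs(m$zc - (zmid + 40)))
  E <- -(sol$psi[1, jt] - sol$psi[1, jb]) / ((m$zc[jt] - m$zc[jb]) * 1e-9)
  eps <- el$eps_r * 8.8541878128e-12
  lam <- debye_length(el) * 1e-9
  x <- 10e-9 / lam
  zeta <- sig * lam / eps * besselI(x, 0) / besselI(x, 1)
  v_th <- -eps * zeta * E / el$eta * (1 - 1 / besselI(x, 0))
  expect_equal(v_axis, v_th, tolerance = 0.1)
  # EOF for a negative wall under positive bias flows upward
  expect_gt(v_axis, 0)
})

test_that("current and flow are plane-independent and the conductance matches the access formula", {
  m <- small_mesh()
  el <- electrolyte_spec()
  sol <- solve_coupled(m, el, voltage = 0.02, opts = fast_opts())
  expect_true(sol$converged)
  zmid <- m$z_mem_bottom + m$geometry$slab / 2
  planes <- c(zmid, m$z_mem_bottom - 10, m$z_mem_top + 25)
  I <- vapply(planes, function(z) ionic_current(sol, z), numeric(1))
  Q <- vapply(planes, function(z) flow_rate(sol, z), numeric(1))
  expect_lt(max(abs(I - I[1])) / abs(I[1]), 0.01)
  expect_lt(diff(range(Q)), 0.01 * max(abs(Q), 1e-25) + 1e-25)

  # bare-pore conductance vs sigma_b * [4t/(pi d^2) + 1/d]^-1
  d <- 2 * m$geometry$effective_radius * 1e-9
  t <- m$geometry$slab * 1e-9
  G_an <- bulk_conductivity(el) / (4 * t / (pi * d^2) + 1 / d)
  expect_equal(I[1] / 0.02, G_an, tolerance = 0.15)
})

test_that("low-bias response is linear and antisymmetric", {
  m <- small_mesh("vertical")
  el <- electrolyte_spec()
  sols <- lapply(c(0.02, 0.01, -0.02),
                 function(v) solve_coupled(m, el, v, opts = fast_opts()))
  I <- vapply(sols, ionic_current, numeric(1))
  Q <- vapply(sols, flow_rate, numeric(1))
  expect_equal(I[1] / I[2], 2, tolerance = 0.05)
  expect_equal(Q[1] / Q[2], 2, tolerance = 0.05)
  # reversing the bias reverses current and flow; the residual asymmetry is
  # genuine rectification by the charged sphere, O(V) small at low bias
  expect_lt(abs(I[3] + I[1]), 0.08 * abs(I[1]))
  expect_lt(abs(Q[3] + Q[1]), 0.08 * abs(Q[1]))
})

test_that("EOF grows with the origami charge density and with vertical orientation", {
  el <- electrolyte_spec()
  g <- small_geometry()
  base <- origami_model(radius = 14)
  Q <- function(o) {
    m <- build_domain(g, o, min_cell = 1, max_cell = 6)
    sol <- solve_coupled(m, el, 0.1, opts = fast_opts())
    expect_true(sol$converged)
    flow_rate(sol)
  }
  q_v <- Q(base)
  q_h <- Q(origami_model(radius = 14, orientation = "horizontal"))
  q_v_weak <- Q(origami_model(radius = 14, rho_f = base$rho_f / 3))
  expect_gt(q_v, 0)              # EOF pumps from trans to cis
  expect_gt(q_v, q_h)            # the central orientation contrast
  expect_gt(abs(q_v), abs(q_v_weak))  # more charge, more EOF

  # swapping the anisotropy only (same scalars) preserves the contrast
  kap <- permeability_from_channels(2, 0.4)
  q_v2 <- Q(origami_model(radius = 14, d_c = 2, phi = 0.4))
  q_h2 <- Q(origami_model(radius = 14, d_c = 2, phi = 0.4,
                          orientation = "horizontal"))
  expect_gt(q_v2, q_h2)
})

test_that("axial velocity profile peaks near the pore and decays to the far field", {
  m <- small_mesh("vertical")
  el <- electrolyte_spec()
  sol <- solve_coupled(m, el, 0.1, opts = fast_opts())
  prof <- axial_velocity_profile(sol)
  expect_equal(nrow(prof), m$nz + 1)
  vpk <- max(abs(prof$vz_ms))
  far <- abs(prof$vz_ms[which.min(prof$z_nm)])
  expect_lt(far, 0.1 * vpk)
  # the vertical profile dominates the horizontal one through the pore region
  mh <- small_mesh("horizontal")
  solh <- solve_coupled(mh, el, 0.1, opts = fast_opts())
  profh <- axial_velocity_profile(solh)
  pore <- prof$z_nm > m$z_mem_bottom & prof$z_nm < m$z_mem_top
  expect_true(all(abs(prof$vz_ms[pore]) > abs(profh$vz_ms[pore])))
})

test_that("field export and summary report round the run's key quantities", {
  m <- small_mesh("vertical")
  el <- electrolyte_spec()
  sol <- solve_coupled(m, el, 0.1, opts = fast_opts())
  f <- tempfile(fileext = ".csv")
  write_field(sol, f)
  d <- read.csv(f)
  expect_equal(nrow(d), m$nr * m$nz)
  expect_true(all(c("psi_V", "vz_ms", "p_Pa", "c1_mM") %in% names(d)))
  s <- field_summary(sol)
  expect_true(s$converged)
  expect_equal(s$flow_rate_m3s, flow_rate(sol))
  expect_error(ionic_current(sol, 1e5), "outside")
  expect_error(solve_coupled(m, el, 2), "1 V")
})
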