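test_that("channel permeabilities follow the capillary-bundle value and anisotropy contract", {
  # hand-evaluated capillary bundle: phi d^2/32 = 0.3 * (1.5e-9)^2 / 32
  k <- permeability_from_channels(1.5, 0.3)
  expect_equal(unname(k["kappa_par"]), 2.109e-20, tolerance = 1e-3)
  expect_gt(k["kappa_par"], k["kappa_perp"])
  expect_gt(k["kappa_perp"], 0)

  # anisotropy holds over the whole valid parameter range
  for (d in c(1, 1.5, 2)) for (phi in c(0.05, 0.2, 0.5, 0.8, 0.95)) {
    kk <- permeability_from_channels(d, phi)
    expect_gt(kk["kappa_par"] / kk["kappa_perp"], 1)
  }

  # vanishing void space: both permeabilities vanish
  k0 <- permeability_from_channels(1.5, 1e-6)
  expect_lt(k0["kappa_par"], 1e-25)
  expect_lt(k0["kappa_perp"], 1e-25)
})

test_that("geometry validation rejects degenerate configurations", {
  expect_error(pore_geometry(pore_radius = 120), "reservoir")
  expect_error(pore_geometry(pore_radius = 4, lipid = 5), "effective")
  g <- pore_geometry()
  expect_error(build_domain(g, origami_model(radius = 3)), "smaller than the pore")
  expect_error(origami_model(rho_f = 1e8), "negative")
})

test_that("bare-pore mesh has only bulk and solid materials", {
  m <- build_domain(pore_geometry(), NULL)
  expect_setequal(mesh_materials(m), c("bulk", "membrane", "lipid"))
  expect_true(all(m$invkr == 0) && all(m$invkz == 0))
})

test_that("cell volumes tile the domain exactly and the sphere volume is recovered", {
  g <- pore_geometry()
  o <- origami_model()
  m <- build_domain(g, o)
  # exact tiling of the cylindrical domain
  vtot <- pi * max(m$rf)^2 * (max(m$zf) - min(m$zf))
  expect_equal(sum(m$volume), vtot, tolerance = 1e-12)

  # origami cell volume vs the analytic volume of the seated sphere clipped
  # by the pore wall: integrate pi * r_allowed(z)^2 over the sphere extent
  R <- o$radius
  zc_s <- m$sphere_center
  r_allowed <- function(z) {
    rs <- sqrt(pmax(R^2 - (z - zc_s)^2, 0))
    ifelse(z < m$z_mem_top, pmin(rs, g$effective_radius), rs)
  }
  v_expected <- stats::integrate(function(z) pi * r_allowed(z)^2,
                                 zc_s - R, zc_s + R, rel.tol = 1e-10)$value
  vsphere <- sum(m$volume[m$label == 3L])
  expect_equal(vsphere, v_expected, tolerance = 0.01)
})

test_that("orientation swap changes only the permeability tensor axes", {
  g <- pore_geometry()
  mv <- build_domain(g, origami_model(orientation = "vertical"))
  mh <- build_domain(g, origami_model(orientation = "horizontal"))
  expect_identical(mv$label, mh$label)
  expect_identical(mv$porosity, mh$porosity)
  expect_identical(mv$rho_f, mh$rho_f)
  expect_identical(mv$rf, mh$rf)
  expect_identical(mv$zf, mh$zf)
  # tensor axes swapped inside origami cells
  expect_identical(mv$invkz, mh$invkr)
  expect_identical(mv$invkr, mh$invkz)
  org <- mv$label == 3L
  expect_true(all(mv$invkz[org] < mv$invkr[org]))  # vertical: easy axial flow
})

test_that("mesh refinement leaves the total domain volume unchanged", {
  g <- pore_geometry()
  m1 <- build_domain(g, NULL, min_cell = 1.5)
  m2 <- build_domain(g, NULL, min_cell = 0.75)
  expect_equal(sum(m1$volume), sum(m2$volume), tolerance = 1e-10)
  expect_gt(m2$nr * m2$nz, m1$nr * m1$nz)
})

test_that("mesh export writes readable node and cell tables", {
  m <- build_domain(small_geometry(), origami_model(radius = 14))
  stem <- tempfile("mesh")
  paths <- write_mesh(m, stem)
  cells <- read.csv(paths[2])
  expect_equal(nrow(cells), m$nr * m$nz)
  expect_setequal(unique(cells$material), mesh_materials(m))
})
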