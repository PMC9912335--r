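# Structured axisymmetric finite-volume mesh of the docked-sphere nanopore
# domain. Cells are axis-aligned annular rings; material (bulk fluid,
# membrane, lipid, origami) is constant per cell and assigned by cell center.
# The mesh is graded: uniform fine spacing around the membrane, pore, and
# sphere, geometric coarsening toward the reservoir boundaries.

.MAT_BULK <- 0L; .MAT_MEMBRANE <- 1L; .MAT_LIPID <- 2L; .MAT_ORIGAMI <- 3L
.MAT_NAMES <- c(bulk = 0L, membrane = 1L, lipid = 2L, origami = 3L)

# uniform subdivision of [a, b] into cells of size ~h (exact fit)
faces_uniform <- function(a, b, h) {
  if (b - a < 1e-9) return(a)
  n <- max(1L, ceiling((b - a) / h - 1e-9))
  seq(a, b, length.out = n + 1L)
}

# graded subdivision: spacing h0 at the `fine_end` ("lo"/"hi"), growing by
# `grade` per cell up to hmax, rescaled to fit [a, b] exactly
faces_graded <- function(a, b, h0, hmax, grade = 1.3, fine_end = "lo") {
  len <- b - a
  steps <- numeric(0)
  h <- h0
  while (sum(steps) < len) {
    steps <- c(steps, h)
    h <- min(h * grade, hmax)
  }
  steps <- steps * (len / sum(steps))
  if (fine_end == "hi") steps <- rev(steps)
  a + c(0, cumsum(steps))
}

#' Build the axisymmetric computational domain
#'
#' Assembles the graded structured mesh covering both reservoirs, the
#' lipid-coated membrane, the pore lumen, and (if given) the docked origami
#' sphere, tangent to the membrane top at the pore axis. Origami cells carry
#' the orientation-dependent permeability tensor: kappa_par along z for a
#' vertical sphere, along r for a horizontal one.
#'
#' @param geometry A `pore_geometry`.
#' @param origami An `origami_model`, or NULL for a bare pore.
#' @param electrolyte Optional `electrolyte_spec`; with `resolution` it sets
#'   the fine spacing to `debye_length/resolution` where that is coarser than
#'   `min_cell` (smeared volumetric charge does not require sub-Debye cells
#'   for flux metrics; see the package vignette).
#' @param resolution Target cells per Debye length in charged regions.
#' @param min_cell Finest allowed cell size (nm).
#' @param max_cell Coarsest cell size in the far reservoirs (nm).
#' @param grade Geometric growth factor of the coarsening.
#' @param min_cell_z Finest axial cell size (nm); defaults to the radial
#'   value. Useful where gradients are predominantly radial (long channels).
#' @return Object of class `axi_mesh`: face coordinates `rf`, `zf` (nm), cell
#'   centers/sizes, per-cell `label`, `porosity`, `rho_f` (C/m^3), inverse
#'   permeabilities `invkr`, `invkz` (1/m^2), `volume` (nm^3), plus the input
#'   specs and key axial coordinates.
#' @export
build_domain <- function(geometry, origami = NULL, electrolyte = NULL,
                         resolution = 2, min_cell = 0.75, max_cell = 8,
                         grade = 1.3, min_cell_z = NULL) {
  stopifnot(inherits(geometry, "pore_geometry"))
  if (!is.null(origami)) {
    stopifnot(inherits(origami, "origami_model"))
    if (origami$radius < geometry$effective_radius)
      stop("build_domain: origami sphere smaller than the pore cannot dock")
  }
  h <- min_cell
  if (!is.null(electrolyte)) {
    stopifnot(resolution >= 2)
    h <- max(min_cell, debye_length(electrolyte) / resolution)
  }
  hz <- if (is.null(min_cell_z)) h else min_cell_z

  g <- geometry
  a_eff <- g$effective_radius
  z1 <- g$reservoir_height            # membrane (slab) bottom
  z2 <- z1 + g$slab                   # slab top
  rs <- if (is.null(origami)) 0 else origami$radius
  pad <- 2
  z_fine_top <- z2 + (if (rs > 0) 2 * rs + pad else pad)
  z_top <- z_fine_top + g$reservoir_height

  zf <- c(
    faces_graded(0, z1 - pad, hz, max_cell, grade, fine_end = "hi"),
    faces_uniform(z1 - pad, z1, hz)[-1],
    faces_uniform(z1, z1 + g$lipid, hz)[-1],
    faces_uniform(z1 + g$lipid, z2 - g$lipid, hz)[-1],
    faces_uniform(z2 - g$lipid, z2, hz)[-1],
    faces_uniform(z2, z_fine_top, hz)[-1],
    faces_graded(z_fine_top, z_top, hz, max_cell, grade, fine_end = "lo")[-1]
  )

  r_fine <- min(max(g$pore_radius, rs) + pad, g$reservoir_radius)
  rf <- c(
    faces_uniform(0, a_eff, h),
    faces_uniform(a_eff, g$pore_radius, h)[-1],
    faces_uniform(g$pore_radius, r_fine, h)[-1],
    if (r_fine < g$reservoir_radius)
      faces_graded(r_fine, g$reservoir_radius, h, max_cell, grade,
                   fine_end = "lo")[-1]
  )

  nr <- length(rf) - 1L; nz <- length(zf) - 1L
  rc <- (rf[-1] + rf[-length(rf)]) / 2
  zc <- (zf[-1] + zf[-length(zf)]) / 2
  dr <- diff(rf); dz <- diff(zf)

  R <- matrix(rc, nr, nz); Z <- matrix(zc, nr, nz, byrow = TRUE)
  label <- matrix(.MAT_BULK, nr, nz)

  in_slab <- Z > z1 & Z < z2 & R > a_eff
  sin_core <- Z > z1 + g$lipid & Z < z2 - g$lipid & R > g$pore_radius
  label[in_slab] <- .MAT_LIPID
  label[in_slab & sin_core] <- .MAT_MEMBRANE

  # the docked sphere seats on the pore rim (electrophoretically pressed):
  # center height above the slab such that the sphere touches the rim circle
  # r = a_eff, settling a further seat_depth into the mouth
  zc_sph <- z2 + (if (rs > 0) sqrt(rs^2 - a_eff^2) - origami$seat_depth else 0)
  if (rs > 0) {
    in_sph <- (R^2 + (Z - zc_sph)^2) <= rs^2 & label == .MAT_BULK
    label[in_sph] <- .MAT_ORIGAMI
  }

  porosity <- matrix(1, nr, nz)
  porosity[label == .MAT_MEMBRANE | label == .MAT_LIPID] <- 0
  rho_f <- matrix(0, nr, nz)
  invkr <- matrix(0, nr, nz); invkz <- matrix(0, nr, nz)
  if (rs > 0) {
    org <- label == .MAT_ORIGAMI
    porosity[org] <- origami$phi
    rho_f[org] <- origami$rho_f
    if (origami$orientation == "vertical") {
      invkz[org] <- 1 / origami$kappa_par
      invkr[org] <- 1 / origami$kappa_perp
    } else {
      invkz[org] <- 1 / origami$kappa_perp
      invkr[org] <- 1 / origami$kappa_par
    }
  }

  vol <- outer(pi * (rf[-1]^2 - rf[-length(rf)]^2), dz)  # nm^3

  structure(list(rf = rf, zf = zf, rc = rc, zc = zc, dr = dr, dz = dz,
                 nr = nr, nz = nz, label = label, porosity = porosity,
                 rho_f = rho_f, invkr = invkr, invkz = invkz, volume = vol,
                 geometry = geometry, origami = origami,
                 z_mem_bottom = z1, z_mem_top = z2,
                 sphere_bottom = if (rs > 0) zc_sph - rs else NA_real_,
                 sphere_center = if (rs > 0) zc_sph else NA_real_,
                 h_fine = h),
            class = "axi_mesh")
}

#' @export
print.axi_mesh <- function(x, ...) {
  cat(sprintf("axi_mesh: %d x %d cells, r up to %g nm, z up to %g nm, h_fine %.3g nm\n",
              x$nr, x$nz, max(x$rf), max(x$zf), x$h_fine))
  tb <- table(factor(x$label, levels = .MAT_NAMES,
                     labels = names(.MAT_NAMES)))
  print(tb)
  invisible(x)
}

#' Material names present in a mesh
#' @param mesh An `axi_mesh`.
#' @return Character vector of material labels used.
#' @export
mesh_materials <- function(mesh) {
  names(.MAT_NAMES)[.MAT_NAMES %in% unique(as.integer(mesh$label))]
}

#' Export a mesh to plain-text node/cell files
#'
#' Writes `<stem>_nodes.csv` (face-grid node coordinates) and
#' `<stem>_cells.csv` (per-cell center, size, material, porosity, fixed
#' charge, permeability components) for external inspection.
#'
#' @param mesh An `axi_mesh`.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_mesh <- function(mesh, stem) {
  nodes <- expand.grid(r_nm = mesh$rf, z_nm = mesh$zf)
  fn <- paste0(stem, "_nodes.csv")
  utils::write.csv(nodes, fn, row.names = FALSE)
  cells <- data.frame(
    r_nm = as.vector(matrix(mesh$rc, mesh$nr, mesh$nz)),
    z_nm = as.vector(matrix(mesh$zc, mesh$nr, mesh$nz, byrow = TRUE)),
    material = names(.MAT_NAMES)[match(as.vector(mesh$label), .MAT_NAMES)],
    porosity = as.vector(mesh$porosity),
    rho_f = as.vector(mesh$rho_f),
    inv_kappa_r = as.vector(mesh$invkr),
    inv_kappa_z = as.vector(mesh$invkz))
  fc <- paste0(stem, "_cells.csv")
  utils::write.csv(cells, fc, row.names = FALSE)
  invisible(c(fn, fc))
}
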