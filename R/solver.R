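# Coupled Poisson / Nernst-Planck / Stokes-Brinkman solver on the
# axisymmetric finite-volume mesh.
#
# Outer iteration is a Gummel fixed point: (1) Poisson for the potential with
# a damped-Newton space-charge linearisation, (2) Scharfetter-Gummel
# (exponentially fitted) Nernst-Planck for each ion species, which keeps
# concentrations positive, (3) creeping-flow (Stokes) momentum with the
# electric body force on the mobile space charge and an anisotropic Brinkman
# drag inside the origami, with incompressibility enforced exactly by a
# staggered-grid saddle-point solve. The Stokes matrix depends only on the
# mesh and is factorised once per call.
#
# Linear systems are solved by sparse LU (Matrix). The Stokes block is
# nondimensionalised (lengths in nm, velocity scale 1 cm/s) so all blocks are
# well scaled.

#' Solver options
#'
#' @param tol Nonlinear (outer) tolerance on the maximum relative update over
#'   all equation blocks.
#' @param max_iter Maximum outer iterations.
#' @param relax Under-relaxation factor in (0, 1] applied to the potential,
#'   concentration, and velocity updates.
#' @param verbose Print residuals per iteration.
#' @return Object of class `solver_options`.
#' @export
solver_options <- function(tol = 1e-6, max_iter = 200, relax = 0.3,
                           verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1, relax > 0, relax <= 1)
  structure(list(tol = tol, max_iter = max_iter, relax = relax,
                 verbose = verbose), class = "solver_options")
}

# geometric precomputation shared by all blocks (SI lengths)
solver_grid <- function(mesh) {
  L <- 1e-9
  rf <- mesh$rf * L; zf <- mesh$zf * L
  rc <- mesh$rc * L; zc <- mesh$zc * L
  nr <- mesh$nr; nz <- mesh$nz
  fluid <- mesh$label == .MAT_BULK | mesh$label == .MAT_ORIGAMI
  pid <- matrix(NA_integer_, nr, nz)
  pid[fluid] <- seq_len(sum(fluid))
  Az <- pi * (rf[-1]^2 - rf[-(nr + 1)]^2)          # z-face area per ring, m^2
  Ar <- outer(2 * pi * rf, diff(zf))               # r-face areas, (nr+1) x nz
  Vc <- outer(Az, diff(zf))                        # cell volumes, m^3
  list(L = L, rf = rf, zf = zf, rc = rc, zc = zc, nr = nr, nz = nz,
       fluid = fluid, pid = pid, np = sum(fluid), Az = Az, Ar = Ar, Vc = Vc)
}

# Bernoulli function of the exponential fitting, B(x) = x/(e^x - 1)
bernoulli_fn <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-10
  out[small] <- 1 - x[small] / 2
  xs <- x[!small]
  out[!small] <- ifelse(xs > 500, 0,
                        ifelse(xs < -500, -xs, xs / (expm1(xs))))
  out
}

# --- Poisson block -----------------------------------------------------------
# Damped (Gummel-linearised) Poisson step: (-div eps grad + S) psi_new =
# rho(c) + S psi_old with S = (F^2/RT) sum z^2 c per volume.
poisson_step <- function(gr, mesh, el, psi, rho_mob, Sdamp, voltage,
                         sigma_wall) {
  eps <- el$eps_r * .const$eps0
  nr <- gr$nr; nz <- gr$nz; pid <- gr$pid; fluid <- gr$fluid
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(gr$np)

  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v)
  }

  # east faces i | i+1
  for (dir in c("e", "n")) {
    if (dir == "e") {
      pm <- fluid[-nr, , drop = FALSE] & fluid[-1, , drop = FALSE]
      A <- gr$Ar[2:nr, , drop = FALSE][pm]
      d <- matrix(diff(gr$rc), nr - 1, nz)[pm]
      P <- pid[-nr, , drop = FALSE][pm]; N <- pid[-1, , drop = FALSE][pm]
    } else {
      pm <- fluid[, -nz, drop = FALSE] & fluid[, -1, drop = FALSE]
      A <- matrix(gr$Az, nr, nz - 1)[pm]
      d <- matrix(diff(gr$zc), nr, nz - 1, byrow = TRUE)[pm]
      P <- pid[, -nz, drop = FALSE][pm]; N <- pid[, -1, drop = FALSE][pm]
    }
    Cf <- eps * A / d
    add(P, P, Cf); add(N, N, Cf); add(P, N, -Cf); add(N, P, -Cf)
  }

  # Dirichlet reservoirs: bottom (trans) +V/2, top (cis) -V/2
  bot <- which(fluid[, 1]); topc <- which(fluid[, nz])
  Cb <- eps * gr$Az[bot] / (gr$zc[1] - gr$zf[1])
  add(pid[bot, 1], pid[bot, 1], Cb)
  rhs[pid[bot, 1]] <- rhs[pid[bot, 1]] + Cb * (+voltage / 2)
  Ct <- eps * gr$Az[topc] / (gr$zf[nz + 1] - gr$zc[nz])
  add(pid[topc, nz], pid[topc, nz], Ct)
  rhs[pid[topc, nz]] <- rhs[pid[topc, nz]] + Ct * (-voltage / 2)

  # wall surface charge on fluid faces adjacent to solid cells
  if (sigma_wall != 0) {
    solid <- !fluid
    fe <- fluid[-nr, , drop = FALSE] & solid[-1, , drop = FALSE]
    rhs[pid[-nr, , drop = FALSE][fe]] <- rhs[pid[-nr, , drop = FALSE][fe]] +
      sigma_wall * gr$Ar[2:nr, , drop = FALSE][fe]
    fw <- fluid[-1, , drop = FALSE] & solid[-nr, , drop = FALSE]
    rhs[pid[-1, , drop = FALSE][fw]] <- rhs[pid[-1, , drop = FALSE][fw]] +
      sigma_wall * gr$Ar[2:nr, , drop = FALSE][fw]
    fn <- fluid[, -nz, drop = FALSE] & solid[, -1, drop = FALSE]
    rhs[pid[, -nz, drop = FALSE][fn]] <- rhs[pid[, -nz, drop = FALSE][fn]] +
      sigma_wall * matrix(gr$Az, nr, nz - 1)[fn]
    fs <- fluid[, -1, drop = FALSE] & solid[, -nz, drop = FALSE]
    rhs[pid[, -1, drop = FALSE][fs]] <- rhs[pid[, -1, drop = FALSE][fs]] +
      sigma_wall * matrix(gr$Az, nr, nz - 1)[fs]
  }

  # volume terms: space charge + damping
  Vc <- gr$Vc[fluid]
  rho_tot <- (rho_mob + mesh$rho_f)[fluid]
  add(pid[fluid], pid[fluid], Sdamp[fluid] * Vc)
  rhs <- rhs + (rho_tot + Sdamp[fluid] * psi[fluid]) * Vc

  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(gr$np, gr$np))
  sol <- as.numeric(Matrix::solve(M, rhs))
  out <- matrix(0, nr, nz)
  out[fluid] <- sol
  out
}

# --- Nernst-Planck block -----------------------------------------------------
# One species: FV balance of Scharfetter-Gummel fluxes including drift and
# advection; Dirichlet bulk concentration on the reservoir boundaries.
np_step <- function(gr, mesh, el, sp, psi, vr, vz) {
  D <- el$diffusivity[sp]; z <- el$valence[sp]; cb <- el$conc[sp]
  VT <- gas_constant() * el$temperature / .const$F
  nr <- gr$nr; nz <- gr$nz; pid <- gr$pid; fluid <- gr$fluid
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  rhs <- numeric(gr$np)
  add <- function(a, b, v) {
    ii <<- c(ii, a); jj <<- c(jj, b); xx <<- c(xx, v)
  }

  for (dir in c("e", "n")) {
    if (dir == "e") {
      pm <- fluid[-nr, , drop = FALSE] & fluid[-1, , drop = FALSE]
      A <- gr$Ar[2:nr, , drop = FALSE][pm]
      d <- matrix(diff(gr$rc), nr - 1, nz)[pm]
      P <- pid[-nr, , drop = FALSE][pm]; N <- pid[-1, , drop = FALSE][pm]
      dpsi <- (psi[-1, , drop = FALSE] - psi[-nr, , drop = FALSE])[pm]
      vfac <- vr[2:nr, , drop = FALSE][pm]
    } else {
      pm <- fluid[, -nz, drop = FALSE] & fluid[, -1, drop = FALSE]
      A <- matrix(gr$Az, nr, nz - 1)[pm]
      d <- matrix(diff(gr$zc), nr, nz - 1, byrow = TRUE)[pm]
      P <- pid[, -nz, drop = FALSE][pm]; N <- pid[, -1, drop = FALSE][pm]
      dpsi <- (psi[, -1, drop = FALSE] - psi[, -nz, drop = FALSE])[pm]
      vfac <- vz[, 2:nz, drop = FALSE][pm]
    }
    Pe <- vfac * d / D - z * dpsi / VT
    cP <- A * D / d * bernoulli_fn(-Pe)
    cN <- A * D / d * bernoulli_fn(Pe)
    add(P, P, cP); add(P, N, -cN)
    add(N, N, cN); add(N, P, -cP)
  }

  # reservoir Dirichlet (bulk) via an SG half-cell face to the boundary value
  voltage <- attr(psi, "voltage") %||% 0
  bot <- which(fluid[, 1])
  d0 <- gr$zc[1] - gr$zf[1]
  Pe <- -vz[bot, 1] * d0 / D + z * (psi[bot, 1] - voltage / 2) / VT
  cP <- gr$Az[bot] * D / d0 * bernoulli_fn(-Pe)
  cN <- gr$Az[bot] * D / d0 * bernoulli_fn(Pe)
  add(pid[bot, 1], pid[bot, 1], cP)
  rhs[pid[bot, 1]] <- rhs[pid[bot, 1]] + cN * cb
  topc <- which(fluid[, nz])
  d1 <- gr$zf[nz + 1] - gr$zc[nz]
  Pe <- vz[topc, nz + 1] * d1 / D + z * (psi[topc, nz] + voltage / 2) / VT
  cP <- gr$Az[topc] * D / d1 * bernoulli_fn(-Pe)
  cN <- gr$Az[topc] * D / d1 * bernoulli_fn(Pe)
  add(pid[topc, nz], pid[topc, nz], cP)
  rhs[pid[topc, nz]] <- rhs[pid[topc, nz]] + cN * cb

  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(gr$np, gr$np))
  sol <- as.numeric(Matrix::solve(M, rhs))
  out <- matrix(0, nr, nz)
  out[fluid] <- sol
  out
}

# species flux (mol/s) across every interior z-face row, by the same SG
# discretisation; used for the ionic current
np_zflux <- function(gr, mesh, el, sp, psi, conc, vz) {
  D <- el$diffusivity[sp]; z <- el$valence[sp]
  VT <- gas_constant() * el$temperature / .const$F
  nr <- gr$nr; nz <- gr$nz; fluid <- gr$fluid
  flux <- matrix(0, nr, nz + 1)
  pm <- fluid[, -nz, drop = FALSE] & fluid[, -1, drop = FALSE]
  A <- matrix(gr$Az, nr, nz - 1)
  d <- matrix(diff(gr$zc), nr, nz - 1, byrow = TRUE)
  dpsi <- psi[, -1, drop = FALSE] - psi[, -nz, drop = FALSE]
  Pe <- vz[, 2:nz, drop = FALSE] * d / D - z * dpsi / VT
  J <- A * D / d * (bernoulli_fn(-Pe) * conc[, -nz, drop = FALSE] -
                      bernoulli_fn(Pe) * conc[, -1, drop = FALSE])
  J[!pm] <- 0
  flux[, 2:nz] <- J
  flux
}
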