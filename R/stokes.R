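# Staggered-grid (MAC) Stokes-Brinkman block of the coupled solver.
#
# Velocities live on cell faces, pressure at cell centers; incompressibility
# is a per-cell flux balance, so the computed flow rate is conserved to
# machine precision and plane-independent. The block is nondimensionalised
# with lengths in nm and a 1 cm/s velocity scale; momentum and continuity
# rows are then all O(1) and the saddle-point system is solved by sparse LU,
# factorised once per mesh.

.stokes_U0 <- 1e-2  # velocity scale, m/s

# Assemble the Stokes-Brinkman saddle-point operator for a mesh.
# Returns unknown index maps, the factorised matrix, and index arrays used to
# rebuild the (iteration-dependent) body-force RHS quickly.
stokes_setup <- function(gr, mesh, eta, pressure_drop = 0) {
  nr <- gr$nr; nz <- gr$nz
  fluid <- gr$fluid
  rf <- mesh$rf; zf <- mesh$zf; rc <- mesh$rc; zc <- mesh$zc
  dr <- mesh$dr; dz <- mesh$dz
  L0 <- 1e-9; U0 <- .stokes_U0
  P0 <- eta * U0 / L0          # pressure scale, Pa
  F0 <- eta * U0 / L0^2        # body-force scale, N/m^3

  vr_id <- matrix(NA_integer_, nr + 1, nz)
  for (i in 2:nr) for (j in 1:nz)
    if (fluid[i - 1, j] && fluid[i, j]) vr_id[i, j] <- 1L
  vz_id <- matrix(NA_integer_, nr, nz + 1)
  for (i in 1:nr) {
    if (fluid[i, 1]) vz_id[i, 1] <- 1L
    if (fluid[i, nz]) vz_id[i, nz + 1] <- 1L
    for (j in 2:nz) if (fluid[i, j - 1] && fluid[i, j]) vz_id[i, j] <- 1L
  }
  nvr <- sum(!is.na(vr_id)); nvz <- sum(!is.na(vz_id)); npp <- gr$np
  vr_id[!is.na(vr_id)] <- seq_len(nvr)
  vz_id[!is.na(vz_id)] <- nvr + seq_len(nvz)
  p_id <- matrix(NA_integer_, nr, nz)
  p_id[fluid] <- nvr + nvz + seq_len(npp)
  ntot <- nvr + nvz + npp

  cap <- 16L * ntot
  ti <- integer(cap); tj <- integer(cap); tx <- numeric(cap); nt <- 0L
  add <- function(a, b, v) {
    nt <<- nt + 1L
    if (nt > length(ti)) {
      length(ti) <<- 2L * length(ti); length(tj) <<- 2L * length(tj)
      length(tx) <<- 2L * length(tx)
    }
    ti[nt] <<- a; tj[nt] <<- b; tx[nt] <<- v
  }
  rhs0 <- numeric(ntot)

  vr_list <- which(!is.na(vr_id), arr.ind = TRUE)
  vr_list <- vr_list[order(vr_id[!is.na(vr_id)]), , drop = FALSE]
  vz_list <- which(!is.na(vz_id), arr.ind = TRUE)
  vz_list <- vz_list[order(vz_id[!is.na(vz_id)]), , drop = FALSE]

  # --- r-momentum -----------------------------------------------------------
  for (q in seq_len(nvr)) {
    i <- vr_list[q, 1]; j <- vr_list[q, 2]
    row <- vr_id[i, j]
    # radial: d/dr[(1/r) d(r vr)/dr]
    span <- rc[i] - rc[i - 1]
    for (m in c(i - 1L, i)) {
      sgn <- if (m == i) 1 else -1
      cc <- sgn / (span * rc[m] * dr[m])
      if (!is.na(vr_id[m + 1, j])) add(row, vr_id[m + 1, j],  cc * rf[m + 1])
      if (!is.na(vr_id[m, j]))     add(row, vr_id[m, j],     -cc * rf[m])
    }
    # axial diffusion with wall ghosts
    dzj <- dz[j]
    if (j < nz) {
      wall_up <- !fluid[i - 1, j + 1] && !fluid[i, j + 1]
      if (wall_up) {
        add(row, row, -1 / ((zf[j + 1] - zc[j]) * dzj))
      } else {
        h <- zc[j + 1] - zc[j]
        if (!is.na(vr_id[i, j + 1])) add(row, vr_id[i, j + 1], 1 / (h * dzj))
        add(row, row, -1 / (h * dzj))
      }
    }
    if (j > 1) {
      wall_dn <- !fluid[i - 1, j - 1] && !fluid[i, j - 1]
      if (wall_dn) {
        add(row, row, -1 / ((zc[j] - zf[j]) * dzj))
      } else {
        h <- zc[j] - zc[j - 1]
        if (!is.na(vr_id[i, j - 1])) add(row, vr_id[i, j - 1], 1 / (h * dzj))
        add(row, row, -1 / (h * dzj))
      }
    }
    # pressure gradient
    add(row, p_id[i, j], -1 / span)
    add(row, p_id[i - 1, j], 1 / span)
    # Brinkman drag
    ik <- L0^2 * (mesh$invkr[i - 1, j] + mesh$invkr[i, j]) / 2
    if (ik > 0) add(row, row, -ik)
  }

  # --- z-momentum -----------------------------------------------------------
  for (q in seq_len(nvz)) {
    i <- vz_list[q, 1]; j <- vz_list[q, 2]
    row <- vz_id[i, j]
    cells <- if (j == 1) 1L else if (j == nz + 1) nz else c(j - 1L, j)
    # radial: (1/r) d/dr (r dvz/dr), free slip at the outer boundary
    if (i < nr) {
      wall_e <- all(!fluid[i + 1, cells])
      if (wall_e) {
        add(row, row, -rf[i + 1] / ((rf[i + 1] - rc[i]) * rc[i] * dr[i]))
      } else {
        h <- rc[i + 1] - rc[i]
        cc <- rf[i + 1] / (h * rc[i] * dr[i])
        if (!is.na(vz_id[i + 1, j])) add(row, vz_id[i + 1, j], cc)
        add(row, row, -cc)
      }
    }
    if (i > 1) {
      wall_w <- all(!fluid[i - 1, cells])
      if (wall_w) {
        add(row, row, -rf[i] / ((rc[i] - rf[i]) * rc[i] * dr[i]))
      } else {
        h <- rc[i] - rc[i - 1]
        cc <- rf[i] / (h * rc[i] * dr[i])
        if (!is.na(vz_id[i - 1, j])) add(row, vz_id[i - 1, j], cc)
        add(row, row, -cc)
      }
    }
    # axial diffusion
    dzm <- if (j > 1) dz[j - 1] else dz[1]
    dzp <- if (j <= nz) dz[j] else dz[nz]
    ctrl <- (dzm + dzp) / 2
    if (j <= nz) {
      if (!is.na(vz_id[i, j + 1])) add(row, vz_id[i, j + 1], 1 / (dzp * ctrl))
      add(row, row, -1 / (dzp * ctrl))
    }
    if (j > 1) {
      if (!is.na(vz_id[i, j - 1])) add(row, vz_id[i, j - 1], 1 / (dzm * ctrl))
      add(row, row, -1 / (dzm * ctrl))
    }
    # pressure gradient (ghost reservoir pressure at open boundaries)
    if (j == 1) {
      h <- 2 * (zc[1] - zf[1])
      add(row, p_id[i, 1], -1 / h)
      rhs0[row] <- rhs0[row] - (pressure_drop / P0) / h
    } else if (j == nz + 1) {
      h <- 2 * (zf[nz + 1] - zc[nz])
      add(row, p_id[i, nz], 1 / h)
    } else {
      h <- zc[j] - zc[j - 1]
      add(row, p_id[i, j], -1 / h)
      add(row, p_id[i, j - 1], 1 / h)
    }
    # Brinkman drag
    ik <- L0^2 * mean(mesh$invkz[i, cells])
    if (ik > 0) add(row, row, -ik)
  }

  # --- continuity -----------------------------------------------------------
  for (i in 1:nr) for (j in 1:nz) {
    if (!fluid[i, j]) next
    row <- p_id[i, j]
    Vh <- pi * (rf[i + 1]^2 - rf[i]^2) * dz[j]
    if (!is.na(vr_id[i + 1, j]))
      add(row, vr_id[i + 1, j],  2 * pi * rf[i + 1] * dz[j] / Vh)
    if (!is.na(vr_id[i, j]))
      add(row, vr_id[i, j],     -2 * pi * rf[i] * dz[j] / Vh)
    Ah <- pi * (rf[i + 1]^2 - rf[i]^2)
    if (!is.na(vz_id[i, j + 1])) add(row, vz_id[i, j + 1],  Ah / Vh)
    if (!is.na(vz_id[i, j]))     add(row, vz_id[i, j],     -Ah / Vh)
  }

  A <- Matrix::sparseMatrix(i = ti[seq_len(nt)], j = tj[seq_len(nt)],
                            x = tx[seq_len(nt)], dims = c(ntot, ntot))
  list(A = A, lu = Matrix::lu(A), rhs0 = rhs0,
       vr_id = vr_id, vz_id = vz_id, p_id = p_id,
       vr_list = vr_list, vz_list = vz_list,
       nvr = nvr, nvz = nvz, npp = npp, ntot = ntot,
       F0 = F0, P0 = P0, U0 = U0, L0 = L0)
}

# Solve the Stokes block for a given mobile charge density and potential.
stokes_solve <- function(st, gr, mesh, rho_mob, psi) {
  rhs <- st$rhs0
  L0 <- st$L0
  # body force on vr faces: f_r = -rho * dpsi/dr (mobile charge only)
  vl <- st$vr_list
  if (nrow(vl)) {
    i <- vl[, 1]; j <- vl[, 2]
    span <- (mesh$rc[i] - mesh$rc[i - 1]) * L0
    fr <- -0.5 * (rho_mob[cbind(i - 1, j)] + rho_mob[cbind(i, j)]) *
      (psi[cbind(i, j)] - psi[cbind(i - 1, j)]) / span
    rhs[st$vr_id[cbind(i, j)]] <- rhs[st$vr_id[cbind(i, j)]] - fr / st$F0
  }
  vl <- st$vz_list
  interior <- vl[, 2] > 1 & vl[, 2] <= gr$nz
  if (any(interior)) {
    i <- vl[interior, 1]; j <- vl[interior, 2]
    span <- (mesh$zc[j] - mesh$zc[j - 1]) * L0
    fz <- -0.5 * (rho_mob[cbind(i, j - 1)] + rho_mob[cbind(i, j)]) *
      (psi[cbind(i, j)] - psi[cbind(i, j - 1)]) / span
    rhs[st$vz_id[cbind(i, j)]] <- rhs[st$vz_id[cbind(i, j)]] - fz / st$F0
  }
  sol <- as.numeric(Matrix::solve(st$lu, rhs))
  vr <- matrix(0, gr$nr + 1, gr$nz)
  ok <- !is.na(st$vr_id)
  vr[ok] <- sol[st$vr_id[ok]] * st$U0
  vz <- matrix(0, gr$nr, gr$nz + 1)
  ok <- !is.na(st$vz_id)
  vz[ok] <- sol[st$vz_id[ok]] * st$U0
  p <- matrix(0, gr$nr, gr$nz)
  p[gr$fluid] <- sol[st$p_id[gr$fluid]] * st$P0
  list(vr = vr, vz = vz, p = p)
}
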