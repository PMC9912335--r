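#' Electrolyte specification
#'
#' Describes the ionic species and solvent entering the
#' Poisson-Nernst-Planck-Stokes model. The default is 1 M KCl at room
#' temperature, the standard buffer for solid-state nanopore recordings.
#'
#' @param valence Integer vector of species valences z_i.
#' @param diffusivity Numeric vector of diffusivities D_i (m^2/s).
#' @param conc Numeric vector of bulk concentrations c_i (mol/m^3); must be
#'   bulk electroneutral, sum(z_i c_i) = 0.
#' @param eps_r Relative permittivity of the solvent (dimensionless).
#' @param eta Dynamic viscosity (Pa s).
#' @param temperature Temperature (K).
#' @return Object of class `electrolyte_spec`.
#' @examples
#' el <- electrolyte_spec()           # 1 M KCl
#' debye_length(el)                   # ~0.30 nm
#' @export
electrolyte_spec <- function(valence = c(1L, -1L),
                             diffusivity = c(1.96e-9, 2.03e-9),
                             conc = c(1000, 1000),
                             eps_r = 78,
                             eta = 1e-3,
                             temperature = 298) {
  n <- length(valence)
  stopifnot(length(diffusivity) == n, length(conc) == n,
            all(diffusivity > 0), all(conc > 0),
            eps_r > 0, eta > 0, temperature > 0)
  if (abs(sum(valence * conc)) > 1e-9 * sum(abs(valence) * conc))
    stop("electrolyte_spec: bulk electroneutrality sum(z_i c_i) = 0 violated")
  structure(list(valence = as.integer(valence), diffusivity = diffusivity,
                 conc = conc, eps_r = eps_r, eta = eta,
                 temperature = temperature),
            class = "electrolyte_spec")
}

#' Debye screening length
#'
#' lambda_D = sqrt(eps_r eps0 kB T / (sum (z_i e)^2 c_i NA)). Sets the
#' thickness of the ionic double layer: ~0.30 nm in 1 M KCl, ~3.0 nm in
#' 10 mM KCl; scales as c^(-1/2).
#'
#' @param electrolyte An `electrolyte_spec`.
#' @return Debye length in nm.
#' @export
debye_length <- function(electrolyte) {
  stopifnot(inherits(electrolyte, "electrolyte_spec"))
  el <- electrolyte
  denom <- sum((el$valence * .const$e)^2 * el$conc * .const$Navo)
  if (denom <= 0) stop("debye_length: zero ionic strength")
  lam <- sqrt(el$eps_r * .const$eps0 * .const$kB * el$temperature / denom)
  lam * 1e9
}

#' Bulk electrolyte conductivity (Nernst-Einstein)
#'
#' sigma = (F^2 / R T) * sum z_i^2 D_i c_i. Used for the access + channel
#' conductance cross-check of the solver.
#'
#' @param electrolyte An `electrolyte_spec`.
#' @return Conductivity in S/m.
#' @export
bulk_conductivity <- function(electrolyte) {
  el <- electrolyte
  RT <- gas_constant() * el$temperature
  .const$F^2 / RT * sum(el$valence^2 * el$diffusivity * el$conc)
}
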