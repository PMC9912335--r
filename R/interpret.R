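#' Fold change between two characteristic times
#'
#' Ratio of two characteristic trapping times, e.g. the cholesterol-locked
#' versus bare-sphere time constant for the same protein.
#'
#' @param tau_a Numeric, characteristic time of condition A (s).
#' @param tau_b Numeric, characteristic time of condition B (s); must be > 0.
#' @return `tau_a / tau_b` (dimensionless).
#' @export
fold_change <- function(tau_a, tau_b) {
  stopifnot(is.numeric(tau_a), is.numeric(tau_b))
  if (any(tau_b <= 0)) stop("fold_change: reference time constant must be positive")
  tau_a / tau_b
}

#' Trapping-barrier increase from a trapping-time fold change
#'
#' Maps a fold change in trapping time to an increase of the trapping energy
#' barrier via the Boltzmann factor, tau ~ exp(dG / kB T), assuming the
#' attempt frequency is unchanged between conditions. A 100-fold extension of
#' the trapping time thus corresponds to ln(100) = 4.6, i.e. about 5 kB T.
#'
#' @param fold Positive fold change in trapping time.
#' @return Barrier increase in units of kB T.
#' @export
barrier_increase <- function(fold) {
  stopifnot(is.numeric(fold))
  if (any(fold <= 0)) stop("barrier_increase: fold change must be positive")
  log(fold)
}

#' Stokes drag force on a trapped protein
#'
#' Viscous drag F = 6 pi eta r v on a sphere of hydrodynamic radius r held in
#' a flow of local velocity v. For a small protein (r ~ 3 nm) in the
#' electro-osmotic flow at the pore (v of order cm/s) this is of picoNewton
#' magnitude.
#'
#' @param eta Dynamic viscosity (Pa s).
#' @param r Hydrodynamic radius (m).
#' @param v Local fluid velocity (m/s).
#' @return Force in Newton.
#' @export
stokes_drag <- function(eta, r, v) {
  stopifnot(eta > 0, r > 0, is.numeric(v))
  6 * pi * eta * r * v
}

#' Exponential mass scaling of trapping times
#'
#' Fits ln(tau) = ln(tau0) + b * M by ordinary least squares, the exponential
#' dependence of trapping time on protein molecular mass. The fit is performed
#' in log space, where multiplicative (lognormal) scatter in tau is
#' homoscedastic.
#'
#' @param mass_kda Numeric vector of molecular masses (kDa), at least two
#'   distinct values.
#' @param tau_s Numeric vector of characteristic trapping times (s), > 0.
#' @return An object of class `mass_scaling_fit`: list with `ln_tau0`, `tau0`,
#'   `slope` (1/kDa), `se_slope`, `residuals` (on ln tau), and the underlying
#'   `lm` fit.
#' @export
fit_mass_scaling <- function(mass_kda, tau_s) {
  stopifnot(length(mass_kda) == length(tau_s), length(mass_kda) >= 2)
  if (any(tau_s <= 0)) stop("fit_mass_scaling: trapping times must be positive")
  if (length(unique(mass_kda)) < 2)
    stop("fit_mass_scaling: need at least two distinct masses")
  fit <- stats::lm(log(tau_s) ~ mass_kda)
  cf <- stats::coef(fit)
  # suppressWarnings: R warns on essentially perfect (noise-free) fits
  se <- tryCatch(suppressWarnings(
    summary(fit)$coefficients["mass_kda", "Std. Error"]),
    error = function(e) NA_real_)
  structure(list(
    ln_tau0 = unname(cf[1]),
    tau0 = exp(unname(cf[1])),
    slope = unname(cf[2]),
    se_slope = unname(se),
    residuals = unname(stats::residuals(fit)),
    fit = fit
  ), class = "mass_scaling_fit")
}

#' @export
print.mass_scaling_fit <- function(x, ...) {
  cat(sprintf("Mass scaling: tau = %.3g s * exp(%.4g /kDa * M)\n", x$tau0, x$slope))
  invisible(x)
}
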