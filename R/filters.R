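# Low-pass filtering of current traces.
#
# Patch-clamp style acquisition applies a causal analog low-pass (classically a
# 4-pole Bessel, valued for its flat group delay) before digitisation. The
# Bessel design is built from the tabulated 4th-order analog prototype poles
# (-3 dB frequency normalised to 1 rad/s) and mapped to a digital filter by the
# bilinear transform with frequency prewarping; Butterworth designs come from
# signal::butter.

# 4th-order Bessel prototype, -3 dB magnitude-normalised
.bessel4_poles <- c(-0.99520876 + 1.25710574i, -1.37006783 + 0.41024972i,
                    -1.37006783 - 0.41024972i, -0.99520876 - 1.25710574i)

#' Design a causal low-pass filter
#'
#' @param cutoff -3 dB cutoff frequency (Hz).
#' @param fs Sample rate (Hz); `cutoff < fs/2` required.
#' @param family "bessel" (4-pole, default), "butterworth", or "none".
#' @param order Filter order (Bessel implementation is fixed at 4).
#' @return List with ARMA coefficients `b`, `a` (or NULL for "none").
#' @keywords internal
design_lowpass <- function(cutoff, fs, family = c("bessel", "butterworth", "none"),
                           order = 4) {
  family <- match.arg(family)
  if (family == "none") return(NULL)
  stopifnot(cutoff > 0, cutoff < fs / 2)
  if (family == "butterworth") {
    bf <- signal::butter(order, 2 * cutoff / fs, type = "low")
    return(list(b = bf$b, a = bf$a))
  }
  if (order != 4) stop("Bessel design implemented for order 4 only")
  wc <- 2 * fs * tan(pi * cutoff / fs)  # prewarped analog cutoff (rad/s)
  p <- .bessel4_poles * wc
  g <- Re(prod(-p))                      # unity DC gain
  zpg <- signal::bilinear(Sz = complex(0), Sp = p, Sg = g, T = 1 / fs)
  b <- Re(polyz(zpg$zero)) * zpg$gain
  a <- Re(polyz(zpg$pole))
  list(b = b, a = a)
}

# monic polynomial coefficients from roots (descending powers)
polyz <- function(r) {
  p <- 1 + 0i
  for (x in r) p <- c(p, 0) - c(0, p * x)
  p
}

#' Apply a causal low-pass filter to a sampled signal
#' @keywords internal
apply_lowpass <- function(x, cutoff, fs, family = "bessel", order = 4) {
  fl <- design_lowpass(cutoff, fs, family, order)
  if (is.null(fl)) return(x)
  as.numeric(signal::filter(fl$b, fl$a, x))
}

#' Frequency response magnitude-squared of the acquisition filter
#'
#' Used for equivalent-noise-bandwidth computations: ENBW = integral of
#' |H(f)|^2 df over (0, fs/2) for a unity-DC-gain low-pass.
#'
#' @param cutoff,fs,family,order As in `design_lowpass`.
#' @param n Number of frequency points.
#' @return data.frame with `freq` (Hz) and `h2` (|H|^2).
#' @keywords internal
filter_response2 <- function(cutoff, fs, family = "bessel", order = 4, n = 4096) {
  fl <- design_lowpass(cutoff, fs, family, order)
  f <- seq(0, fs / 2, length.out = n)
  if (is.null(fl)) return(data.frame(freq = f, h2 = rep(1, n)))
  w <- 2 * pi * f / fs
  z <- exp(1i * w)
  num <- outer(z, seq_along(fl$b) - 1, function(zz, k) zz^(-k)) %*% fl$b
  den <- outer(z, seq_along(fl$a) - 1, function(zz, k) zz^(-k)) %*% fl$a
  data.frame(freq = f, h2 = as.numeric(Mod(num / den)^2))
}

#' Equivalent noise bandwidth of the acquisition filter (Hz)
#' @keywords internal
filter_enbw <- function(cutoff, fs, family = "bessel", order = 4) {
  r <- filter_response2(cutoff, fs, family, order)
  sum(r$h2) * (r$freq[2] - r$freq[1])
}

#' 10-90% rise time of the acquisition low-pass (s)
#'
#' Approximated by the standard single-pole-equivalent relation 0.34/cutoff,
#' adequate for flagging events too brief for full amplitude resolution.
#' @keywords internal
filter_rise_time <- function(cutoff) 0.34 / cutoff
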