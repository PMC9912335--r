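# Noise and level metrics: Welch power spectral density, sigma over a stated
# bandwidth, signal-to-noise ratio, relative blockades, and the pink + white
# decomposition S(f) = A/f^alpha + B of the baseline spectrum.

#' Welch power spectral density estimate
#'
#' Averaged periodogram over Hann-windowed, half-overlapping segments,
#' one-sided and normalised so that the integral of the PSD over frequency
#' equals the signal variance (Parseval).
#'
#' @param trace A `current_trace` or numeric vector (pA).
#' @param segment Segment length in samples (default 2^14).
#' @param fs Sample rate (Hz) for a bare numeric vector.
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return data.frame of class `noise_spectrum` with `freq` (Hz) and `psd`
#'   (pA^2/Hz); attributes `segment`, `n_avg`, `fs`.
#' @export
psd_welch <- function(trace, segment = 2^14, fs = NULL, overlap = 0.5) {
  x <- trace_samples(trace)
  fs <- trace_fs(trace, fs)
  n <- length(x)
  if (segment > n) stop("psd_welch: segment longer than trace")
  step <- max(1L, floor(segment * (1 - overlap)))
  starts <- seq(1L, n - segment + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segment) / (segment + 1)))  # Hann
  U <- sum(w^2)
  nf <- segment %/% 2
  acc <- numeric(nf + 1)
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    acc <- acc + Mod(X[seq_len(nf + 1)])^2
  }
  p <- acc / length(starts) / (fs * U)
  # one-sided: double all bins except DC (and Nyquist for even segment)
  p[2:nf] <- 2 * p[2:nf]
  out <- data.frame(freq = seq(0, nf) * fs / segment, psd = p)
  attr(out, "segment") <- segment
  attr(out, "n_avg") <- length(starts)
  attr(out, "fs") <- fs
  class(out) <- c("noise_spectrum", "data.frame")
  out
}

#' Noise SD over a stated bandwidth
#'
#' SD of the trace after low-passing to `cutoff` (4-pole Bessel, matching the
#' acquisition convention). If the trace is already band-limited at or below
#' the requested cutoff, the plain SD is returned.
#'
#' @param trace A `current_trace` or numeric vector.
#' @param cutoff Bandwidth (Hz); must not exceed the acquisition cutoff.
#' @param fs Sample rate (Hz) for a bare numeric vector.
#' @return sigma in pA.
#' @export
sigma_at_bandwidth <- function(trace, cutoff, fs = NULL) {
  x <- trace_samples(trace)
  fs <- trace_fs(trace, fs)
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("sigma_at_bandwidth: cutoff must be in (0, fs/2)")
  acq_cut <- if (inherits(trace, "current_trace") &&
                 trace$acquisition$filter_family != "none")
    trace$acquisition$cutoff else Inf
  if (cutoff > acq_cut * 1.0001)
    stop("sigma_at_bandwidth: cutoff exceeds the acquisition bandwidth")
  if (cutoff >= acq_cut * 0.9999) return(stats::sd(x))
  # mean-subtract (avoids the DC step response of the causal filter) and
  # discard the startup transient before measuring
  y <- apply_lowpass(x - mean(x), cutoff, fs)
  n0 <- min(length(y) %/% 4, ceiling(10 * fs / cutoff))
  stats::sd(y[(n0 + 1):length(y)])
}

#' Signal-to-noise ratio of the docking step
#'
#' SNR = (I_open - I_dock) / sigma.
#'
#' @param i_open Open-pore current (pA).
#' @param i_dock Docked-level current (pA).
#' @param sigma Current noise SD (pA), > 0.
#' @return Dimensionless SNR.
#' @export
snr <- function(i_open, i_dock, sigma) {
  if (any(sigma <= 0)) stop("snr: sigma must be positive")
  (i_open - i_dock) / sigma
}

#' Relative blockade of a current level
#'
#' 1 - I_level/I_open: the fraction of the open-pore current suppressed by
#' the occupying object (0.17 for the vertical docked sphere).
#'
#' @param i_level Level current (pA).
#' @param i_open Open-pore current (pA), non-zero.
#' @return Fractional blockade.
#' @export
blockade_fraction <- function(i_level, i_open) {
  if (any(i_open == 0)) stop("blockade_fraction: zero open-pore current")
  1 - i_level / i_open
}

#' Pink + white decomposition of a noise spectrum
#'
#' Least-squares fit of log10 S(f) to S(f) = A/f^alpha + B over a frequency
#' band (default 1 Hz - 1 kHz, where the excess 1/f noise lives).
#'
#' @param spectrum A `noise_spectrum` from [psd_welch()].
#' @param f_range Fit band (Hz).
#' @param alpha Fixed pink exponent, or NA to estimate it.
#' @return List with `pink_A`, `white_B`, `alpha`, and the `nls` fit.
#' @export
fit_noise_spectrum <- function(spectrum, f_range = c(1, 1000), alpha = 1) {
  stopifnot(inherits(spectrum, "noise_spectrum"))
  d <- spectrum[spectrum$freq >= f_range[1] & spectrum$freq <= f_range[2] &
                  spectrum$freq > 0, ]
  if (nrow(d) < 5) stop("fit_noise_spectrum: too few bins in the fit band")
  A0 <- max(stats::median(d$psd[seq_len(max(3, nrow(d) %/% 10))]) * d$freq[1],
            .Machine$double.eps)
  B0 <- stats::median(d$psd[d$freq > 0.5 * f_range[2]])
  est_alpha <- is.na(alpha)
  fml <- if (est_alpha) log10(psd) ~ log10(A / freq^al + B)
         else log10(psd) ~ log10(A / freq^alpha + B)
  start <- if (est_alpha) list(A = A0, B = B0, al = 1) else list(A = A0, B = B0)
  fit <- stats::nls(fml, data = d, start = start,
                    control = stats::nls.control(warnOnly = TRUE))
  cf <- stats::coef(fit)
  list(pink_A = unname(cf["A"]), white_B = unname(cf["B"]),
       alpha = if (est_alpha) unname(cf["al"]) else alpha, fit = fit)
}

#' Log-log slope of a spectrum over a band
#'
#' Least-squares slope of log10(PSD) vs log10(f); -alpha for pure 1/f^alpha
#' noise.
#'
#' @param spectrum A `noise_spectrum`.
#' @param f_range Band (Hz), default 10-1000 Hz.
#' @return Slope (dimensionless).
#' @export
psd_slope <- function(spectrum, f_range = c(10, 1000)) {
  d <- spectrum[spectrum$freq >= f_range[1] & spectrum$freq <= f_range[2] &
                  spectrum$psd > 0, ]
  unname(stats::coef(stats::lm(log10(psd) ~ log10(freq), data = d))[2])
}
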