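# Rendering of synthetic current traces: piecewise levels from the state
# path, Gaussian white + 1/f (pink) noise, causal low-pass filtering, and a
# voltage protocol that scales and signs the levels.

#' Noise model for trace synthesis
#'
#' Additive current noise with one-sided PSD S(f) = A / f^alpha + B:
#' a white floor `white_psd` = B (pA^2/Hz) plus low-frequency pink noise of
#' coefficient `pink_A` = A (pA^2) and exponent `alpha`. In NEOtrap
#' recordings the pink component reflects mechanical instability of the
#' docked sphere and dominates below ~1 kHz.
#'
#' @param white_psd White (thermal/shot) PSD level B, pA^2/Hz.
#' @param pink_A Pink coefficient A, pA^2 (PSD A/f^alpha).
#' @param alpha Pink exponent, in [0.5, 1.5].
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(white_psd = 0.00546, pink_A = 0.6, alpha = 1) {
  stopifnot(white_psd >= 0, pink_A >= 0, alpha >= 0.5, alpha <= 1.5)
  structure(list(white_psd = white_psd, pink_A = pink_A, alpha = alpha),
            class = "noise_model")
}

#' Acquisition settings
#'
#' @param sample_rate Sample rate (Hz).
#' @param cutoff Low-pass -3 dB cutoff (Hz); must be below Nyquist.
#' @param filter_family "bessel" (4-pole, default), "butterworth" or "none".
#' @param filter_order Filter order.
#' @return Object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(sample_rate = 125e3, cutoff = 10e3,
                             filter_family = "bessel", filter_order = 4) {
  stopifnot(sample_rate > 0, cutoff > 0)
  if (cutoff >= sample_rate / 2)
    stop("acquisition_spec: cutoff must be below the Nyquist frequency")
  structure(list(sample_rate = sample_rate, cutoff = cutoff,
                 filter_family = filter_family, filter_order = filter_order),
            class = "acquisition_spec")
}

#' Voltage protocol
#'
#' Piecewise-constant applied bias, e.g. the alternation between -100 mV and
#' +100 mV used to probe whether a docked sphere survives voltage inversion.
#'
#' @param duration_s Segment durations (s), positive.
#' @param voltage_mV Segment voltages (mV), recycled against durations.
#' @return data.frame of class `voltage_protocol`.
#' @export
voltage_protocol <- function(duration_s, voltage_mV) {
  n <- max(length(duration_s), length(voltage_mV))
  duration_s <- rep_len(duration_s, n); voltage_mV <- rep_len(voltage_mV, n)
  stopifnot(all(duration_s > 0))
  structure(data.frame(duration_s = duration_s, voltage_mV = voltage_mV),
            class = c("voltage_protocol", "data.frame"))
}

#' Alternating +/-V protocol
#' @param v_mV Bias magnitude (mV).
#' @param half_period_s Duration of each polarity segment (s).
#' @param n_cycles Number of +/- cycles.
#' @param start_positive Start with the positive segment.
#' @export
alternating_protocol <- function(v_mV = 100, half_period_s = 2, n_cycles = 4,
                                 start_positive = TRUE) {
  v <- rep(c(v_mV, -v_mV), n_cycles)
  if (!start_positive) v <- -v
  voltage_protocol(rep(half_period_s, 2 * n_cycles), v)
}

# deterministic-per-seed pink noise by spectral shaping: Gaussian random
# spectrum scaled to the one-sided target PSD A/f^alpha, Hermitian inverse FFT
synth_pink <- function(n, fs, A, alpha, seed) {
  if (A <= 0) return(numeric(n))
  m <- stats::nextn(n, 2)
  set.seed(as.integer(seed %% .Machine$integer.max))
  k <- seq_len(m %/% 2 - 1)
  f <- k * fs / m
  amp <- sqrt(A / f^alpha * fs * m / 2)
  X <- complex(real = stats::rnorm(length(k)), imaginary = stats::rnorm(length(k))) *
    (amp / sqrt(2))
  nyq <- sqrt(A / ((fs / 2)^alpha) * fs * m / 2) * stats::rnorm(1)
  spec <- c(0, X, nyq, Conj(rev(X)))
  x <- Re(stats::fft(spec, inverse = TRUE)) / m
  x[seq_len(n)]
}

#' Render a current trace from a state path
#'
#' Converts a telegraph state path into a uniformly sampled current trace:
#' each state's level (fraction of I0) is scaled by the instantaneous protocol
#' voltage relative to the scheme's reference bias (sign included), additive
#' white noise is drawn in the time domain and pink noise synthesized in the
#' frequency domain, and finally the causal acquisition low-pass is applied.
#'
#' @param path A `state_path` from [simulate_state_path()].
#' @param scheme The `kinetic_scheme` (levels); defaults to the path's scheme.
#' @param noise A `noise_model`.
#' @param acq An `acquisition_spec`.
#' @param protocol A `voltage_protocol`; defaults to the path's protocol.
#' @param seed Integer seed for the noise draws.
#' @return Object of class `current_trace`: list with `current` (pA),
#'   `time_step` (s), acquisition/noise/protocol/scheme metadata and seeds.
#' @export
render_trace <- function(path, scheme = attr(path, "scheme"),
                         noise = noise_model(), acq = acquisition_spec(),
                         protocol = attr(path, "protocol"), seed = 1) {
  stopifnot(inherits(path, "state_path"), inherits(acq, "acquisition_spec"))
  duration <- attr(path, "duration")
  fs <- acq$sample_rate
  n <- round(duration * fs)
  tt <- (seq_len(n) - 0.5) / fs

  lev <- state_level_frac(scheme)
  seg_of <- findInterval(tt, c(0, cumsum(path$t_end - path$t_start)),
                         rightmost.closed = TRUE)
  seg_of[seg_of > nrow(path)] <- nrow(path)
  base <- lev[path$state[seg_of]] * scheme$i0_pA

  pe <- cumsum(protocol$duration_s)
  vseg <- findInterval(tt, c(0, pe), rightmost.closed = TRUE)
  vseg[vseg > nrow(protocol)] <- nrow(protocol)
  vfac <- protocol$voltage_mV[vseg] / scheme$v_ref_mV
  x <- base * vfac

  if (noise$white_psd > 0) {
    set.seed(as.integer((seed + 1) %% .Machine$integer.max))
    x <- x + stats::rnorm(n, 0, sqrt(noise$white_psd * fs / 2))
  }
  if (noise$pink_A > 0)
    x <- x + synth_pink(n, fs, noise$pink_A, noise$alpha, seed + 2)

  x <- apply_lowpass(x, acq$cutoff, fs, acq$filter_family, acq$filter_order)

  structure(list(current = x, time_step = 1 / fs, duration = duration,
                 acquisition = acq, noise = noise, protocol = protocol,
                 scheme = scheme, seed = as.numeric(seed)),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("current_trace: %.6g s at %g kHz (%d samples), %s %g kHz filter\n",
              x$duration, x$acquisition$sample_rate / 1e3, length(x$current),
              x$acquisition$filter_family, x$acquisition$cutoff / 1e3))
  invisible(x)
}

#' Built-in generator presets
#'
#' Presets parameterised from the published NEOtrap operating points:
#' \describe{
#'   \item{vertical_avidin}{Avidin trapping by a vertically locked sphere at
#'     +100 mV: capture 7.7 /s, escape 11 /s, docked level 0.83 I0.}
#'   \item{horizontal_avidin}{Horizontally locked sphere: capture 3.85 /s
#'     (half the vertical), escape 2970 /s (270-fold the vertical), docked
#'     level 0.855 I0. Sampled at 50 kHz to resolve the ~0.3 ms dwells.}
#'   \item{uniform_avidin}{Uniformly cholesterol-functionalized sphere:
#'     trapping time constant 50 ms (escape 20 /s) at 100 mV.}
#'   \item{bare_docking}{Bare sphere under voltage inversions: docks at
#'     positive bias, is ejected at negative bias; elevated 1/f noise
#'     (sigma ~ 13 pA at 10 kHz).}
#'   \item{cholesterol_docking}{Cholesterol-functionalized sphere: stays
#'     docked through inversions; reduced 1/f noise (sigma ~ 8 pA).}
#'   \item{vertical_docking, horizontal_docking}{Two-level open/docked traces
#'     with the orientation-specific blockades (17% and 14.5%).}
#'   \item{open_pore}{Baseline-only trace (sigma ~ 7 pA).}
#' }
#'
#' @param preset Preset name.
#' @param seed Integer seed.
#' @param duration Trace duration (s); NULL for the preset default.
#' @return A `current_trace`.
#' @export
make_fixture <- function(preset, seed = 1, duration = NULL) {
  noise_chol <- noise_model(white_psd = 0.00546, pink_A = 0.6)
  noise_bare <- noise_model(white_psd = 0.00546, pink_A = 7.3)
  noise_open <- noise_model(white_psd = 0.0049,  pink_A = 0.1)
  acq25 <- acquisition_spec(sample_rate = 25e3, cutoff = 10e3)
  acq50 <- acquisition_spec(sample_rate = 50e3, cutoff = 10e3)

  p <- switch(preset,
    vertical_avidin = list(
      scheme = kinetic_scheme(docked_frac = 0.83, capture_rate = 7.7,
                              escape_rate = 11),
      noise = noise_chol, acq = acq25, dur = 600, init = "docked"),
    horizontal_avidin = list(
      scheme = kinetic_scheme(docked_frac = 0.855, capture_rate = 3.85,
                              escape_rate = 2970),
      noise = noise_chol, acq = acq50, dur = 300, init = "docked"),
    uniform_avidin = list(
      scheme = kinetic_scheme(docked_frac = 0.83, capture_rate = 7.7,
                              escape_rate = 20),
      noise = noise_chol, acq = acq25, dur = 300, init = "docked"),
    bare_docking = list(
      scheme = kinetic_scheme(docked_frac = 0.83, dock_rate = 2,
                              undock_rate = 0, undock_rate_neg = 50),
      noise = noise_bare, acq = acq25,
      protocol = alternating_protocol(100, 2, 4), init = "open"),
    cholesterol_docking = list(
      scheme = kinetic_scheme(docked_frac = 0.83, dock_rate = 2,
                              undock_rate = 0, undock_rate_neg = 0),
      noise = noise_chol, acq = acq25,
      protocol = alternating_protocol(100, 2, 4), init = "open"),
    vertical_docking = list(
      scheme = kinetic_scheme(docked_frac = 0.83, dock_rate = 1,
                              undock_rate = 1),
      noise = noise_chol, acq = acq25, dur = 20, init = "open"),
    horizontal_docking = list(
      scheme = kinetic_scheme(docked_frac = 0.855, dock_rate = 1,
                              undock_rate = 1),
      noise = noise_chol, acq = acq25, dur = 20, init = "open"),
    open_pore = list(
      scheme = kinetic_scheme(docked_frac = 0.83),
      noise = noise_open, acq = acq25, dur = 10, init = "open"),
    stop("make_fixture: unknown preset '", preset, "'")
  )

  protocol <- p$protocol
  if (is.null(protocol)) {
    dur <- if (!is.null(duration)) duration else p$dur
    protocol <- voltage_protocol(dur, 100)
  } else if (!is.null(duration)) {
    protocol$duration_s <- protocol$duration_s *
      duration / sum(protocol$duration_s)
  }
  path <- simulate_state_path(p$scheme, seed = seed, protocol = protocol,
                              initial_state = p$init)
  tr <- render_trace(path, scheme = p$scheme, noise = p$noise, acq = p$acq,
                     protocol = protocol, seed = seed + 7)
  tr$preset <- preset
  attr(tr, "state_path") <- path
  tr
}
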