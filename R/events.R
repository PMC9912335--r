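# Event detection and dwell-time statistics for NEOtrap current traces.
#
# Trapping events are downward excursions from the docked baseline. Detection
# uses a two-threshold (hysteresis) scheme standard in nanopore dwell
# analysis: an event opens when the current crosses baseline - k*sigma and
# closes when it re-crosses baseline - (k/2)*sigma. Dwell times of a
# Poissonian escape process are exponential, for which the maximum-likelihood
# time constant is the sample mean; uncertainties come from bootstrap
# resampling.

trace_samples <- function(trace) {
  if (inherits(trace, "current_trace")) trace$current else as.numeric(trace)
}

trace_fs <- function(trace, fs = NULL) {
  if (inherits(trace, "current_trace")) trace$acquisition$sample_rate
  else if (!is.null(fs)) fs
  else stop("sample rate required for a bare numeric trace")
}

#' Find current levels from the all-points histogram
#'
#' Kernel-smooths the all-points current histogram and picks its modes, the
#' standard way the open, attempted-docking, docked, and trapped levels are
#' read off a recording. Each mode is refined to the mean of the samples
#' assigned to it (nearest mode), which is unbiased for symmetric noise.
#'
#' @param trace A `current_trace` or numeric vector (pA).
#' @param min_weight Minimum fraction of samples a level must hold.
#' @param bw Kernel bandwidth (pA) passed to [stats::density()]; default
#'   "nrd0".
#' @return Numeric vector of level means (pA), sorted descending.
#' @export
find_levels <- function(trace, min_weight = 0.02, bw = "nrd0") {
  x <- trace_samples(trace)
  if (!length(x)) stop("find_levels: empty trace")
  if (stats::sd(x) == 0) return(x[1])
  d <- stats::density(x, bw = bw, n = 2048)
  y <- d$y
  pk <- which(diff(sign(diff(y))) == -2) + 1
  if (!length(pk)) pk <- which.max(y)
  modes <- d$x[pk]
  # assign samples to nearest candidate mode, refine, and weigh
  idx <- findInterval(x, c(-Inf, (modes[-1] + modes[-length(modes)]) / 2, Inf))
  w <- tabulate(idx, nbins = length(modes)) / length(x)
  keep <- w >= min_weight
  if (!any(keep)) keep[which.max(w)] <- TRUE
  means <- vapply(which(keep), function(k) mean(x[idx == k]), numeric(1))
  sort(means, decreasing = TRUE)
}

#' Estimate baseline level and noise SD of a trace
#'
#' Baseline = highest histogram mode (the unoccupied level); sigma = robust
#' (MAD-based) SD of the samples within +/- 4 initial-sigma of it.
#'
#' @param trace A `current_trace` or numeric vector.
#' @return List with `baseline` (pA) and `sigma` (pA).
#' @export
estimate_baseline <- function(trace) {
  x <- trace_samples(trace)
  lv <- find_levels(trace)
  base <- lv[1]
  s0 <- stats::mad(x)
  near <- x[abs(x - base) < 4 * max(s0, .Machine$double.eps)]
  s <- stats::mad(near, center = base)
  if (!is.finite(s) || s == 0) s <- stats::sd(near)
  list(baseline = base, sigma = s)
}

#' Detect blockade events by two-threshold crossing
#'
#' @param trace A `current_trace` or numeric vector (pA).
#' @param baseline Baseline current (pA); estimated if NULL.
#' @param sigma Baseline noise SD (pA); estimated if NULL.
#' @param k Threshold multiplier: events open at `baseline - k*sigma` and
#'   close (hysteresis) at `baseline - k/2*sigma`. Must be > 0.
#' @param min_dwell_samples Events shorter than this many samples are
#'   discarded (detection dead time).
#' @param fs Sample rate (Hz), required for a bare numeric trace.
#' @return data.frame of class `event_table`: `start`, `end` (sample indices),
#'   `dwell_s`, `mean_pA`, `rel_blockade`, `quality_ok` (dwell comfortably
#'   above the filter rise time). Attributes: `baseline`, `sigma`, `k`,
#'   `total_time`, `unoccupied_time`, `min_dwell_s`, `fs`. Events truncated by
#'   the trace boundaries are dropped.
#' @export
detect_events <- function(trace, baseline = NULL, sigma = NULL, k = 5,
                          min_dwell_samples = 3, fs = NULL) {
  if (k <= 0) stop("detect_events: threshold multiplier k must be positive")
  x <- trace_samples(trace)
  fs <- trace_fs(trace, fs)
  if (is.null(baseline) || is.null(sigma)) {
    est <- estimate_baseline(trace)
    if (is.null(baseline)) baseline <- est$baseline
    if (is.null(sigma)) sigma <- est$sigma
  }
  thr_deep <- baseline - k * sigma
  thr_re <- baseline - k / 2 * sigma

  below_re <- x < thr_re
  r <- rle(below_re)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)

  ev_start <- integer(0); ev_end <- integer(0)
  if (length(runs)) {
    deep <- x < thr_deep
    cs <- cumsum(deep)
    s <- starts[runs]; e <- ends[runs]
    ndeep <- cs[e] - cs[s] + deep[s]
    hit <- ndeep > 0
    s <- s[hit]; e <- e[hit]
    if (length(s)) {
      # event opens at the first deep crossing inside the run
      first_deep <- vapply(seq_along(s),
                           function(i) s[i] + which.max(deep[s[i]:e[i]]) - 1L,
                           integer(1))
      ev_start <- first_deep; ev_end <- e
    }
  }

  n <- length(x)
  keep <- logical(length(ev_start))
  if (length(ev_start))
    keep <- ev_start > 1L & ev_end < n &
      (ev_end - ev_start + 1L) >= min_dwell_samples
  ev_start <- ev_start[keep]; ev_end <- ev_end[keep]

  dwell <- (ev_end - ev_start + 1L) / fs
  mean_pA <- vapply(seq_along(ev_start),
                    function(i) mean(x[ev_start[i]:ev_end[i]]), numeric(1))
  cutoff <- if (inherits(trace, "current_trace")) trace$acquisition$cutoff else NA
  rise <- if (is.finite(cutoff)) filter_rise_time(cutoff) else 0
  out <- data.frame(start = ev_start, end = ev_end, dwell_s = dwell,
                    mean_pA = mean_pA,
                    rel_blockade = 1 - mean_pA / baseline,
                    quality_ok = dwell >= 3 * rise)
  attr(out, "baseline") <- baseline
  attr(out, "sigma") <- sigma
  attr(out, "k") <- k
  attr(out, "fs") <- fs
  attr(out, "min_dwell_s") <- min_dwell_samples / fs
  attr(out, "total_time") <- n / fs
  attr(out, "unoccupied_time") <- n / fs - sum(dwell)
  class(out) <- c("event_table", "data.frame")
  out
}

#' Exponential maximum-likelihood fit of dwell times
#'
#' For exponential dwells the MLE of the time constant is the sample mean;
#' with a detection dead time `t_min` (events shorter than t_min are never
#' seen) the observed dwells are left-truncated and, by memorylessness, the
#' MLE becomes mean(dwells) - t_min.
#'
#' @param dwells Numeric vector of dwell times (s), n >= 1.
#' @param t_min Detection dead time (s), default 0.
#' @param bootstrap Number of bootstrap resamples for the SD (0 to skip;
#'   needs n >= 2).
#' @param seed Seed for the bootstrap.
#' @return Object of class `dwell_fit`: `tau` (s), `rate` (1/s),
#'   `bootstrap_sd` (SD of tau), `n`, `method`.
#' @export
fit_dwell_exponential <- function(dwells, t_min = 0, bootstrap = 0, seed = 1) {
  if (!length(dwells)) stop("fit_dwell_exponential: empty dwell set")
  stopifnot(all(dwells >= 0))
  tau <- mean(dwells) - t_min
  if (tau <= 0) stop("fit_dwell_exponential: non-positive tau after dead-time correction")
  bsd <- NA_real_
  if (bootstrap > 0)
    bsd <- bootstrap_sd(dwells, function(d) mean(d) - t_min, B = bootstrap,
                        seed = seed)
  structure(list(tau = tau, rate = 1 / tau, bootstrap_sd = bsd,
                 n = length(dwells), method = "exponential-MLE"),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("tau = %.4g s (rate %.4g /s), n = %d, bootstrap SD = %.3g s\n",
              x$tau, x$rate, x$n, x$bootstrap_sd))
  invisible(x)
}

#' Bootstrap standard deviation of an estimator
#'
#' @param x Numeric sample (n >= 2).
#' @param estimator Function of a numeric vector returning a scalar.
#' @param B Number of resamples with replacement (>= 100).
#' @param seed Integer seed.
#' @return Bootstrap SD (scalar).
#' @export
bootstrap_sd <- function(x, estimator = mean, B = 1000, seed = 1) {
  if (length(x) < 2) stop("bootstrap_sd: need at least two observations")
  if (B < 100) stop("bootstrap_sd: B must be >= 100")
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- length(x)
  stats::sd(vapply(seq_len(B),
                   function(b) estimator(x[sample.int(n, n, replace = TRUE)]),
                   numeric(1)))
}

#' Capture and escape rates from an event table
#'
#' Capture rate = number of events per unit unoccupied (searchable) time, the
#' waiting-time reading of "molecules/s"; escape rate = inverse MLE dwell
#' time. With `correct_min_dwell`, the event count is corrected for events
#' missed below the detection dead time using the fitted exponential
#' (divide by exp(-t_min/tau)), and tau is dead-time corrected. The default
#' is no correction: a causal low-pass stretches each pulse by roughly its
#' rise time, which offsets the dead-time loss on band-limited recordings;
#' enable the correction for unfiltered data with a hard dead time.
#'
#' @param events An `event_table` from [detect_events()].
#' @param bootstrap Bootstrap resamples for the SDs.
#' @param seed Seed for the bootstrap.
#' @param correct_min_dwell Apply the missed-event correction (default FALSE).
#' @param normalization "unoccupied" (default) or "total" time for the
#'   capture rate.
#' @return Object of class `rate_estimates`: `capture_rate`, `escape_rate`
#'   (1/s), `capture_sd`, `escape_sd`, `n_events`, `dwell_fit`.
#' @export
capture_rate <- function(events, bootstrap = 500, seed = 1,
                         correct_min_dwell = FALSE,
                         normalization = c("unoccupied", "total")) {
  stopifnot(inherits(events, "event_table"))
  normalization <- match.arg(normalization)
  n <- nrow(events)
  if (n < 1) stop("capture_rate: no events")
  t_search <- if (normalization == "unoccupied") attr(events, "unoccupied_time")
              else attr(events, "total_time")
  if (t_search <= 0) stop("capture_rate: zero searchable time")
  t_min <- if (correct_min_dwell) attr(events, "min_dwell_s") else 0
  fit <- fit_dwell_exponential(events$dwell_s, t_min = t_min,
                               bootstrap = bootstrap, seed = seed)
  miss_corr <- if (correct_min_dwell) exp(-t_min / fit$tau) else 1
  cap <- n / miss_corr / t_search
  cap_sd <- sqrt(n) / miss_corr / t_search  # Poisson counting
  esc_sd <- if (is.finite(fit$bootstrap_sd)) fit$bootstrap_sd / fit$tau^2
            else NA_real_
  structure(list(capture_rate = cap, escape_rate = fit$rate,
                 capture_sd = cap_sd, escape_sd = esc_sd,
                 n_events = n, dwell_fit = fit,
                 normalization = normalization),
            class = "rate_estimates")
}

#' @export
print.rate_estimates <- function(x, ...) {
  cat(sprintf("capture %.4g +/- %.2g /s, escape %.4g +/- %.2g /s (n = %d)\n",
              x$capture_rate, x$capture_sd, x$escape_rate, x$escape_sd,
              x$n_events))
  invisible(x)
}

#' Dwell-time / blockade scatter of an event table
#'
#' One point per event, relative blockade measured against the docked
#' baseline; `quality_ok` flags events long enough for full amplitude
#' resolution (dwell at least three filter rise times).
#'
#' @param events An `event_table`.
#' @return data.frame with `dwell_s`, `rel_blockade`, `quality_ok`.
#' @export
event_scatter <- function(events) {
  stopifnot(inherits(events, "event_table"))
  if (!nrow(events)) stop("event_scatter: no events")
  events[, c("dwell_s", "rel_blockade", "quality_ok")]
}
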