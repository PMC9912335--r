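test_that("find_levels recovers square-wave and noisy mixture levels", {
  # noise-free two-level square wave
  x <- rep(c(100, 80), each = 5000, times = 20)
  lv <- find_levels(x)
  expect_equal(lv, c(100, 80), tolerance = 1e-9)

  # Gaussian noise sigma = 2 on the same levels, 1e6 samples: means to 0.1 pA
  set.seed(21)
  xn <- rep(c(100, 80), each = 5000, times = 100) + rnorm(1e6, 0, 2)
  lvn <- find_levels(xn)
  expect_equal(length(lvn), 2)
  expect_lt(abs(lvn[1] - 100), 0.1)
  expect_lt(abs(lvn[2] - 80), 0.1)

  # constant level: a single mode
  expect_equal(find_levels(rep(42, 1000)), 42)
  expect_error(find_levels(numeric(0)), "empty")
})

test_that("detector finds rectangular dips exactly and respects the threshold", {
  tr <- square_dip_trace()
  ev <- detect_events(tr$x, baseline = 1000, sigma = 5, fs = tr$fs)
  expect_equal(nrow(ev), 3)
  expect_equal(ev$dwell_s, c(0.05, 0.02, 0.1), tolerance = 1e-9)
  expect_equal(ev$mean_pA, rep(800, 3))
  expect_equal(ev$rel_blockade, rep(0.2, 3), tolerance = 1e-12)

  # noise well below half the dip depth: still exactly 3 events
  set.seed(4)
  xn <- tr$x + rnorm(tr$n, 0, 8)
  evn <- detect_events(xn, baseline = 1000, sigma = 8, fs = tr$fs)
  expect_equal(nrow(evn), 3)
  expect_equal(evn$dwell_s, c(0.05, 0.02, 0.1), tolerance = 0.05)

  # dip shallower than k*sigma: no events
  ev0 <- detect_events(tr$x, baseline = 1000, sigma = 50, fs = tr$fs)
  expect_equal(nrow(ev0), 0)

  expect_error(detect_events(tr$x, baseline = 1000, sigma = 5, k = 0,
                             fs = tr$fs), "positive")
})

test_that("noise-free detection equals the generator's state path", {
  sch <- kinetic_scheme(i0_pA = 1000, capture_rate = 10, escape_rate = 40)
  p <- simulate_state_path(sch, duration = 30, seed = 8)
  acq <- acquisition_spec(sample_rate = 50e3, cutoff = 20e3,
                          filter_family = "none")
  tr <- render_trace(p, noise = noise_model(0, 0), acq = acq, seed = 1)
  base <- 1000 * sch$docked_frac
  ev <- detect_events(tr, baseline = base, sigma = base * 0.01,
                      min_dwell_samples = 1)
  d_true <- state_dwells(p, "trapped")
  # interior sojourns one-to-one, dwell within one sample
  expect_equal(nrow(ev), length(d_true))
  expect_lt(max(abs(sort(ev$dwell_s) - sort(d_true))), 2 / 50e3)
  # scatter equals ground truth: blockade = 1 - trapped/docked
  sc <- event_scatter(ev)
  expect_equal(unique(round(sc$rel_blockade, 9)),
               round(1 - sch$trapped_frac, 9))
})

test_that("events truncated by the trace boundaries are excluded", {
  fs <- 1e4
  x <- rep(1000, 3e4)
  x[1:500] <- 800           # cut at start
  x[10000:10500] <- 800     # interior
  x[29500:30000] <- 800     # cut at end
  ev <- detect_events(x, baseline = 1000, sigma = 5, fs = fs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, 10000)
})

test_that("exponential MLE equals the sample mean and handles dead time", {
  expect_equal(fit_dwell_exponential(c(1, 1, 1))$tau, 1)
  set.seed(31)
  d <- rexp(5000, 11)
  fit <- fit_dwell_exponential(d)
  expect_equal(fit$tau, mean(d))  # MLE identity, machine precision
  se <- (1 / 11) / sqrt(5000)
  expect_lt(abs(fit$tau - 1 / 11), 3 * se)
  # left-truncated sample: mean - t_min restores tau
  tmin <- 0.05
  dt <- d[d > tmin]
  fit_t <- fit_dwell_exponential(dt, t_min = tmin)
  expect_lt(abs(fit_t$tau - 1 / 11), 3 * (1 / 11) / sqrt(length(dt)))
  expect_error(fit_dwell_exponential(numeric(0)), "empty")
})

test_that("bootstrap SD matches the analytic standard error of tau", {
  expect_equal(bootstrap_sd(rep(2, 50), mean, B = 200, seed = 1), 0)
  set.seed(17)
  d <- rexp(1000, 5)
  bsd <- bootstrap_sd(d, mean, B = 1000, seed = 2)
  expect_equal(bsd, 0.2 / sqrt(1000), tolerance = 0.15)
  # doubling B is stable to < 5%
  bsd2 <- bootstrap_sd(d, mean, B = 2000, seed = 3)
  expect_lt(abs(bsd2 - bsd) / bsd, 0.05)
  expect_error(bootstrap_sd(3, mean), "two")
  expect_error(bootstrap_sd(d, mean, B = 50), "100")
})

test_that("capture rate is events per unoccupied time with bootstrap SDs", {
  # 10 events of 0.1 s in a 2 s trace: 1 s unoccupied -> 10 /s
  fs <- 1e4
  x <- rep(1000, 2 * fs)
  for (k in 0:9) x[(k * 2000 + 500):(k * 2000 + 1499)] <- 700
  ev <- detect_events(x, baseline = 1000, sigma = 5, fs = fs)
  expect_equal(nrow(ev), 10)
  expect_equal(attr(ev, "unoccupied_time"), 1, tolerance = 1e-3)
  rt <- capture_rate(ev, bootstrap = 200, correct_min_dwell = FALSE)
  expect_equal(rt$capture_rate, 10, tolerance = 0.01)
  expect_equal(rt$escape_rate, 10, tolerance = 0.01)
  rt_tot <- capture_rate(ev, bootstrap = 200, correct_min_dwell = FALSE,
                         normalization = "total")
  expect_equal(rt_tot$capture_rate, 5, tolerance = 0.01)
})

test_that("rates are recovered from synthetic traces across the escape-rate range", {
  # parameter-recovery at two escape rates spanning the trapping contrast;
  # expected event counts >= 500, dwells above the filter rise time
  cases <- list(list(ke = 11, dur = 90, fs = 25e3),
                list(ke = 1500, dur = 60, fs = 50e3))
  for (cs in cases) {
    sch <- kinetic_scheme(capture_rate = 10, escape_rate = cs$ke)
    p <- simulate_state_path(sch, duration = cs$dur, seed = 13)
    acq <- acquisition_spec(sample_rate = cs$fs, cutoff = 10e3)
    tr <- render_trace(p, noise = noise_model(0.005, 0.6), acq = acq, seed = 14)
    ev <- detect_events(tr)
    rt <- capture_rate(ev, bootstrap = 200, seed = 1)
    expect_gt(rt$n_events, 400)
    expect_lt(abs(rt$capture_rate - 10) / 10, 0.1)
    expect_lt(abs(rt$escape_rate - cs$ke) / cs$ke, 0.1)
  }
})

test_that("short filtered events are flagged by the dwell-quality column", {
  sch <- kinetic_scheme(capture_rate = 20, escape_rate = 3000)
  p <- simulate_state_path(sch, duration = 20, seed = 23)
  acq <- acquisition_spec(sample_rate = 50e3, cutoff = 10e3)
  tr <- render_trace(p, noise = noise_model(0.002, 0), acq = acq, seed = 2)
  ev <- detect_events(tr)
  short <- ev[!ev$quality_ok, ]
  long <- ev[ev$quality_ok & ev$dwell_s > 5 * neotrap:::filter_rise_time(10e3), ]
  expect_gt(nrow(short), 0)
  # amplitude of very short events is attenuated vs the long-event amplitude
  expect_lt(mean(short$rel_blockade), mean(long$rel_blockade))
})
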