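test_that("state paths are reproducible and respect the kinetic scheme", {
  sch <- kinetic_scheme(capture_rate = 5, escape_rate = 50)
  p1 <- simulate_state_path(sch, duration = 10, seed = 42)
  p2 <- simulate_state_path(sch, duration = 10, seed = 42)
  expect_identical(p1, p2)
  p3 <- simulate_state_path(sch, duration = 10, seed = 43)
  expect_false(identical(p1$t_start, p3$t_start))

  # zero capture rate: never trapped
  sch0 <- kinetic_scheme(capture_rate = 0, escape_rate = 50)
  p0 <- simulate_state_path(sch0, duration = 10, seed = 1)
  expect_false("trapped" %in% p0$state_name)

  # all-zero rates: stays in initial state
  schz <- kinetic_scheme()
  pz <- simulate_state_path(schz, duration = 5, seed = 1, initial_state = "docked")
  expect_equal(nrow(pz), 1)
  expect_equal(pz$state_name, "docked")
})

test_that("trapped dwell times are exponential with the right mean", {
  sch <- kinetic_scheme(capture_rate = 200, escape_rate = 10)
  p <- simulate_state_path(sch, duration = 1100, seed = 7)
  d <- state_dwells(p, "trapped")
  expect_gt(length(d), 5000)
  # sample mean within 3 SE of 1/k_e
  se <- 0.1 / sqrt(length(d))
  expect_lt(abs(mean(d) - 0.1), 3 * se)
  # KS test against the exponential CDF at the 1% level
  ks <- suppressWarnings(ks.test(d[1:5000], pexp, rate = 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("long-run trapped occupancy matches the two-state balance", {
  kc <- 20; ke <- 30
  sch <- kinetic_scheme(capture_rate = kc, escape_rate = ke)
  p <- simulate_state_path(sch, duration = 600, seed = 3)
  occ <- sum((p$t_end - p$t_start)[p$state_name == "trapped"]) / 600
  occ_th <- kc / (kc + ke)
  n_soj <- sum(p$state_name == "trapped")
  se <- occ_th * (1 - occ_th) / sqrt(n_soj)  # crude sojourn-count SE
  expect_lt(abs(occ - occ_th), 3 * se)
})

test_that("noise-free unfiltered rendering equals the piecewise levels exactly", {
  sch <- kinetic_scheme(i0_pA = 1000, docked_frac = 0.8, trapped_frac = 0.75,
                        capture_rate = 5, escape_rate = 20)
  p <- simulate_state_path(sch, duration = 2, seed = 5)
  acq <- acquisition_spec(sample_rate = 10e3, cutoff = 4e3,
                          filter_family = "none")
  tr <- render_trace(p, noise = noise_model(0, 0), acq = acq, seed = 1)
  expect_equal(length(tr$current), 2 * 10e3)
  expect_equal(sort(unique(tr$current)), c(600, 800), tolerance = 1e-12)
  # level at a time known to be docked from the path
  i_mid <- round(mean(c(p$t_start[1], p$t_end[1])) * 10e3)
  expect_equal(tr$current[i_mid], 800)
})

test_that("rendered noise has the requested white SD and pink spectral slope", {
  sch <- kinetic_scheme()
  p <- simulate_state_path(sch, duration = 8, seed = 1)
  acq <- acquisition_spec(sample_rate = 125e3, cutoff = 50e3,
                          filter_family = "none")
  B <- 0.004
  trw <- render_trace(p, noise = noise_model(white_psd = B, pink_A = 0),
                      acq = acq, seed = 2)
  sd_target <- sqrt(B * 125e3 / 2)
  expect_equal(sd(trw$current), sd_target, tolerance = 0.05)

  trp <- render_trace(p, noise = noise_model(white_psd = 0, pink_A = 1),
                      acq = acq, seed = 2)
  sp <- psd_welch(trp$current - mean(trp$current), fs = 125e3)
  expect_equal(psd_slope(sp, c(10, 1000)), -1, tolerance = 0.1)
})

test_that("the acquisition filter reduces white sigma by the analytic bandwidth ratio", {
  n <- 2^20; fs <- 125e3
  set.seed(9)
  x <- rnorm(n)
  y <- neotrap:::apply_lowpass(x, 10e3, fs)
  enbw <- neotrap:::filter_enbw(10e3, fs)
  ratio_th <- sqrt(enbw / (fs / 2))
  expect_equal(sd(y[1e4:n]) / sd(x), ratio_th, tolerance = 0.05)
})

test_that("identical inputs and seed give bit-identical traces", {
  t1 <- make_fixture("vertical_avidin", seed = 5, duration = 3)
  t2 <- make_fixture("vertical_avidin", seed = 5, duration = 3)
  expect_identical(t1$current, t2$current)
})

test_that("docking presets respond to voltage inversion as designed", {
  # bare sphere: ejected at negative bias; level tracks bias sign
  trb <- make_fixture("bare_docking", seed = 2)
  pathb <- attr(trb, "state_path")
  protb <- trb$protocol
  tneg <- cumsum(protb$duration_s)[1] + 0.5  # inside first negative segment
  st <- pathb$state_name[findInterval(tneg, pathb$t_start)]
  expect_equal(st, "open")

  # cholesterol sphere: once docked, stays docked through inversions
  trc <- make_fixture("cholesterol_docking", seed = 2)
  pathc <- attr(trc, "state_path")
  t_dock <- pathc$t_start[match("docked", pathc$state_name)]
  after <- pathc$state_name[pathc$t_start >= t_dock]
  expect_true(all(after == "docked"))
})

test_that("unknown preset errors cleanly", {
  expect_error(make_fixture("sideways_avidin"), "unknown preset")
})
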