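test_that("boxcar smoothing is NaN-aware, centred and edge-truncated", {
  expect_equal(boxcar(rep(3.5, 50), 2, 0.1), rep(3.5, 50))
  x <- rep(0, 21); x[11] <- 1
  sm <- boxcar(x, 0.5, 0.1)  # 5-sample window
  expect_equal(sm[9:13], rep(0.2, 5))
  expect_equal(sm[8], 0)
  set.seed(3)
  x <- stats::rnorm(200)
  x[sample(200, 30)] <- NaN
  for (w in c(3, 8, 25))
    expect_equal(boxcar(x, w * 0.1, 0.1), oracle_boxcar(x, w))
})

test_that("previous-neighbour resampling matches the linear-scan oracle", {
  expect_equal(
    resample_previous_neighbour(c(1, 2, 3), c(0, 1, 2), 1.55), 2)
  expect_true(is.na(resample_previous_neighbour(c(1, 2), c(1, 2), 0.5)))
  set.seed(8)
  ts <- sort(stats::runif(60, 0, 30))
  v <- stats::rnorm(60)
  grid <- seq(0, 30, 0.1)
  expect_equal(resample_previous_neighbour(v, ts, grid),
               oracle_prev_neighbour(v, ts, grid))
})

test_that("dF/F handles constant, degenerate and invariance cases", {
  tt <- seq(0, 300, 1 / 1.5)
  rec <- data.frame(volume_t_s = tt, F_cell = 120, F_background = 20)
  d <- compute_dff(rec)
  expect_true(all(abs(d$dff[is.finite(d$dff)]) < 1e-12))
  # cell equal to background: F_actual = 0 everywhere -> undefined
  rec0 <- data.frame(volume_t_s = tt, F_cell = 20, F_background = 20)
  expect_error(compute_dff(rec0), "undefined")
  # invariance to common gain and offset on both channels
  set.seed(4)
  f <- 100 + 30 * sin(tt / 20) + stats::rnorm(length(tt))
  rec1 <- data.frame(volume_t_s = tt, F_cell = f + 25, F_background = 25)
  rec2 <- data.frame(volume_t_s = tt, F_cell = 3.7 * (f + 25) + 11,
                     F_background = 3.7 * 25 + 11)
  expect_equal(compute_dff(rec1)$dff, compute_dff(rec2)$dff,
               tolerance = 1e-9)
})

test_that("stimulation masking excludes 105 s from the baseline", {
  tt <- seq(0, 1200, 1 / 1.5)
  f <- rep(100, length(tt))
  stim <- c(300, 600)
  # large artefact after each stimulation; masking must keep F0 at 100
  for (on in stim) f[tt >= on & tt < on + 105] <- 400
  rec <- data.frame(volume_t_s = tt, F_cell = f + 20, F_background = 20)
  d <- compute_dff(rec, window_s = 1200, stim_onsets = stim)
  unmasked <- !d$stim_mask & is.finite(d$dff)
  expect_lt(max(abs(d$dff[unmasked])), 1e-9)
  expect_true(any(d$stim_mask))
  # without masking the artefact contaminates the baseline
  d2 <- compute_dff(rec, window_s = 1200)
  expect_gt(max(abs(d2$dff[!d2$stim_mask & is.finite(d2$dff)])), 0.01)
})

test_that("dF/F averages to ~0 over a full baseline window by construction", {
  set.seed(12)
  tt <- seq(0, 3600, 1 / 1.5)
  f <- 100 + cumsum(stats::rnorm(length(tt), 0, 0.3))
  rec <- data.frame(volume_t_s = tt, F_cell = f + 20, F_background = 20)
  d <- compute_dff(rec, window_s = 1200)
  mid <- d$t_s >= 1200 & d$t_s <= 2400
  expect_lt(abs(mean(d$dff[mid], na.rm = TRUE)), 0.02)
})

test_that("triggered averages equal the double-loop oracle", {
  t <- seq(0, 100, 0.1)
  # constant trace: mean constant, sem zero
  ens <- triggered_average(rep(2, length(t)), t, c(30, 50, 70), 5)
  expect_equal(ens$mean, rep(2, length(ens$rel_t)))
  expect_equal(ens$sem, rep(0, length(ens$rel_t)))
  # a return transition 20 s after the trigger truncates that trace
  x <- seq_along(t) * 0.01
  ens2 <- triggered_average(x, t, 40, 30, exclusion_times = 60)
  expect_true(all(is.na(ens2$traces[1, ens2$rel_t >= 20])))
  expect_true(all(is.finite(ens2$traces[1, ens2$rel_t < 20])))
  # random events vs the loop oracle, exactly
  set.seed(21)
  x <- stats::rnorm(length(t))
  ev <- sort(stats::runif(8, 5, 95))
  excl <- sort(stats::runif(10, 0, 100))
  got <- triggered_average(x, t, ev, 8, exclusion_times = excl)
  want <- oracle_triggered(x, t, ev, 8, excl)
  expect_equal(got$mean, want$mean, tolerance = 1e-12)
  expect_equal(got$sem, want$sem, tolerance = 1e-12)
  expect_equal(got$n, want$n)
  # with exclusions the sample count never grows with relative time
  post <- got$n[got$rel_t >= 0]
  expect_true(all(diff(post) <= 0))
  expect_error(triggered_average(x, t, 500, 5), "zero usable events")
})

test_that("cross-correlation peaks at the documented lag convention", {
  t <- seq(0, 200, 0.1)
  a <- sin(t / 5) + 0.1 * cos(t / 3)
  cc <- cross_correlate(a, a, 0.1, 10)
  expect_equal(cc$lag_s[which.max(cc$r)], 0)
  expect_equal(max(cc$r), 1)
  # b delayed by 3 s: peak at +3 s
  b <- c(rep(NA, 30), a[seq_len(length(a) - 30)])
  cc2 <- cross_correlate(a, b, 0.1, 10)
  expect_equal(cc2$lag_s[which.max(cc2$r)], 3)
  expect_error(cross_correlate(a[1:5], a[1:5], 0.1, 0.2), "10 overlapping")
  # common latent + independent noise on two cells: zero-lag peak
  set.seed(31)
  lat <- stats::filter(stats::rnorm(length(t)), rep(1, 50) / 50,
                       sides = 2)
  c1 <- as.numeric(lat) + stats::rnorm(length(t), 0, 0.05)
  c2 <- as.numeric(lat) + stats::rnorm(length(t), 0, 0.05)
  cc3 <- cross_correlate(c1, c2, 0.1, 5)
  expect_equal(cc3$lag_s[which.max(cc3$r)], 0, tolerance = 0.3)
})

test_that("slope to threshold follows the zero-crossing definition", {
  dt <- 0.1
  t <- seq(0, 130, dt)
  # piecewise linear: fall to -0.1 at t=20, rise crossing 0 at t=65,
  # reaching 0.35 at the endpoint t=110 (bend complete at 113.3)
  x <- numeric(length(t))
  x[t <= 20] <- -0.1 * (t[t <= 20] / 20)
  seg2 <- t > 20 & t <= 65
  x[seg2] <- -0.1 + 0.1 * (t[seg2] - 20) / 45
  seg3 <- t > 65
  x[seg3] <- 0.35 * (t[seg3] - 65) / 45
  d <- data.frame(t_s = t, dff = x)
  r <- slope_to_threshold(d, ovulation_start_s = 5, bend_complete_s = 113.3)
  expect_true(r$defined)
  expect_equal(r$slope, 0.35 / 45, tolerance = 0.01)
  expect_equal(r$t_start, 65, tolerance = 0.2)
  # flat-at-zero signal after the minimum: slope 0
  d0 <- data.frame(t_s = t, dff = rep(0, length(t)))
  r0 <- slope_to_threshold(d0, 5, 113.3)
  expect_equal(r0$slope, 0)
  # never reaching zero: undefined and flagged
  dn <- data.frame(t_s = t, dff = rep(-0.2, length(t)))
  rn <- slope_to_threshold(dn, 5, 113.3)
  expect_false(rn$defined)
  expect_true(is.na(rn$slope))
})

test_that("stimulation binning uses the documented seven-bin edges", {
  t <- seq(0, 200, 0.1)
  mk <- function(peak) {
    x <- numeric(length(t))
    x[t >= 52 & t <= 52.4] <- peak   # inside the 1-3 s response window
    x
  }
  for (case in list(c(0.01, 1), c(0.60, 7), c(0.30, 4),
                    c(0.02, 2), c(0.519, 6), c(0.52, 7))) {
    d <- data.frame(t_s = t, dff = mk(case[1]))
    sb <- stim_response_bins(d, 51)
    expect_equal(sb$bin, case[2])
  }
  # behavioural delta is post minus pre
  beh <- data.frame(t_s = t, value = ifelse(t > 51.01, 2, 5))
  sb <- stim_response_bins(data.frame(t_s = t, dff = mk(0.3)), 51,
                           behaviour = beh)
  expect_equal(sb$behaviour_delta, 2 - 5)
  # stimulation too close to the end of the recording is skipped
  sb2 <- stim_response_bins(data.frame(t_s = t, dff = mk(0.3)),
                            c(51, 199))
  expect_equal(nrow(sb2), 1)
  expect_equal(attr(sb2, "n_skipped"), 1)
})

test_that("the full pipeline recovers latent ramp timing", {
  tt <- seq(0, 1800, 0.5)
  A <- 0.35 * pmax(0, 1 - abs(tt - 835) / 35)  # triangular peak at 835 s
  latent <- data.frame(t_s = tt, A = A)
  rec <- simulate_fluorescence(latent, fluorescence_sim_spec(), seed = 5)
  d <- compute_dff(rec, window_s = 1200)
  i_peak <- which.max(replace(d$dff, is.na(d$dff), -Inf))
  # peak of dF/F within about one volume period of the latent peak
  expect_lt(abs(d$t_s[i_peak] - 835), 1.5)
  expect_gt(max(d$dff, na.rm = TRUE), 0.2)
})
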