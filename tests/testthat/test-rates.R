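test_that("Clopper-Pearson equals the binomial-tail root-finding oracle", {
  expect_equal(clopper_pearson(0, 20, 0.9)[["lo"]], 0)
  expect_equal(clopper_pearson(20, 20, 0.9)[["hi"]], 1)
  for (n in c(1, 5, 10, 37, 120)) for (k in unique(c(0, 1, n %/% 2, n)))
    for (lev in c(0.9, 0.95)) {
      got <- clopper_pearson(k, n, lev)
      want <- oracle_cp(k, n, lev)
      expect_equal(got[["lo"]], want[["lo"]], tolerance = 1e-10)
      expect_equal(got[["hi"]], want[["hi"]], tolerance = 1e-10)
    }
  expect_error(clopper_pearson(5, 4, 0.9), "invalid")
  expect_error(clopper_pearson(-1, 4, 0.9), "invalid")
  expect_error(clopper_pearson(1, 4, 1.2), "invalid")
})

test_that("elapsed time since transition matches examples and the scan oracle", {
  t <- seq(0, 300, 0.5)
  el <- elapsed_since_transition(
    t, 100, data.frame(start_s = 150, end_s = 200))
  sel <- el$in_search
  expect_equal(range(el$elapsed_s[sel]), c(50, 100))
  expect_false(any(el$since_session_start[t >= 100]))
  # no transitions: everything flagged since session start
  el0 <- elapsed_since_transition(t, numeric(0))
  expect_true(all(el0$since_session_start))
  expect_equal(el0$elapsed_s, t - t[1])
  # interleaved random transitions equal the brute-force scan
  set.seed(5)
  trans <- sort(stats::runif(12, 0, 290))
  el2 <- elapsed_since_transition(t, trans)
  expect_equal(el2$elapsed_s, oracle_elapsed(t, trans))
})

test_that("rate-curve arithmetic follows the visit-based estimator", {
  # one bin: 1 egg over 120 frames (60 s of search at 2 Hz) = 1 egg/min
  frames <- data.frame(elapsed_s = seq(0, 59.5, 0.5),
                       direction = "higher->lower", search_id = "s1")
  eggs <- data.frame(elapsed_s = 30, direction = "higher->lower")
  rc <- compute_rate_curve(frames, eggs, c(0, 60))
  expect_equal(rc$rate_eggs_per_min, 1)
  expect_equal(rc$n_visits, 1)  # one continuous stay = one visit
  # zero eggs: rate 0, CI transformed from the exact binomial bound
  frames10 <- do.call(rbind, lapply(1:10, function(i)
    data.frame(elapsed_s = seq(0, 59.5, 0.5),
               direction = "higher->lower",
               search_id = paste0("s", i))))
  rc0 <- compute_rate_curve(frames10, eggs[0, ], c(0, 60))
  expect_equal(rc0$rate_eggs_per_min, 0)
  expect_equal(rc0$ci_lo, 0)
  expect_equal(rc0$n_visits, 10)
  expect_equal(rc0$ci_hi,
               120 * clopper_pearson(0, 10, 0.9)[["hi"]] * 10 / 1200)
  # eggs in a bin with no visits is inconsistent
  expect_error(
    compute_rate_curve(frames, data.frame(elapsed_s = 70,
                                          direction = "higher->lower"),
                       c(0, 60, 120)),
    "inconsistent")
})

test_that("visit counting increments only on assignment changes", {
  # elapsed walks 0..29.5 s then a new transition resets it to 0:
  # bin [0,15) is entered twice, bin [15,30) once
  frames <- data.frame(
    elapsed_s = c(seq(0, 29.5, 0.5), seq(0, 9.5, 0.5)),
    direction = "higher->lower", search_id = "s1")
  rc <- compute_rate_curve(frames, data.frame(elapsed_s = numeric(0),
                                              direction = character(0)),
                           c(0, 15, 30))
  expect_equal(rc$n_visits, c(2, 1))
  expect_equal(rc$n_frames, c(50, 30))
})

test_that("counts re-aggregate exactly under bin refinement", {
  rf <- session_rate_frames(default_cohort()[1:6])
  coarse <- c(0, 60, 240, 7200)
  fine <- c(0, 15, 30, 60, 120, 240, 480, 960, 1920, 3840, 7200)
  rc_c <- compute_rate_curve(rf$frames, rf$eggs, coarse)
  rc_f <- compute_rate_curve(rf$frames, rf$eggs, fine)
  for (d in unique(rc_c$direction)) for (b in seq_len(length(coarse) - 1)) {
    inb <- rc_f$direction == d & rc_f$bin_lo_s >= coarse[b] &
      rc_f$bin_hi_s <= coarse[b + 1]
    row <- rc_c[rc_c$direction == d & rc_c$bin_lo_s == coarse[b], ]
    expect_equal(sum(rc_f$n_eggs[inb]), row$n_eggs)
    expect_equal(sum(rc_f$n_frames[inb]), row$n_frames)
  }
  # totals: every egg and every padded search frame lands in some bin
  expect_equal(sum(rc_c$n_eggs), nrow(rf$eggs))
  expect_equal(sum(rc_c$n_frames), nrow(rf$frames))
})

test_that("choice-fraction confidence intervals attain nominal coverage", {
  set.seed(19)
  p_true <- 0.93
  n <- 771
  hit <- logical(1000)
  for (i in seq_along(hit)) {
    k <- stats::rbinom(1, n, p_true)
    ci <- clopper_pearson(k, n, 0.95)
    hit[i] <- ci[["lo"]] <= p_true && p_true <= ci[["hi"]]
  }
  expect_gte(mean(hit), 0.93)
})

test_that("rate-curve intervals cover a constant-hazard truth", {
  # searches with per-frame egg hazard h, one substrate, no transitions,
  # all inside a single wide bin; the transformed CP interval should
  # cover the true rate 120 * h at (at least) its nominal level
  # searches enter a 60 s bin and either lay an egg there (constant
  # per-frame hazard) or pass through; the Clopper-Pearson interval on
  # eggs/visits, transformed by 120 * visits/frames, should cover the
  # true rate 120 * h
  run_cov <- function(h, n_search = 500, bin_frames = 120L, reps = 1000) {
    hit <- logical(reps)
    for (r in seq_along(hit)) {
      draw <- stats::rgeom(n_search, h) + 1L   # frames until the egg
      laid <- draw <= bin_frames
      len <- pmin(draw, bin_frames)
      ci <- clopper_pearson(sum(laid), n_search, 0.95) *
        120 * n_search / sum(len)
      hit[r] <- ci[["lo"]] <= 120 * h && 120 * h <= ci[["hi"]]
    }
    mean(hit)
  }
  set.seed(23)
  # disfavoured-substrate regime (~0.1 eggs/min, few eggs per visit):
  # the regime the interval is scientifically used in; near-nominal
  expect_gte(run_cov(0.00075), 0.93)
  # known limitation: at high egg-per-visit probability the negative
  # egg/frame-count correlation makes the transformed interval mildly
  # anticonservative; it must still not collapse
  expect_gte(run_cov(0.004), 0.85)
})

test_that("disfavoured-substrate rate is suppressed early and recovers late", {
  rf <- session_rate_frames(default_cohort())
  rc <- compute_rate_curve(rf$frames, rf$eggs, c(0, 60, 240, 7200))
  dis <- rc[rc$direction == "lower->higher", ]
  fav <- rc[rc$direction == "higher->lower", ]
  expect_lt(dis$rate_eggs_per_min[1], dis$rate_eggs_per_min[3])
  # early suppression is specific to the disfavoured option: an order of
  # magnitude below the favoured-substrate rate at the same elapsed time
  expect_lt(dis$rate_eggs_per_min[1], 0.5 * fav$rate_eggs_per_min[1])
})

test_that("short searches are padded to 30 s in the denominator", {
  p <- drift_params(noise_sd = 0, drift_rate_high = 0.2,
                    inter_egg_refractory = 60)
  ch <- chamber_spec()
  s <- simulate_session(p, ch, 1800, seed = 2, hold_at = c(20, 5))
  # deterministic searches of 5 s + 3 s delay: every counted search
  # contributes at least 30 s of frames
  rf <- session_rate_frames(s)
  expect_gt(nrow(s$egg_events), 3)
  per_search <- table(rf$frames$search_id)
  expect_true(all(per_search >= 30 / 0.5))
})
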