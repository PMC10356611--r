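test_that("substrate assignment follows the centroid and midline tie-break", {
  ch <- chamber_spec()  # midline at 20, 0mM below, 500mM above
  tr <- data.frame(t_s = seq(0, 4.5, 0.5), x_mm = 5,
                   y_mm = c(1, 5, 10, 19, 20, 20.0001, 25, 30, 39, 2))
  a <- assign_substrate(tr, ch)
  expect_equal(a$label, c(rep("0mM", 5), rep("500mM", 4), "0mM"))
  expect_true(a$on_barrier[4] && a$on_barrier[5] && a$on_barrier[6])
  expect_false(any(a$on_barrier[c(1, 9)]))
  # sinusoidal crossing flips at analytically known frames
  t <- seq(0, 100, 0.5)
  y <- 20 + 5 * sin(2 * pi * t / 20)
  lab <- assign_substrate(data.frame(t_s = t, x_mm = 5, y_mm = y), ch)$label
  expect_equal(lab, ifelse(y <= 20, "0mM", "500mM"))
  tr$y_mm[3] <- 41
  expect_error(assign_substrate(tr, ch), "frame 3")
})

test_that("search-start detection matches the loop oracle and honours the floor", {
  dt <- 0.5
  t <- seq(0, 300, dt)
  dep <- 300
  # 60 s standstill ending 40 s before deposition, walking otherwise
  speed <- rep(5, length(t))
  speed[t >= 200 & t < 260] <- 0
  r <- detect_search_start(speed, t, dep)
  expect_equal(r$search_start_s, oracle_search_start(speed, t, dep),
               tolerance = 1)
  expect_false(r$clamped || r$fallback)
  # continuous walking: the minimum search duration emerges as 9 s
  r2 <- detect_search_start(rep(5, length(t)), t, dep)
  expect_equal(r2$duration_s, 9)
  expect_true(r2$fallback)
  # identically-zero speed clamps to 9 s
  r3 <- detect_search_start(rep(0, length(t)), t, dep)
  expect_equal(r3$duration_s, 9)
  expect_true(r3$clamped)
})

test_that("search duration is never below 9 s over randomized speed traces", {
  set.seed(101)
  t <- seq(0, 400, 0.5)
  for (i in 1:100) {
    speed <- stats::runif(length(t), 0, 6)
    # random still stretches
    for (j in seq_len(sample(0:3, 1))) {
      a <- stats::runif(1, 0, 350)
      speed[t >= a & t <= a + stats::runif(1, 5, 80)] <- 0
    }
    dep <- stats::runif(1, 150, 400)
    r <- detect_search_start(speed, t, dep)
    expect_gte(r$duration_s, 9 - 1e-9)
    expect_equal(r$search_start_s, oracle_search_start(speed, t, dep),
                 tolerance = 1e-9)
  }
})

test_that("transition de-rocking removes only rocking triplets", {
  # transitions at 0, 1, 2 s: the middle one is eliminated
  labs <- c("A", "B", "A", "B", "B", "B")
  t <- c(-0.5, 0, 1, 2, 3, 4)
  ev <- detect_transitions(labs, t)
  expect_equal(ev$time_s, c(0, 2))
  expect_equal(ev$to_substrate, c("B", "B"))
  # single transition kept; well-separated transitions all kept
  expect_equal(nrow(detect_transitions(c("A", "B"), c(0, 0.5))), 1)
  labs10 <- rep(c("A", "B"), each = 20, times = 5)
  t10 <- seq_along(labs10) * 0.5
  expect_equal(nrow(detect_transitions(labs10, t10)), 9)
  expect_equal(nrow(detect_transitions(character(0), numeric(0))), 0)
})

test_that("transition detection is invariant to constant-label padding", {
  set.seed(7)
  labs <- sample(c("A", "B"), 300, replace = TRUE)
  t <- seq_along(labs) * 0.5
  base <- detect_transitions(labs, t)
  pad <- c(rep(labs[1], 50), labs, rep(labs[length(labs)], 50))
  tp <- seq_along(pad) * 0.5
  shifted <- detect_transitions(pad, tp)
  expect_equal(nrow(shifted), nrow(base))
  expect_equal(shifted$time_s - 25, base$time_s)
})

test_that("choice and leaving statistics count eggs, starts and leavers", {
  t <- seq(0, 99.5, 0.5)
  lab <- ifelse(t < 40 | t >= 70, "0mM", "500mM")
  fl <- data.frame(t_s = t, label = lab)
  eggs <- data.frame(
    search_start_s = c(5, 35, 65),
    deposition_s = c(20, 50, 90),
    substrate = c("0mM", "500mM", "0mM"))
  st <- choice_and_leaving_stats(eggs, fl)
  eggs_on_0 <- st[st$metric == "eggs_on" & st$option == "0mM", ]
  expect_equal(c(eggs_on_0$k, eggs_on_0$n), c(2, 3))
  starts_0 <- st[st$metric == "search_started_on" & st$option == "0mM", ]
  expect_equal(starts_0$k, 2)  # searches at 5 and 35 start on 0mM
  left_0 <- st[st$metric == "left_start_substrate" & st$option == "0mM", ]
  expect_equal(c(left_0$k, left_0$n), c(1, 2))  # the 35 s search crosses
  left_5 <- st[st$metric == "left_start_substrate" & st$option == "500mM", ]
  expect_equal(c(left_5$k, left_5$n), c(1, 1))  # the 65 s search crosses back
  # k = 0: fraction 0 with exact-zero lower bound
  z <- fraction_with_ci(0, 10)
  expect_equal(z$fraction, 0)
  expect_equal(z$ci_lo, 0)
  # n = 0 is reported as missing
  expect_true(is.na(fraction_with_ci(0, 0)$fraction))
})

test_that("binary rank-sum is exact at small n and matches wilcox at large n", {
  # exhaustive agreement with permutation enumeration
  for (n1 in 1:5) for (n2 in 1:5)
    for (k1 in 0:n1) for (k2 in 0:n2) {
      p <- binary_group_ranksum(k1, n1, k2, n2)
      expect_equal(p, oracle_ranksum_exact(k1, n1, k2, n2),
                   tolerance = 1e-12,
                   info = sprintf("k1=%d n1=%d k2=%d n2=%d", k1, n1, k2, n2))
    }
  expect_equal(binary_group_ranksum(3, 5, 3, 5), 1)
  expect_equal(binary_group_ranksum(5, 5, 5, 5), 1)
  expect_equal(binary_group_ranksum(0, 5, 0, 5), 1)
  # large-sample normal approximation cross-checked against wilcox.test
  for (cs in list(c(734, 771, 592, 771), c(149, 179, 212, 592),
                  c(60, 100, 40, 120))) {
    mine <- binary_group_ranksum(cs[1], cs[2], cs[3], cs[4])
    ref <- stats::wilcox.test(
      c(rep(1, cs[1]), rep(0, cs[2] - cs[1])),
      c(rep(1, cs[3]), rep(0, cs[4] - cs[3])),
      exact = FALSE, correct = FALSE)$p.value
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("per-fly summaries exclude sparse flies and compute medians", {
  eggs <- data.frame(
    fly = c(rep("f1", 5), rep("f2", 4)),
    search_start_s = 0,
    deposition_s = c(10, 20, 30, 40, 50, 5, 6, 7, 8))
  eggs$search_start_s <- 0
  s <- per_fly_search_summary(eggs, min_eggs = 5)
  expect_equal(s$fly, "f1")
  expect_equal(s$median_search_s, 30)
  expect_equal(nrow(per_fly_search_summary(eggs[eggs$fly == "f2", ])), 0)
})

test_that("hyperpolarization-mimic cohorts search >=2x longer without losing choice", {
  ses_d <- sim_cohort("kirctl", 60, 7200, seeds = 301:360)
  ses_k <- sim_cohort("kirmimic", 60, 7200, seeds = 401:460,
                      params = kir_mimic_params(drift_params(), 0.4))
  eggs_d <- cohort_eggs(ses_d); eggs_k <- cohort_eggs(ses_k)
  sum_d <- per_fly_search_summary(eggs_d, min_eggs = 5)
  sum_k <- per_fly_search_summary(eggs_k, min_eggs = 5)
  expect_gt(nrow(sum_d), 0); expect_gt(nrow(sum_k), 0)
  expect_gte(stats::median(sum_k$median_search_s) /
               stats::median(sum_d$median_search_s), 2)
  # the slowed drive gives the fly more substrate encounters per
  # decision: the preferred-substrate fraction rises
  expect_gte(mean(eggs_k$substrate == "0mM"),
             mean(eggs_d$substrate == "0mM"))
})
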