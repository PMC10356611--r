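# Independent brute-force oracles: literal loop re-implementations and
# closed forms used to pin the vectorised code paths.

oracle_boxcar <- function(x, w) {
  n <- length(x)
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  out <- numeric(n)
  for (i in seq_len(n)) {
    v <- x[max(1L, i - half_lo):min(n, i + half_hi)]
    v <- v[is.finite(v)]
    out[i] <- if (length(v)) mean(v) else NaN
  }
  out
}

oracle_prev_neighbour <- function(values, ts, grid) {
  out <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    ok <- which(ts <= grid[i] + 1e-12)
    if (length(ok)) out[i] <- values[max(ok)]
  }
  out
}

oracle_elapsed <- function(t, trans) {
  out <- numeric(length(t))
  for (i in seq_along(t)) {
    prev <- trans[trans <= t[i]]
    out[i] <- if (length(prev)) t[i] - max(prev) else t[i] - t[1]
  }
  out
}

oracle_spike_rate <- function(spikes, centres, w) {
  vapply(centres, function(tc)
    sum(spikes > tc - w / 2 - 1e-12 & spikes <= tc + w / 2) / w,
    numeric(1))
}

oracle_triggered <- function(x, t, events, window_s, excl = NULL) {
  dt <- t[2] - t[1]
  m <- round(window_s / dt)
  rel <- seq(-m, m) * dt
  mat <- matrix(NA_real_, length(events), length(rel))
  for (i in seq_along(events)) {
    for (j in seq_along(rel)) {
      k <- round((events[i] + rel[j] - t[1]) / dt) + 1L
      if (k >= 1 && k <= length(t)) mat[i, j] <- x[k]
      if (!is.null(excl)) {
        nxt <- excl[excl > events[i]]
        if (length(nxt) && rel[j] >= min(nxt) - events[i] - 1e-9)
          mat[i, j] <- NA_real_
      }
    }
  }
  n <- colSums(is.finite(mat))
  mu <- ifelse(n > 0, colMeans(mat, na.rm = TRUE), NA_real_)
  sd_ <- apply(mat, 2, function(cc) stats::sd(cc[is.finite(cc)]))
  list(rel_t = rel, mean = mu,
       sem = ifelse(n > 1, sd_ / sqrt(n), NA_real_), n = n)
}

# Clopper-Pearson bounds by root-finding on the binomial tails
oracle_cp <- function(k, n, level) {
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else
    stats::uniroot(function(p) sum(stats::dbinom(k:n, n, p)) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  hi <- if (k == n) 1 else
    stats::uniroot(function(p) sum(stats::dbinom(0:k, n, p)) - a,
                   c(1e-12, 1 - 1e-12), tol = 1e-14)$root
  c(lo = lo, hi = hi)
}

# two-sided exact permutation rank-sum p on binary groups (enumeration)
oracle_ranksum_exact <- function(k1, n1, k2, n2) {
  x <- c(rep(1, k1), rep(0, n1 - k1), rep(1, k2), rep(0, n2 - k2))
  N <- n1 + n2
  r <- rank(x)
  mu <- n1 * (N + 1) / 2
  Wobs <- sum(r[seq_len(n1)])
  idx <- utils::combn(N, n1)
  Ws <- apply(idx, 2, function(j) sum(r[j]))
  mean(abs(Ws - mu) >= abs(Wobs - mu) - 1e-9)
}

# literal loop re-implementation of the search-start detector
oracle_search_start <- function(speed, t, dep, boxcar_s = 18.5,
                                thr = 0.1, min_s = 9) {
  keep <- which(t <= dep + 1e-9)
  sp <- speed[keep]; tk <- t[keep]
  dt <- t[2] - t[1]
  sm <- oracle_boxcar(sp, round(boxcar_s / dt))
  best <- NA_real_
  for (i in rev(seq_along(sp))) if (sm[i] < thr) { best <- tk[i]; break }
  start <- if (is.na(best)) dep - min_s else best
  if (dep - start < min_s) start <- dep - min_s
  start
}

# frame-by-frame recursion for the relative-value drift trace
oracle_value_trace <- function(labels, p, fav, dt) {
  out <- numeric(length(labels))
  last <- 0
  for (i in seq_along(labels)) {
    tt <- (i - 1) * dt
    if (!is.na(fav) && labels[i] == fav) {
      last <- tt
      out[i] <- p$drift_rate_high
    } else if (is.na(fav)) {
      out[i] <- p$drift_rate_high
    } else {
      out[i] <- p$drift_rate_high -
        (p$drift_rate_high - p$drift_rate_low) * exp(-(tt - last) / p$value_adapt_tau)
    }
  }
  out
}

# analytic exponential-filter response to a step-rate pulse, and its
# boxcar average by numerical quadrature (the forward-model oracle)
oracle_gcamp_pulse <- function(r0, t_on, t_off, tau, boxcar_s) {
  y <- function(tt) {
    out <- numeric(length(tt))
    rising <- tt >= t_on & tt < t_off
    out[rising] <- r0 * (1 - exp(-(tt[rising] - t_on) / tau))
    after <- tt >= t_off
    out[after] <- r0 * (1 - exp(-(t_off - t_on) / tau)) *
      exp(-(tt[after] - t_off) / tau)
    out
  }
  B <- function(tt) vapply(tt, function(s)
    stats::integrate(y, s - boxcar_s / 2, s + boxcar_s / 2,
                     rel.tol = 1e-10, subdivisions = 500L)$value / boxcar_s,
    numeric(1))
  list(y = y, B = B)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
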