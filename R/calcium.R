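# dF/F computation (background subtraction + running-mean baseline) and
# event-aligned statistics on the common 10 Hz timebase.

#' NaN-aware centred boxcar filter
#'
#' Centred moving average with the window truncated at the trace ends;
#' NA/NaN samples are excluded from both numerator and denominator, so a
#' window with no finite samples yields NaN.
#'
#' @param x Numeric series on a uniform grid.
#' @param width_s Window width in seconds.
#' @param dt Sample interval in seconds.
#' @return Smoothed series of the same length.
#' @export
boxcar <- function(x, width_s, dt) {
  if (!(width_s > 0)) stop("width_s must be positive")
  n <- length(x)
  if (n == 0) return(x)
  w <- max(1L, round(width_s / dt))
  half_lo <- (w - 1L) %/% 2L
  half_hi <- w - 1L - half_lo
  ok <- is.finite(x)
  xv <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xv))
  cn <- c(0, cumsum(as.numeric(ok)))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  num <- cs[hi + 1L] - cs[lo]
  den <- cn[hi + 1L] - cn[lo]
  out <- num / den        # 0/0 -> NaN where the window is all-NA
  out
}

# time-windowed NaN-aware running mean for possibly non-uniform timestamps
running_mean_window <- function(x, t, window_s) {
  ok <- is.finite(x)
  xv <- ifelse(ok, x, 0)
  cs <- c(0, cumsum(xv))
  cn <- c(0, cumsum(as.numeric(ok)))
  lo <- findInterval(t - window_s / 2 - 1e-12, t) + 1L
  hi <- findInterval(t + window_s / 2 + 1e-12, t)
  (cs[hi + 1L] - cs[lo]) / (cn[hi + 1L] - cn[lo])
}

#' Resample a series onto a uniform grid by previous-neighbour assignment
#'
#' Each grid point takes the value of the latest sample at or before it;
#' grid points before the first sample are NA.
#'
#' @param values Sample values.
#' @param timestamps Sorted sample times.
#' @param grid_t Target grid times.
#' @return Values on the grid.
#' @export
resample_previous_neighbour <- function(values, timestamps, grid_t) {
  stopifnot(length(values) == length(timestamps))
  if (length(values) == 0) return(rep(NA_real_, length(grid_t)))
  idx <- findInterval(grid_t + 1e-12, timestamps)
  out <- rep(NA_real_, length(grid_t))
  out[idx > 0] <- values[idx[idx > 0]]
  out
}

#' Compute dF/F from a pooled fluorescence recording
#'
#' Background is subtracted first, `F_actual(t) = F_cell(t) -
#' F_background(t)`.  The baseline `F0(t)` is the centred running mean
#' of `F_actual` over `window_s` (default 20 min), truncated at the
#' recording edges; when a stimulation schedule is given, `stim_blank_s`
#' seconds after each stimulation onset are set to NaN before the
#' baseline is computed so stimulation transients cannot contaminate
#' `F0`.  Then `dff = (F_actual - F0) / F0`, with samples where
#' `F0 <= 0` set to NaN, and the result is resampled to a uniform grid
#' (default 10 Hz) by previous-neighbour assignment.
#'
#' @param rec Data frame `volume_t_s, F_cell, F_background`.
#' @param window_s Baseline window in seconds.
#' @param stim_onsets Optional vector of stimulation onset times.
#' @param stim_blank_s Seconds masked after each onset.
#' @param grid_hz Output grid rate in Hz.
#' @param f0 `"running"` for the running-mean baseline or `"fixed"` for
#'   a constant baseline (whole-recording mean), kept as a robustness
#'   variant.
#' @return Data frame `t_s, dff, stim_mask` on the uniform grid, with
#'   attribute `n_nonpositive_f0` counting samples dropped because
#'   `F0 <= 0`.
#' @export
compute_dff <- function(rec, window_s = 1200, stim_onsets = NULL,
                        stim_blank_s = 105, grid_hz = 10,
                        f0 = c("running", "fixed")) {
  f0 <- match.arg(f0)
  if (!(window_s > 0)) stop("window_s must be positive")
  tt <- rec$volume_t_s
  if (length(tt) < 2 || diff(range(tt)) < 120)
    stop("recording must span at least 2 minutes")
  f_act <- rec$F_cell - rec$F_background
  f_mask <- f_act
  masked <- rep(FALSE, length(tt))
  for (on in stim_onsets)
    masked <- masked | (tt >= on & tt < on + stim_blank_s)
  f_mask[masked] <- NaN
  f0v <- if (f0 == "running") running_mean_window(f_mask, tt, window_s)
         else rep(mean(f_mask, na.rm = TRUE), length(tt))
  dff <- (f_act - f0v) / f0v
  bad <- is.finite(f0v) & f0v <= 0
  dff[bad] <- NaN
  if (all(!is.finite(dff))) stop("dF/F is undefined everywhere")
  grid_t <- seq(0, max(tt), by = 1 / grid_hz)
  out <- data.frame(
    t_s = grid_t,
    dff = resample_previous_neighbour(dff, tt, grid_t),
    stim_mask = resample_previous_neighbour(as.numeric(masked), tt,
                                            grid_t) > 0)
  out$stim_mask[is.na(out$stim_mask)] <- FALSE
  attr(out, "n_nonpositive_f0") <- sum(bad)
  out
}

#' Event-triggered ensemble average
#'
#' Cuts the series into `[-window_s, +window_s]` snippets around each
#' event and averages them per relative-time sample.  When
#' `exclusion_times` are given, each snippet is truncated at the first
#' exclusion event after its own trigger: samples at or after it are
#' dropped (e.g. a return transition 20 s after a substrate transition
#' removes everything from +20 s onwards from that trace).
#'
#' @param x Series on a uniform grid.
#' @param t Grid times.
#' @param event_times Trigger times (must lie within the recording).
#' @param window_s Half-window in seconds.
#' @param exclusion_times Optional times that truncate individual
#'   snippets.
#' @return List of class `aligned_ensemble`: `rel_t`, `traces` (events
#'   in rows), `mean`, `sem`, `n` (contributing traces per sample).
#' @export
triggered_average <- function(x, t, event_times, window_s,
                              exclusion_times = NULL) {
  stopifnot(length(x) == length(t), length(t) >= 2)
  dt <- t[2] - t[1]
  usable <- event_times >= t[1] & event_times <= t[length(t)]
  event_times <- event_times[usable]
  if (length(event_times) == 0) stop("zero usable events")
  m <- round(window_s / dt)
  rel_t <- seq(-m, m) * dt
  traces <- matrix(NA_real_, nrow = length(event_times), ncol = 2L * m + 1L)
  for (i in seq_along(event_times)) {
    e0 <- round((event_times[i] - t[1]) / dt)  # nearest grid sample
    idx <- e0 + seq(-m, m) + 1L
    valid <- idx >= 1L & idx <= length(t)
    traces[i, valid] <- x[idx[valid]]
    if (!is.null(exclusion_times)) {
      nxt <- exclusion_times[exclusion_times > event_times[i]]
      if (length(nxt)) {
        cut <- min(nxt) - event_times[i]
        traces[i, rel_t >= cut - 1e-9] <- NA_real_
      }
    }
  }
  n <- colSums(is.finite(traces))
  mu <- ifelse(n > 0, colMeans(traces, na.rm = TRUE), NA_real_)
  sd_ <- apply(traces, 2, function(col) stats::sd(col[is.finite(col)]))
  sem <- ifelse(n > 1, sd_ / sqrt(n), NA_real_)
  structure(list(rel_t = rel_t, traces = traces, mean = mu, sem = sem,
                 n = n), class = "aligned_ensemble")
}

#' Normalised cross-correlation versus lag
#'
#' Pearson correlation of two gridded series at integer-sample lags up
#' to `max_lag_s`, dropping incomplete pairs pairwise.  Positive lag
#' means `b` is delayed relative to `a`: if `b(t) = a(t - 3)` the peak
#' is at lag +3 s.
#'
#' @param a,b Series on the same uniform grid.
#' @param dt Grid interval in seconds.
#' @param max_lag_s Maximum |lag| in seconds.
#' @return Data frame `lag_s, r`.
#' @export
cross_correlate <- function(a, b, dt, max_lag_s) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  L <- round(max_lag_s / dt)
  lags <- seq(-L, L)
  r <- vapply(lags, function(k) {
    if (k >= 0) { ai <- a[seq_len(n - k)]; bi <- b[seq_len(n - k) + k] }
    else { ai <- a[seq_len(n + k) - k]; bi <- b[seq_len(n + k)] }
    ok <- is.finite(ai) & is.finite(bi)
    if (sum(ok) < 10) return(NA_real_)
    stats::cor(ai[ok], bi[ok])
  }, numeric(1))
  if (all(is.na(r))) stop("fewer than 10 overlapping samples at all lags")
  data.frame(lag_s = lags * dt, r = r)
}

#' Net dF/F slope from baseline re-crossing to just before the bend
#'
#' The dF/F trace is smoothed with a `smooth_s` boxcar; the signal
#' minimum after `ovulation_start_s` is located, then the first
#' subsequent time the smoothed signal reaches 0 (`t_start`).  The net
#' slope is the smoothed dF/F at `bend_complete_s - end_offset_s`
#' (about when the abdomen bend starts) divided by the time from
#' `t_start` to that endpoint.
#'
#' @param dff Data frame `t_s, dff` on a uniform grid.
#' @param ovulation_start_s,bend_complete_s Event times bracketing the
#'   rise.
#' @param smooth_s Boxcar width in seconds.
#' @param end_offset_s Seconds before bend completion at which the
#'   endpoint is taken.
#' @return List `slope` (dF/F per second, NA when the smoothed signal
#'   never reaches 0 before the endpoint, flagged by `defined = FALSE`),
#'   `t_start`, `t_end`, `defined`.
#' @export
slope_to_threshold <- function(dff, ovulation_start_s, bend_complete_s,
                               smooth_s = 5, end_offset_s = 3.3) {
  t <- dff$t_s
  dt <- t[2] - t[1]
  sm <- boxcar(dff$dff, smooth_s, dt)
  t_end <- bend_complete_s - end_offset_s
  span <- which(t >= ovulation_start_s & t <= bend_complete_s &
                  is.finite(sm))
  if (!length(span)) stop("dff does not cover ovulation through bend")
  i_min <- span[which.min(sm[span])]
  after <- span[span >= i_min & t[span] <= t_end + 1e-9]
  i0 <- after[sm[after] >= 0][1]
  if (is.na(i0))
    return(list(slope = NA_real_, t_start = NA_real_, t_end = t_end,
                defined = FALSE))
  t_start <- t[i0]
  i_end <- which.min(abs(t - t_end))
  denom <- t_end - t_start
  slope <- if (denom > 0) (sm[i_end] - 0) / denom else 0
  list(slope = slope, t_start = t_start, t_end = t_end, defined = TRUE)
}

#' Bin optogenetic stimulations by evoked dF/F and behavioural change
#'
#' Each stimulation is assigned to one of seven bins by the maximum
#' dF/F 1-3 s after its onset: bin 1 below the first edge (0.02), bins
#' 2-6 the equal 0.10-wide interior bins, bin 7 at or above the last
#' edge (0.52).  The behavioural change is the mean behavioural signal
#' 2-4 s after onset minus the mean 0-2 s before onset (post minus
#' pre).  Stimulations too close to the recording end are skipped.
#'
#' @param dff Data frame `t_s, dff` on a uniform grid.
#' @param stim_onsets Stimulation onset times.
#' @param behaviour Optional data frame `t_s, value` on the same grid.
#' @param edges Bin edges for the evoked dF/F (7 bins from 6 edges).
#' @param resp_window Response window (s after onset) for the max dF/F.
#' @param post_window,pre_window Windows for the behavioural delta.
#' @return Data frame `stim_onset_s, max_dff, bin, behaviour_delta`,
#'   with skipped stimulations counted in attribute `n_skipped`.
#' @export
stim_response_bins <- function(dff, stim_onsets, behaviour = NULL,
                               edges = c(0.02, 0.12, 0.22, 0.32, 0.42, 0.52),
                               resp_window = c(1, 3),
                               post_window = c(2, 4),
                               pre_window = c(-2, 0)) {
  t <- dff$t_s
  out <- list(); skipped <- 0L
  for (on in stim_onsets) {
    need_end <- on + max(resp_window[2], post_window[2])
    if (need_end > t[length(t)] + 1e-9) { skipped <- skipped + 1L; next }
    ri <- t >= on + resp_window[1] & t <= on + resp_window[2]
    mx <- suppressWarnings(max(dff$dff[ri], na.rm = TRUE))
    if (!is.finite(mx)) { skipped <- skipped + 1L; next }
    bin <- findInterval(mx, edges) + 1L
    delta <- NA_real_
    if (!is.null(behaviour)) {
      bt <- behaviour$t_s
      post <- behaviour$value[bt >= on + post_window[1] &
                                bt <= on + post_window[2]]
      pre <- behaviour$value[bt >= on + pre_window[1] &
                               bt <= on + pre_window[2]]
      delta <- mean(post, na.rm = TRUE) - mean(pre, na.rm = TRUE)
    }
    out[[length(out) + 1L]] <- data.frame(
      stim_onset_s = on, max_dff = mx, bin = bin, behaviour_delta = delta)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(stim_onset_s = numeric(0), max_dff = numeric(0),
               bin = integer(0), behaviour_delta = numeric(0))
  rownames(res) <- NULL
  attr(res, "n_skipped") <- skipped
  res
}
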