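# Egg-laying rate versus time since the last substrate transition, with
# the visit-based exact binomial confidence-interval transformation.
#
# Per bin the estimator is rate = 120 * n_eggs / n_frames (eggs/min at
# 2 Hz video).  The confidence interval is computed on n_eggs / n_visits
# with the Clopper-Pearson method and transformed to eggs/min by
# multiplying by 120 * n_visits / n_frames; it cannot be computed on
# n_eggs / n_frames directly because it would then depend on the frame
# rate.

#' Clopper-Pearson exact binomial confidence interval
#'
#' Standard beta-quantile bounds; the lower bound is exactly 0 when
#' `k = 0` and the upper bound exactly 1 when `k = n`.
#'
#' @param k Successes.
#' @param n Trials.
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(lo, hi)` of fractions.
#' @export
clopper_pearson <- function(k, n, level = 0.9) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1 || length(n) != 1 ||
      is.na(k) || is.na(n) || k < 0 || n < 1 || k > n || k != round(k))
    stop("invalid k or n for clopper_pearson")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("invalid confidence level")
  a <- (1 - level) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lo = lo, hi = hi)
}

#' Time elapsed since the last substrate transition, per frame
#'
#' For every frame, the elapsed time is measured from the most recent
#' transition at or before that frame, regardless of whether that
#' transition occurred during the current search period or earlier.
#' Frames before the first transition carry elapsed time measured from
#' the session start and are flagged `since_session_start`.  Frames are
#' marked `in_search` when they fall inside one of the supplied search
#' periods.
#'
#' @param t Frame times in seconds.
#' @param transition_times Sorted transition times.
#' @param search_periods Data frame with `start_s`, `end_s` (one row per
#'   search period), or `NULL` for no search annotation.
#' @return Data frame `t_s, elapsed_s, since_session_start, in_search`.
#' @export
elapsed_since_transition <- function(t, transition_times,
                                     search_periods = NULL) {
  idx <- findInterval(t, transition_times)
  elapsed <- ifelse(idx == 0, t - t[1], t - transition_times[pmax(idx, 1L)])
  in_search <- rep(FALSE, length(t))
  if (!is.null(search_periods) && nrow(search_periods))
    for (i in seq_len(nrow(search_periods)))
      in_search <- in_search |
        (t >= search_periods$start_s[i] - 1e-9 &
           t <= search_periods$end_s[i] + 1e-9)
  data.frame(t_s = t, elapsed_s = elapsed,
             since_session_start = idx == 0, in_search = in_search)
}

#' Egg-laying rate curve with visit-based confidence intervals
#'
#' Bins search-period frames and egg depositions by elapsed time since
#' the last substrate transition, separately per transition direction,
#' and estimates per-bin egg-laying rates.  A "visit" is an entry of a
#' frame's (direction, bin) assignment into the bin: the counter
#' increments when the assignment differs from the previous frame of the
#' same search period (the first frame of each search counts as an
#' entry), not while the fly stays in the bin frame-to-frame.
#'
#' @param frames Data frame of search-period frames with `elapsed_s`,
#'   `direction`, `search_id`, ordered by time within search period.
#' @param eggs Data frame of depositions with `elapsed_s`, `direction`.
#' @param bin_edges Increasing bin edges in seconds (bins are
#'   `[e_i, e_{i+1})`); must cover all elapsed values.
#' @param level Confidence level for the Clopper-Pearson interval.
#' @param frame_rate Video frame rate in Hz (2 Hz gives the factor 120
#'   to eggs/min).
#' @return Data frame `direction, bin_lo_s, bin_hi_s, n_eggs, n_frames,
#'   n_visits, rate_eggs_per_min, ci_lo, ci_hi`.  The rate is `NA` for
#'   bins with no frames.
#' @export
compute_rate_curve <- function(frames, eggs, bin_edges, level = 0.9,
                               frame_rate = 2) {
  stopifnot(is.numeric(bin_edges), !is.unsorted(bin_edges))
  nb <- length(bin_edges) - 1L
  if (nb < 1) stop("need at least two bin edges")
  if (nrow(frames) &&
      (min(frames$elapsed_s) < bin_edges[1] ||
       max(frames$elapsed_s) >= bin_edges[nb + 1]))
    stop("bin_edges do not cover all elapsed values")
  per_min <- 60 * frame_rate
  dirs <- sort(unique(c(frames$direction, eggs$direction)))
  fbin <- findInterval(frames$elapsed_s, bin_edges)
  ebin <- if (nrow(eggs)) findInterval(eggs$elapsed_s, bin_edges) else integer(0)
  # visits: change of (direction, bin) assignment within a search period
  new_visit <- logical(nrow(frames))
  if (nrow(frames)) {
    first <- c(TRUE, frames$search_id[-1] != frames$search_id[-nrow(frames)])
    changed <- c(TRUE, fbin[-1] != fbin[-nrow(frames)] |
                   frames$direction[-1] != frames$direction[-nrow(frames)])
    new_visit <- first | changed
  }
  out <- list()
  for (d in dirs) {
    fd <- frames$direction == d
    ed <- if (nrow(eggs)) eggs$direction == d else logical(0)
    for (b in seq_len(nb)) {
      in_bin <- fd & fbin == b
      n_frames <- sum(in_bin)
      n_visits <- sum(new_visit[in_bin])
      n_eggs <- sum(ed & ebin == b)
      if (n_visits == 0 && n_eggs > 0)
        stop("inconsistent counts: eggs in a bin with no visits")
      if (n_frames > 0) {
        rate <- per_min * n_eggs / n_frames
        ci <- clopper_pearson(n_eggs, n_visits, level) *
          per_min * n_visits / n_frames
      } else {
        rate <- NA_real_; ci <- c(lo = NA_real_, hi = NA_real_)
      }
      out[[length(out) + 1L]] <- data.frame(
        direction = d, bin_lo_s = bin_edges[b], bin_hi_s = bin_edges[b + 1],
        n_eggs = n_eggs, n_frames = n_frames, n_visits = n_visits,
        rate_eggs_per_min = rate, ci_lo = ci[["lo"]], ci_hi = ci[["hi"]],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default geometric bin edges for rate curves
#'
#' @param max_s Upper edge in seconds.
#' @return Numeric vector of edges.
#' @export
default_rate_bins <- function(max_s = 7200) {
  e <- c(0, 15, 30, 60, 120, 240, 480, 960, 1920, 3840, 7200)
  e[e <= max_s]
}

#' Build rate-curve inputs from simulated sessions
#'
#' Assembles the per-frame and per-egg tables that
#' [compute_rate_curve()] consumes: substrate labels, de-rocked
#' transitions, search periods (from the recorded egg events), elapsed
#' times, and transition directions.  Search periods shorter than
#' `pad_to_s` are padded by extending the start earlier (padding frames
#' inherit the elapsed times they would have had), which inflates the
#' denominator for very brief searches.  Direction is labelled by the
#' substrate currently occupied: `higher->lower` when the fly is on the
#' lower-sucrose (higher-relative-value) option, `lower->higher`
#' otherwise; for equal-concentration chambers the two sides are used
#' directly.
#'
#' @param sessions A `sim_session` or list of them.
#' @param pad_to_s Minimum counted search duration in seconds.
#' @return List with `frames` and `eggs` data frames for
#'   [compute_rate_curve()].
#' @export
session_rate_frames <- function(sessions, pad_to_s = 30) {
  if (inherits(sessions, "sim_session")) sessions <- list(sessions)
  all_frames <- list(); all_eggs <- list()
  for (s_i in seq_along(sessions)) {
    ses <- sessions[[s_i]]
    lab <- ses$labels
    t <- ses$trajectory$t_s
    fav <- ses$favoured
    tr <- detect_transitions(lab, t)
    eggs <- ses$egg_events
    if (!nrow(eggs)) next
    start <- pmax(t[1], pmin(eggs$search_start_s,
                             eggs$deposition_s - pad_to_s))
    sp <- data.frame(start_s = start, end_s = eggs$deposition_s)
    el <- elapsed_since_transition(t, tr$time_s, sp)
    dir_of <- function(l) {
      if (is.na(fav)) paste0("to_", l)
      else if (l == fav) "higher->lower" else "lower->higher"
    }
    for (e_i in seq_len(nrow(sp))) {
      sel <- which(el$in_search & t >= sp$start_s[e_i] - 1e-9 &
                     t <= sp$end_s[e_i] + 1e-9)
      if (!length(sel)) next
      all_frames[[length(all_frames) + 1L]] <- data.frame(
        elapsed_s = el$elapsed_s[sel],
        direction = vapply(lab[sel], dir_of, character(1)),
        search_id = sprintf("s%d_e%d", s_i, e_i),
        stringsAsFactors = FALSE)
    }
    dep_idx <- pmax(findInterval(eggs$deposition_s, t), 1L)
    all_eggs[[length(all_eggs) + 1L]] <- data.frame(
      elapsed_s = el$elapsed_s[dep_idx],
      direction = vapply(eggs$substrate, dir_of, character(1)),
      stringsAsFactors = FALSE)
  }
  empty_f <- data.frame(elapsed_s = numeric(0), direction = character(0),
                        search_id = character(0), stringsAsFactors = FALSE)
  empty_e <- data.frame(elapsed_s = numeric(0), direction = character(0),
                        stringsAsFactors = FALSE)
  list(frames = if (length(all_frames)) do.call(rbind, all_frames) else empty_f,
       eggs = if (length(all_eggs)) do.call(rbind, all_eggs) else empty_e)
}
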